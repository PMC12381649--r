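#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib neurofold, .registration = TRUE
NULL

#' Triangulated surface mesh
#'
#' A closed, oriented triangle mesh with vertex coordinates in millimetres.
#' Faces are stored counter-clockwise as seen from outside, so face normals
#' point outward. Optional per-vertex scalar fields (depth maps, labels) live
#' in \code{vertexData}.
#'
#' @slot vertices numeric matrix, n x 3, vertex positions in mm.
#' @slot faces integer matrix, m x 3, 1-based vertex indices, CCW/outward.
#' @slot vertexData data.frame of optional per-vertex scalars (may be empty).
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", faces = "matrix",
                 vertexData = "data.frame"),
  prototype(vertices = matrix(numeric(0), 0, 3),
            faces = matrix(integer(0), 0, 3),
            vertexData = data.frame()))

setValidity("SurfaceMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3) return("vertices must have 3 columns")
  if (ncol(f) != 3) return("faces must have 3 columns")
  if (nrow(f) > 0) {
    if (min(f) < 1 || max(f) > nrow(v))
      return("face indices out of range")
  }
  if (nrow(v) > 0 && any(!is.finite(v))) return("non-finite vertex coordinate")
  if (nrow(object@vertexData) > 0 && nrow(object@vertexData) != nrow(v))
    return("vertexData rows must match vertex count")
  TRUE
})

#' Conforming bilayer tetrahedral mesh
#'
#' Tetrahedral discretisation of a cortex/white-matter bilayer. Cortex and
#' white-matter elements share nodes and faces across the gray-white
#' interface. Each cortex element carries the referential unit normal of its
#' nearest pial patch, fixed once in the reference configuration.
#'
#' @slot nodes numeric matrix, n x 3, node positions in mm.
#' @slot tets integer matrix, m x 4, positively oriented tetrahedra.
#' @slot region integer vector, per-element label: 1 = cortex, 2 = white.
#' @slot pialFaces integer matrix, outward-oriented boundary faces on the
#'   pial surface (indices into \code{nodes}).
#' @slot interfaceFaces integer matrix, faces on the gray-white interface.
#' @slot normal0 numeric matrix, m x 3, referential pial unit normal per
#'   element (rows for white elements are zero).
#' @slot pialVertices integer vector, node ids lying on the pial surface.
#' @slot whiteVertices integer vector, node ids on the gray-white interface.
#' @export
setClass("BilayerTetMesh",
  representation(nodes = "matrix", tets = "matrix", region = "integer",
                 pialFaces = "matrix", interfaceFaces = "matrix",
                 normal0 = "matrix", pialVertices = "integer",
                 whiteVertices = "integer"))

setValidity("BilayerTetMesh", function(object) {
  if (ncol(object@nodes) != 3) return("nodes must have 3 columns")
  if (ncol(object@tets) != 4) return("tets must have 4 columns")
  if (length(object@region) != nrow(object@tets))
    return("region length must match tet count")
  if (!all(object@region %in% c(1L, 2L)))
    return("region labels must be 1 (cortex) or 2 (white)")
  if (nrow(object@tets) > 0 &&
      (min(object@tets) < 1 || max(object@tets) > nrow(object@nodes)))
    return("tet indices out of range")
  if (nrow(object@normal0) != nrow(object@tets))
    return("normal0 rows must match tet count")
  TRUE
})

#' Sulcal pit point cloud
#'
#' Sulcal pits of one brain as 3D points (mm) with the basin each pit
#' anchors: basin id, pit depth (depth-map units) and basin area (mm^2).
#'
#' @slot positions numeric matrix, p x 3, pit coordinates in mm.
#' @slot basinId integer vector, unique basin identifier per pit.
#' @slot depth numeric vector, pit depth in depth-map units.
#' @slot basinArea numeric vector, basin area in mm^2.
#' @export
setClass("PitCloud",
  representation(positions = "matrix", basinId = "integer",
                 depth = "numeric", basinArea = "numeric"))

setValidity("PitCloud", function(object) {
  p <- nrow(object@positions)
  if (ncol(object@positions) != 3) return("positions must have 3 columns")
  if (p > 0 && any(!is.finite(object@positions)))
    return("pit positions must be finite")
  if (length(object@basinId) != p || length(object@depth) != p ||
      length(object@basinArea) != p)
    return("basinId, depth, basinArea must match the number of pits")
  if (p > 0 && anyDuplicated(object@basinId))
    return("basin ids must be unique within a cloud")
  if (p > 0 && any(object@basinArea < 0)) return("basin areas must be >= 0")
  TRUE
})

#' Watershed basin segmentation of a surface
#'
#' Per-vertex sulcal basin labelling produced by watershed-by-flooding on a
#' depth map, together with per-basin pits, areas, ridge records and the log
#' of basin merges.
#'
#' @slot labels integer vector, per-vertex basin label (0 = unassigned).
#' @slot pitVertex integer vector, per-basin vertex index of the depth maximum.
#' @slot basinArea numeric vector, per-basin area in mm^2.
#' @slot ridges data.frame with columns basin1, basin2, ridgeVertex,
#'   ridgeHeight.
#' @slot mergeLog data.frame recording merges (from, into, reason).
#' @slot basinIds integer vector, ids aligned with pitVertex/basinArea.
#' @export
setClass("BasinSegmentation",
  representation(labels = "integer", pitVertex = "integer",
                 basinArea = "numeric", ridges = "data.frame",
                 mergeLog = "data.frame", basinIds = "integer"))

#' Result of sulcal pit matching between two brains
#'
#' One-to-one pit correspondences with per-pair Gaussian-kernel similarities,
#' the strongly-paired subset (similarity > 0.5), the aggregate SDSP, and the
#' soft matching matrix prior to discretisation.
#'
#' @slot pairs integer matrix, k x 2: index in P, index in Q.
#' @slot similarity numeric vector, per-pair similarity in (0, 1].
#' @slot strong logical vector, TRUE where similarity > threshold.
#' @slot sdsp numeric scalar, mean similarity over strong pairs (0 if none).
#' @slot matchMatrix numeric matrix, I x J correspondence likelihoods.
#' @slot flags character vector of condition flags (e.g. "no-strong-pairs").
#' @slot scaleFactors numeric vector of the six coarse half-axis factors.
#' @slot transform list with rotation (3 x 3) and translation (length 3) of
#'   the refined rigid registration.
#' @export
setClass("MatchResult",
  representation(pairs = "matrix", similarity = "numeric", strong = "logical",
                 sdsp = "numeric", matchMatrix = "matrix", flags = "character",
                 scaleFactors = "numeric", transform = "list"))

#' Growth simulation trajectory
#'
#' Snapshots of the differential-tangential-growth simulation: growth
#' multipliers, deformed geometry, per-element elastic state and extracted
#' pial/white surfaces at each emitted stage (evenly spaced in the
#' white-matter growth multiplier).
#'
#' @slot bilayer the reference \linkS4class{BilayerTetMesh}.
#' @slot snapshots list of per-stage states (nodes, theta values, elastic
#'   jacobians, stress norms, energies, extracted surfaces).
#' @slot params list of material parameters used.
#' @slot config list of solver configuration used.
#' @export
setClass("GrowthTrajectory",
  representation(bilayer = "BilayerTetMesh", snapshots = "list",
                 params = "list", config = "list"))
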