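#' @include AllClasses.R
NULL

#' Accessors for mesh and pit-cloud objects
#'
#' @param x a \linkS4class{SurfaceMesh}, \linkS4class{BilayerTetMesh} or
#'   \linkS4class{PitCloud}.
#' @return \code{vertices}/\code{nodes}: numeric matrix of coordinates (mm);
#'   \code{faces}/\code{tets}: index matrix; \code{nVertices}, \code{nFaces},
#'   \code{nPits}: integer counts; \code{pitPositions}: p x 3 matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))
#' @rdname accessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))
#' @rdname accessors
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))
#' @rdname accessors
#' @export
setGeneric("pitPositions", function(x) standardGeneric("pitPositions"))
#' @rdname accessors
#' @export
setGeneric("nPits", function(x) standardGeneric("nPits"))
#' @rdname accessors
#' @export
setGeneric("sdsp", function(x) standardGeneric("sdsp"))

#' @rdname accessors
#' @export
setMethod("vertices", "SurfaceMesh", function(x) x@vertices)
#' @rdname accessors
#' @export
setMethod("faces", "SurfaceMesh", function(x) x@faces)
#' @rdname accessors
#' @export
setMethod("nVertices", "SurfaceMesh", function(x) nrow(x@vertices))
#' @rdname accessors
#' @export
setMethod("nFaces", "SurfaceMesh", function(x) nrow(x@faces))
#' @rdname accessors
#' @export
setMethod("pitPositions", "PitCloud", function(x) x@positions)
#' @rdname accessors
#' @export
setMethod("nPits", "PitCloud", function(x) nrow(x@positions))

#' @rdname accessors
#' @export
setMethod("sdsp", "MatchResult", function(x) x@sdsp)

setMethod("show", "SurfaceMesh", function(object) {
  diag <- meshDiagnostics(object)
  cat("SurfaceMesh:", nrow(object@vertices), "vertices,",
      nrow(object@faces), "faces\n")
  cat("  closed:", diag$closed, " manifold:", diag$manifold,
      " oriented:", diag$oriented, "\n")
  if (ncol(object@vertexData) > 0)
    cat("  vertexData:", paste(names(object@vertexData), collapse = ", "), "\n")
})

setMethod("show", "BilayerTetMesh", function(object) {
  cat("BilayerTetMesh:", nrow(object@nodes), "nodes,",
      nrow(object@tets), "tets (",
      sum(object@region == 1L), "cortex /", sum(object@region == 2L),
      "white )\n")
  cat("  pial faces:", nrow(object@pialFaces),
      " interface faces:", nrow(object@interfaceFaces), "\n")
})

setMethod("show", "PitCloud", function(object) {
  cat("PitCloud:", nrow(object@positions), "sulcal pits\n")
  if (nrow(object@positions) > 0) {
    cat("  depth range:", signif(range(object@depth), 4), "\n")
    cat("  basin area range (mm^2):", signif(range(object@basinArea), 4), "\n")
  }
})

setMethod("show", "MatchResult", function(object) {
  cat("MatchResult:", nrow(object@pairs), "matched pairs,",
      sum(object@strong), "strong (similarity > 0.5)\n")
  cat("  SDSP:", signif(object@sdsp, 6), "\n")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "GrowthTrajectory", function(object) {
  ns <- length(object@snapshots)
  cat("GrowthTrajectory:", ns, "snapshots\n")
  if (ns > 0) {
    th <- vapply(object@snapshots, function(s) s$theta_sub, numeric(1))
    cat("  theta_sub:", signif(th, 4), "\n")
  }
})
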