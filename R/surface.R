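#' @include mesh-core.R
NULL

#' Taubin smoothing
#'
#' Low-shrinkage mesh fairing: alternating uniform-weight Laplacian steps
#' with positive factor \code{lambda} and negative factor \code{mu}
#' (pass-band choice lambda = 0.5, mu = -0.53). Connectivity and vertex
#' count are unchanged; volume change on brain-like meshes stays below a few
#' percent at 100 iterations.
#'
#' @param mesh a manifold \linkS4class{SurfaceMesh}.
#' @param iterations number of lambda/mu pairs to apply (the paper-default
#'   workflow uses 100).
#' @param lambda positive smoothing factor.
#' @param mu negative (inflating) factor, |mu| slightly above lambda.
#' @return smoothed \linkS4class{SurfaceMesh}.
#' @export
taubinSmooth <- function(mesh, iterations = 100, lambda = 0.5, mu = -0.53) {
  if (iterations < 0) stop("iterations must be >= 0")
  diag <- meshDiagnostics(mesh)
  if (!diag$manifold) stop("taubinSmooth requires a manifold mesh")
  if (iterations == 0) return(mesh)
  A <- vertexAdjacency(mesh)
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  v <- vertices(mesh)
  for (i in seq_len(iterations)) {
    d <- as.matrix(A %*% v) / deg - v
    v <- v + lambda * d
    d <- as.matrix(A %*% v) / deg - v
    v <- v + mu * d
  }
  SurfaceMesh(v, faces(mesh), mesh@vertexData)
}

#' Uniform isotropic remeshing
#'
#' Resamples a closed genus-0 surface at a uniform target edge length by
#' casting radial rays from the centroid of the input onto its surface along
#' the directions of a geodesic sphere whose resolution matches the target.
#' Valid for surfaces star-shaped about their centroid (which covers smooth
#' fetal-brain-like geometry); the output is closed, manifold and lies on
#' the input surface up to ray-intersection precision.
#'
#' @param mesh closed \linkS4class{SurfaceMesh}.
#' @param targetEdge target median edge length in mm.
#' @return remeshed \linkS4class{SurfaceMesh}.
#' @export
isotropicRemesh <- function(mesh, targetEdge) {
  if (targetEdge <= 0) stop("targetEdge must be positive")
  diag <- meshDiagnostics(mesh)
  if (!diag$closed) stop("isotropicRemesh requires a closed mesh")
  v <- vertices(mesh)
  ctr <- colMeans(v)
  rad <- sqrt(rowSums(sweep(v, 2, ctr, `-`)^2))
  if (targetEdge < min(rad) / 50)
    stop("targetEdge below 1/50 of the minimum feature size")
  rMean <- mean(rad)
  freq <- max(2L, as.integer(round(1.10715 * rMean / targetEdge)))
  sph <- geodesicSphere(1, freq)
  dirs <- vertices(sph)
  rr <- cpp_radial_project(v, faces(mesh), ctr, dirs)
  if (any(rr <= 0))
    stop("remeshing failed: surface is not star-shaped about its centroid")
  newV <- sweep(dirs * rr, 2, ctr, `+`)
  SurfaceMesh(newV, faces(sph))
}

#' Uniform inward offset
#'
#' Moves every vertex by \code{distance} along its inward area-weighted
#' vertex normal; used to derive the white-matter surface from the pial
#' surface at an assumed uniform early cortical thickness (paper-default
#' 1.4 mm). A light Laplacian relaxation pass is applied when the offset
#' creates degenerate triangles.
#'
#' @param mesh closed, outward-oriented \linkS4class{SurfaceMesh}.
#' @param distance inward offset in mm.
#' @return offset \linkS4class{SurfaceMesh}.
#' @export
inwardOffset <- function(mesh, distance) {
  if (distance == 0) return(mesh)
  if (distance < 0) stop("distance must be >= 0")
  n <- vertexNormals(mesh)
  v <- vertices(mesh) - distance * n
  out <- SurfaceMesh(v, faces(mesh), mesh@vertexData)
  # repair pass: if any face degenerated or flipped, relax locally
  ar0 <- faceAreas(mesh)
  ar1 <- faceAreas(out)
  bad <- ar1 < 0.05 * ar0
  if (any(bad)) {
    A <- vertexAdjacency(out)
    deg <- Matrix::rowSums(A); deg[deg == 0] <- 1
    badV <- unique(as.vector(faces(out)[bad, ]))
    for (k in 1:5) {
      sm <- as.matrix(A %*% v) / deg
      v[badV, ] <- 0.5 * v[badV, , drop = FALSE] + 0.5 * sm[badV, , drop = FALSE]
    }
    out <- SurfaceMesh(v, faces(mesh), mesh@vertexData)
    if (any(faceAreas(out) < 1e-12))
      stop("inward offset produced unrecoverable degenerate geometry")
  }
  if (enclosedVolume(out) <= 0)
    stop("inward offset produced a globally self-intersecting surface")
  out
}

# split a prism (bottom a,b,c / top A,B,C columns) into 3 tets with the
# lowest-column-id diagonal rule, so adjacent prisms share quad diagonals
prismToTets <- function(bot, top, colId) {
  o <- order(colId)
  b <- bot[o]; t <- top[o]
  rbind(c(b[1], b[2], b[3], t[3]),
        c(b[1], b[2], t[3], t[2]),
        c(b[1], t[2], t[3], t[1]))
}

#' Build a conforming bilayer tetrahedral mesh
#'
#' Discretises the cortical shell between the pial and white surfaces and
#' the white-matter interior into tetrahedra sharing nodes and faces across
#' the gray-white interface. The mesh is built by radial extrusion: layered
#' copies of the pial triangulation span the cortex (layer count
#' ceil(thickness/targetEdge), at least 2), graded shells fill the white
#' interior, and a central vertex closes the core. Each cortex element
#' stores the referential outward pial normal of its column.
#'
#' @param pial closed outward-oriented pial \linkS4class{SurfaceMesh}.
#' @param white white-matter surface strictly inside \code{pial}. Must have
#'   the same connectivity as \code{pial} (as produced by
#'   \code{\link{inwardOffset}}); otherwise it is resampled onto it.
#' @param targetEdge target element size in mm.
#' @param nCortexLayers optional override of the cortical layer count.
#' @return a \linkS4class{BilayerTetMesh}.
#' @export
buildBilayer <- function(pial, white, targetEdge, nCortexLayers = NULL) {
  vp <- vertices(pial)
  f <- faces(pial)
  if (nVertices(white) != nVertices(pial) ||
      !identical(dim(faces(white)), dim(f))) {
    white <- isotropicRemesh(white, targetEdge) # fallback: resample
    if (nVertices(white) != nVertices(pial))
      stop("white surface must share the pial connectivity")
  }
  vw <- vertices(white)
  thick <- sqrt(rowSums((vp - vw)^2))
  if (any(thick <= 0)) stop("white surface touches the pial surface")
  # verify white is inside pial (along the offset direction)
  ctr <- colMeans(vp)
  if (mean(sqrt(rowSums(sweep(vw, 2, ctr, `-`)^2))) >=
      mean(sqrt(rowSums(sweep(vp, 2, ctr, `-`)^2))))
    stop("white surface must lie strictly inside the pial surface")

  nCtx <- if (is.null(nCortexLayers))
    max(2L, as.integer(ceiling(stats::median(thick) / targetEdge)))
  else as.integer(nCortexLayers)

  nv <- nrow(vp)
  shells <- list()
  # cortex shells: pial (s=0) to white (s=nCtx)
  for (s in 0:nCtx) shells[[length(shells) + 1]] <-
      vp + (s / nCtx) * (vw - vp)
  nShellCtx <- length(shells) # nCtx + 1
  # white interior: graded radial shells from the white surface toward centre
  dirIn <- sweep(vw, 2, ctr, `-`)
  rw <- sqrt(rowSums(dirIn^2))
  step0 <- targetEdge
  fracs <- c()
  rem <- 1
  stepFrac <- step0 / stats::median(rw)
  while (rem - stepFrac > 0.25) {
    rem <- rem - stepFrac
    fracs <- c(fracs, rem)
    stepFrac <- stepFrac * 1.5
  }
  for (fr in fracs) shells[[length(shells) + 1]] <-
      sweep(dirIn * fr, 2, ctr, `+`)
  nShell <- length(shells)
  nodes <- do.call(rbind, shells)
  centerId <- nrow(nodes) + 1L
  nodes <- rbind(nodes, ctr)

  colId <- seq_len(nv) # column identity = pial vertex index
  tl <- vector("list", nShell) # per-layer tet blocks
  regl <- vector("list", nShell)
  for (s in seq_len(nShell - 1)) {
    off0 <- (s - 1) * nv; off1 <- s * nv
    tets <- matrix(0L, 3 * nrow(f), 4)
    for (i in seq_len(nrow(f))) {
      tri <- f[i, ]
      tets[(3 * i - 2):(3 * i), ] <-
        prismToTets(off1 + tri, off0 + tri, colId[tri])
    }
    tl[[s]] <- tets
    regl[[s]] <- rep(if (s <= nCtx) 1L else 2L, nrow(tets))
  }
  # core fan: innermost shell to centre
  off <- (nShell - 1) * nv
  fan <- cbind(off + f[, 1], off + f[, 3], off + f[, 2], centerId)
  tl[[nShell]] <- fan
  regl[[nShell]] <- rep(2L, nrow(fan))
  tets <- do.call(rbind, tl)
  storage.mode(tets) <- "integer"
  dimnames(tets) <- NULL
  region <- unlist(regl)

  # enforce positive orientation
  vol <- tetVolumes(nodes, tets)
  flip <- vol < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  vol <- abs(vol)
  if (any(vol <= 1e-12))
    stop("bilayer construction produced degenerate tetrahedra")

  # referential pial normal per element (cortex rows); column-averaged
  pn <- vertexNormals(pial)
  n0 <- matrix(0, nrow(tets), 3)
  ctxRows <- which(region == 1L)
  colOf <- ((tets[ctxRows, , drop = FALSE] - 1L) %% nv) + 1L
  nx <- (pn[colOf[, 1], 1] + pn[colOf[, 2], 1] + pn[colOf[, 3], 1] +
           pn[colOf[, 4], 1])
  ny <- (pn[colOf[, 1], 2] + pn[colOf[, 2], 2] + pn[colOf[, 3], 2] +
           pn[colOf[, 4], 2])
  nz <- (pn[colOf[, 1], 3] + pn[colOf[, 2], 3] + pn[colOf[, 3], 3] +
           pn[colOf[, 4], 3])
  nrm <- sqrt(nx^2 + ny^2 + nz^2)
  n0[ctxRows, ] <- cbind(nx, ny, nz) / nrm

  interfaceOff <- nCtx * nv
  new("BilayerTetMesh",
      nodes = nodes, tets = tets, region = as.integer(region),
      pialFaces = f, # shell 0 occupies node ids 1..nv with pial connectivity
      interfaceFaces = f + interfaceOff,
      normal0 = n0,
      pialVertices = seq_len(nv),
      whiteVertices = seq_len(nv) + interfaceOff)
}

#' Uniform tetrahedral cube mesh
#'
#' An n x n x n grid of hexahedra, each split into six tetrahedra sharing
#' the main diagonal (Kuhn split, conforming across cells). Single-material
#' fixture for homogeneous-growth verification; all elements are labelled
#' white matter and there is no pial boundary.
#'
#' @param n cells per edge.
#' @param size edge length of the cube in mm.
#' @return a \linkS4class{BilayerTetMesh} with empty pial data.
#' @export
makeTetCube <- function(n = 4, size = 1) {
  g <- seq(0, size, length.out = n + 1)
  id <- function(i, j, k) i + (n + 1) * (j - 1) + (n + 1)^2 * (k - 1)
  nodes <- as.matrix(expand.grid(x = g, y = g, z = g))
  colnames(nodes) <- NULL
  # Kuhn split: 6 tets along the (0,0,0)-(1,1,1) diagonal
  paths <- rbind(c(1, 2, 4, 8), c(1, 2, 6, 8), c(1, 3, 4, 8),
                 c(1, 3, 7, 8), c(1, 5, 6, 8), c(1, 5, 7, 8))
  tl <- list()
  for (k in seq_len(n)) for (j in seq_len(n)) for (i in seq_len(n)) {
    corner <- c(id(i, j, k), id(i + 1, j, k), id(i, j + 1, k),
                id(i + 1, j + 1, k), id(i, j, k + 1), id(i + 1, j, k + 1),
                id(i, j + 1, k + 1), id(i + 1, j + 1, k + 1))
    tl[[length(tl) + 1]] <- matrix(corner[t(paths)], ncol = 4, byrow = TRUE)
  }
  tets <- do.call(rbind, tl)
  storage.mode(tets) <- "integer"
  dimnames(tets) <- NULL
  vol <- tetVolumes(nodes, tets)
  flip <- vol < 0
  if (any(flip)) tets[flip, c(3, 4)] <- tets[flip, c(4, 3)]
  new("BilayerTetMesh", nodes = nodes, tets = tets,
      region = rep(2L, nrow(tets)),
      pialFaces = matrix(integer(0), 0, 3),
      interfaceFaces = matrix(integer(0), 0, 3),
      normal0 = matrix(0, nrow(tets), 3),
      pialVertices = integer(0), whiteVertices = integer(0))
}

# signed tet volumes
tetVolumes <- function(nodes, tets) {
  a <- nodes[tets[, 1], , drop = FALSE]
  b <- nodes[tets[, 2], , drop = FALSE] - a
  c_ <- nodes[tets[, 3], , drop = FALSE] - a
  d <- nodes[tets[, 4], , drop = FALSE] - a
  rowSums(b * vecCross(c_, d)) / 6
}

#' Extract a boundary surface from a bilayer mesh state
#'
#' @param bilayer a \linkS4class{BilayerTetMesh}.
#' @param nodes optional deformed node positions (defaults to reference).
#' @param which \code{"pial"} or \code{"white"}.
#' @return a \linkS4class{SurfaceMesh} with the shell connectivity.
#' @export
extractSurface <- function(bilayer, nodes = NULL, which = c("pial", "white")) {
  which <- match.arg(which)
  if (is.null(nodes)) nodes <- bilayer@nodes
  ids <- if (which == "pial") bilayer@pialVertices else bilayer@whiteVertices
  fgl <- if (which == "pial") bilayer@pialFaces else bilayer@interfaceFaces
  remap <- integer(nrow(nodes))
  remap[ids] <- seq_along(ids)
  SurfaceMesh(nodes[ids, , drop = FALSE],
              matrix(remap[fgl], ncol = 3))
}
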