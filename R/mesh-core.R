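#' @include AllClasses.R
NULL

#' Construct a SurfaceMesh
#'
#' @param vertices n x 3 numeric matrix of positions in mm.
#' @param faces m x 3 index matrix (1-based), counter-clockwise seen from
#'   outside.
#' @param vertexData optional data.frame of per-vertex scalars.
#' @return a \linkS4class{SurfaceMesh}.
#' @export
SurfaceMesh <- function(vertices, faces, vertexData = data.frame()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  new("SurfaceMesh", vertices = vertices, faces = faces,
      vertexData = vertexData)
}

#' Construct a PitCloud
#'
#' @param positions p x 3 numeric matrix of pit coordinates (mm).
#' @param basinId integer vector of unique basin ids (default 1..p).
#' @param depth numeric vector of pit depths (default 0).
#' @param basinArea numeric vector of basin areas in mm^2 (default 0).
#' @return a \linkS4class{PitCloud}.
#' @export
PitCloud <- function(positions, basinId = NULL, depth = NULL,
                     basinArea = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must have 3 columns")
  storage.mode(positions) <- "double"
  p <- nrow(positions)
  if (is.null(basinId)) basinId <- seq_len(p)
  if (is.null(depth)) depth <- rep(0, p)
  if (is.null(basinArea)) basinArea <- rep(0, p)
  new("PitCloud", positions = positions, basinId = as.integer(basinId),
      depth = as.numeric(depth), basinArea = as.numeric(basinArea))
}

# ---- edge / topology helpers ------------------------------------------------

# directed edges of all faces, m*3 x 2
meshHalfedges <- function(faces) {
  rbind(faces[, c(1, 2), drop = FALSE],
        faces[, c(2, 3), drop = FALSE],
        faces[, c(3, 1), drop = FALSE])
}

# undirected edge key strings
edgeKeys <- function(e) {
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "_")
}

#' Mesh diagnostics
#'
#' Reports whether a mesh is a closed, consistently oriented 2-manifold:
#' every undirected edge must be shared by exactly two faces, and appear once
#' in each direction.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return list with logicals \code{closed}, \code{manifold},
#'   \code{oriented}, and counts \code{nVertices}, \code{nFaces},
#'   \code{nEdges}.
#' @export
meshDiagnostics <- function(mesh) {
  f <- faces(mesh)
  if (nrow(f) == 0)
    return(list(closed = FALSE, manifold = FALSE, oriented = FALSE,
                nVertices = nVertices(mesh), nFaces = 0L, nEdges = 0L))
  he <- meshHalfedges(f)
  keys <- edgeKeys(he)
  cnt <- table(keys)
  edgeManifold <- all(cnt <= 2)
  closed <- all(cnt == 2)
  # orientation: each directed edge occurs at most once and, when closed,
  # its reverse occurs exactly once
  dkeys <- paste(he[, 1], he[, 2], sep = "_")
  oriented <- !anyDuplicated(dkeys) && closed
  # vertex manifoldness: the faces around each vertex must form a single
  # edge-connected fan (catches e.g. two tetrahedra glued at one vertex)
  vertexManifold <- TRUE
  if (edgeManifold) {
    nf <- nrow(f)
    vf <- split(rep(seq_len(nf), 3), as.vector(f))
    for (v in names(vf)) {
      fs <- vf[[v]]
      if (length(fs) <= 1) next
      # opposite edge endpoints of v in each incident face
      opp <- lapply(fs, function(fi) setdiff(f[fi, ], as.integer(v)))
      comp <- seq_along(fs)
      for (a in seq_along(fs)) for (b in seq_along(fs)) {
        if (a < b && length(intersect(opp[[a]], opp[[b]])) > 0) {
          ca <- comp[a]; cb <- comp[b]
          comp[comp == cb] <- ca
        }
      }
      if (length(unique(comp)) > 1) { vertexManifold <- FALSE; break }
    }
  }
  list(closed = closed, manifold = edgeManifold && vertexManifold,
       oriented = isTRUE(oriented),
       nVertices = nVertices(mesh), nFaces = nrow(f),
       nEdges = length(cnt))
}

#' Edge lengths of a mesh
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return numeric vector of unique undirected edge lengths (mm).
#' @export
edgeLengths <- function(mesh) {
  f <- faces(mesh); v <- vertices(mesh)
  he <- meshHalfedges(f)
  keep <- he[, 1] < he[, 2]
  e <- he[keep, , drop = FALSE]
  e <- e[!duplicated(edgeKeys(e)), , drop = FALSE]
  sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2))
}

#' Face areas, total surface area and enclosed volume
#'
#' Enclosed volume uses the divergence theorem on the outward-oriented
#' surface.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return \code{faceAreas}: numeric vector; \code{surfaceArea},
#'   \code{enclosedVolume}: scalars.
#' @export
faceAreas <- function(mesh) {
  v <- vertices(mesh); f <- faces(mesh)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cr <- vecCross(b - a, c_ - a)
  0.5 * sqrt(rowSums(cr^2))
}

#' @rdname faceAreas
#' @export
surfaceArea <- function(mesh) sum(faceAreas(mesh))

#' @rdname faceAreas
#' @export
enclosedVolume <- function(mesh) {
  v <- vertices(mesh); f <- faces(mesh)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(rowSums(a * vecCross(b, c_))) / 6
}

vecCross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Area-weighted outward vertex normals
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return n x 3 matrix of unit normals.
#' @export
vertexNormals <- function(mesh) {
  v <- vertices(mesh); f <- faces(mesh)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  fn <- vecCross(b - a, c_ - a) # area-weighted face normal (2A n)
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- tapply(fn[, d], f[, k], sum)
      idx <- as.integer(names(acc))
      n[idx, d] <- n[idx, d] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# sparse vertex adjacency (undirected) as a dgCMatrix
vertexAdjacency <- function(mesh) {
  f <- faces(mesh)
  he <- meshHalfedges(f)
  n <- nVertices(mesh)
  Matrix::sparseMatrix(i = c(he[, 1], he[, 2]), j = c(he[, 2], he[, 1]),
                       x = 1, dims = c(n, n), use.last.ij = TRUE)
}

# neighbor index list
vertexNeighbors <- function(mesh) {
  A <- vertexAdjacency(mesh)
  ap <- A@p; ai <- A@i
  lapply(seq_len(ncol(A)), function(j) {
    if (ap[j + 1] > ap[j]) ai[(ap[j] + 1):ap[j + 1]] + 1L else integer(0)
  })
}

#' Cotangent Laplacian and lumped mass matrix
#'
#' Discrete Laplace-Beltrami stiffness with cotangent weights (positive
#' semi-definite convention: L = D - W) and barycentric lumped vertex mass
#' (one third of incident triangle areas).
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return list with sparse \code{L} (stiffness) and \code{mass} vector
#'   (vertex areas, mm^2).
#' @export
cotanLaplacian <- function(mesh) {
  v <- vertices(mesh); f <- faces(mesh)
  n <- nrow(v)
  i1 <- f[, 1]; i2 <- f[, 2]; i3 <- f[, 3]
  p1 <- v[i1, , drop = FALSE]; p2 <- v[i2, , drop = FALSE]
  p3 <- v[i3, , drop = FALSE]
  cotOf <- function(a, b) { # cot of angle between vectors a, b (rows)
    cr <- sqrt(rowSums(vecCross(a, b)^2))
    rowSums(a * b) / pmax(cr, 1e-300)
  }
  c1 <- cotOf(p2 - p1, p3 - p1) # angle at vertex 1, opposite edge (2,3)
  c2 <- cotOf(p1 - p2, p3 - p2)
  c3 <- cotOf(p1 - p3, p2 - p3)
  ii <- c(i2, i3, i1, i3, i1, i2)
  jj <- c(i3, i2, i3, i1, i2, i1)
  ww <- 0.5 * c(c1, c1, c2, c2, c3, c3)
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  L <- Matrix::Diagonal(x = Matrix::rowSums(W)) - W
  ar <- faceAreas(mesh)
  mass <- numeric(n)
  for (k in 1:3) {
    acc <- tapply(ar / 3, f[, k], sum)
    idx <- as.integer(names(acc))
    mass[idx] <- mass[idx] + acc
  }
  list(L = L, mass = mass)
}

# mixed Voronoi vertex areas (Voronoi area inside non-obtuse triangles,
# area/2 at the obtuse corner and area/4 elsewhere otherwise)
mixedVoronoiArea <- function(mesh) {
  v <- vertices(mesh); f <- faces(mesh)
  n <- nrow(v)
  area <- numeric(n)
  tri <- list(v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
              v[f[, 3], , drop = FALSE])
  ar <- faceAreas(mesh)
  cotAt <- function(a, b, c_) { # cot of angle at a
    u <- b - a; w <- c_ - a
    rowSums(u * w) / pmax(sqrt(rowSums(vecCross(u, w)^2)), 1e-300)
  }
  ct <- cbind(cotAt(tri[[1]], tri[[2]], tri[[3]]),
              cotAt(tri[[2]], tri[[3]], tri[[1]]),
              cotAt(tri[[3]], tri[[1]], tri[[2]]))
  l2 <- cbind(rowSums((tri[[2]] - tri[[3]])^2), # edge opposite corner 1
              rowSums((tri[[3]] - tri[[1]])^2),
              rowSums((tri[[1]] - tri[[2]])^2))
  obtuse <- ct < 0
  anyObt <- rowSums(obtuse) > 0
  contrib <- matrix(0, nrow(f), 3)
  # non-obtuse: Voronoi area at corner k = 1/8 (l_j^2 cot_j + l_i^2 cot_i)
  for (k in 1:3) {
    o1 <- (k %% 3) + 1; o2 <- ((k + 1) %% 3) + 1
    contrib[, k] <- (l2[, o1] * ct[, o1] + l2[, o2] * ct[, o2]) / 8
  }
  for (k in 1:3) {
    contrib[anyObt, k] <- ifelse(obtuse[anyObt, k], ar[anyObt] / 2,
                                 ar[anyObt] / 4)
  }
  for (k in 1:3) {
    acc <- tapply(contrib[, k], f[, k], sum)
    idx <- as.integer(names(acc))
    area[idx] <- area[idx] + acc
  }
  area
}

#' Per-vertex mean curvature
#'
#' Mean curvature from the discrete mean-curvature normal
#' (cotangent-weighted Laplacian of the positions divided by twice the
#' mixed Voronoi vertex area), signed so that convex regions (sphere) are
#' positive.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return numeric vector of H in 1/mm.
#' @export
meanCurvature <- function(mesh) {
  lm <- cotanLaplacian(mesh)
  hn <- as.matrix(lm$L %*% vertices(mesh)) / (2 * mixedVoronoiArea(mesh))
  nrm <- vertexNormals(mesh)
  h <- sqrt(rowSums(hn^2))
  sgn <- sign(rowSums(hn * nrm))
  sgn[sgn == 0] <- 1
  h * sgn
}

#' Geodesic distances on a surface mesh
#'
#' First-order fast marching with a planar virtual-source triangle update;
#' on well-shaped meshes the error against closed-form sphere geodesics is
#' well under 2 percent.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param sources integer vector of source vertex indices.
#' @return numeric vector of per-vertex geodesic distances (mm).
#' @export
geodesicDistance <- function(mesh, sources) {
  if (length(sources) < 1) stop("at least one source vertex required")
  sources <- as.integer(sources)
  if (any(sources < 1 | sources > nVertices(mesh)))
    stop("source vertex index out of range")
  cpp_geodesic_fmm(vertices(mesh), faces(mesh), sources)
}
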