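#' @include mesh-core.R
NULL

#' Depth potential function
#'
#' Reference-free sulcal depth: the regularized (screened Poisson) problem
#' on the surface
#'   (alpha * Mt + L) d = Mt b,   Mt = M / A,   b = 2 (Hbar - H) sqrt(A) g,
#' with L the cotangent Laplace-Beltrami stiffness, M the lumped vertex
#' mass, H the mean curvature (area-weighted mean Hbar) and A the total
#' surface area. Both the normalised mass Mt and the load b are invariant
#' under uniform rescaling of the brain, so the depth map is exactly
#' independent of brain size; alpha (default 0.03) controls the trade-off
#' between mean curvature and average convexity. The fixed calibration
#' gain g makes DPF values approximate geometric sulcal depth in
#' millimetres on fetal-scale folded geometry, keeping the published
#' watershed thresholds (ridge height 1.5) on their intended scale.
#' Sign convention: concave (sulcal) regions are positive, so pits are
#' depth maxima.
#'
#' @param mesh closed manifold \linkS4class{SurfaceMesh}.
#' @param alpha regularization parameter (> 0).
#' @param gain depth-calibration constant (dimensionless).
#' @return list with \code{depth} (per-vertex, DPF units) and \code{alpha}.
#' @export
dpf <- function(mesh, alpha = 0.03, gain = 50) {
  if (alpha <= 0) stop("alpha must be positive")
  lm <- cotanLaplacian(mesh)
  Atot <- sum(lm$mass)
  H <- meanCurvature(mesh)
  Hbar <- sum(H * lm$mass) / Atot
  b <- 2 * (Hbar - H) * sqrt(Atot) * gain
  mt <- lm$mass / Atot
  Amat <- lm$L + Matrix::Diagonal(x = alpha * mt)
  d <- tryCatch(
    as.numeric(Matrix::solve(Amat, mt * b)),
    error = function(e) stop("singular DPF system (disconnected mesh?): ",
                             conditionMessage(e)))
  if (any(!is.finite(d))) stop("DPF solution not finite")
  list(depth = d, alpha = alpha)
}

#' Watershed-by-flooding basin segmentation
#'
#' Floods the depth map from its maxima: vertices are processed in order of
#' decreasing depth; a vertex joins the basin of its deepest
#' already-labelled neighbour, founds a new basin when it has none, and is
#' a ridge vertex when its neighbours span two or more basins. At a ridge
#' the two basins merge iff the ridge height R (the smaller of the two pit
#' depths minus the ridge-vertex depth) is below \code{thrR} and the
#' distance between the two pits is below \code{thrD}. After flooding,
#' every basin with area below \code{thrA} merges into the neighbour
#' sharing the longest common border, iterated to a fixpoint.
#'
#' Defaults follow the published thresholds: thrR = 1.5, thrD = 20,
#' thrA = 50.
#'
#' @param mesh the surface carrying the depth map.
#' @param depth per-vertex depth (pits = maxima), or the list returned by
#'   \code{\link{dpf}}.
#' @param thrR ridge-height merge threshold (depth units).
#' @param thrD pit-distance merge threshold (mm).
#' @param thrA minimal basin area (mm^2).
#' @param distance \code{"geodesic"} (along the surface; default) or
#'   \code{"euclidean"} pit-to-pit distance for the thrD rule.
#' @return a \linkS4class{BasinSegmentation}.
#' @export
watershedByFlooding <- function(mesh, depth, thrR = 1.5, thrD = 20,
                                thrA = 50, distance = c("geodesic",
                                                        "euclidean")) {
  distance <- match.arg(distance)
  if (is.list(depth)) depth <- depth$depth
  nv <- nVertices(mesh)
  if (length(depth) != nv) stop("depth must be defined on every vertex")
  if (any(!is.finite(depth))) stop("depth must be finite")
  if (min(thrR, thrD, thrA) <= 0) stop("thresholds must be positive")
  emptySeg <- function() new("BasinSegmentation",
      labels = integer(nv), pitVertex = integer(0), basinArea = numeric(0),
      ridges = data.frame(basin1 = integer(0), basin2 = integer(0),
                          ridgeVertex = integer(0),
                          ridgeHeight = numeric(0)),
      mergeLog = data.frame(from = integer(0), into = integer(0),
                            reason = character(0)),
      basinIds = integer(0))
  rng <- diff(range(depth))
  if (rng < 1e-12 * max(1, max(abs(depth)))) {
    warning("constant depth map: no pits")
    return(emptySeg())
  }
  nbr <- vertexNeighbors(mesh)
  v <- vertices(mesh)

  # canonical processing order: depth descending, index ascending on ties
  ord <- order(-depth, seq_len(nv))

  # union-find over basins
  parent <- integer(0)
  pitV <- integer(0)
  findRoot <- function(b) {
    while (parent[b] != b) {
      parent[b] <<- parent[parent[b]]
      b <- parent[b]
    }
    b
  }

  geoCache <- new.env(hash = TRUE, parent = emptyenv())
  pitDist <- function(p1, p2) {
    if (distance == "euclidean")
      return(sqrt(sum((v[p1, ] - v[p2, ])^2)))
    key <- as.character(p1)
    dfield <- geoCache[[key]]
    if (is.null(dfield)) {
      dfield <- cpp_geodesic_fmm(v, faces(mesh), p1)
      geoCache[[key]] <- dfield
    }
    dfield[p2]
  }

  labels <- integer(nv)
  ridgeRec <- list()
  mergeRec <- list()

  for (vx in ord) {
    nb <- nbr[[vx]]
    lab <- labels[nb]
    lab <- lab[lab > 0L]
    if (!length(lab)) {
      # new basin seeded at a local maximum of the flooded region
      parent[length(parent) + 1L] <- length(parent) + 1L
      pitV[length(parent)] <- vx
      labels[vx] <- length(parent)
      next
    }
    roots <- unique(vapply(lab, findRoot, integer(1)))
    # join the basin whose pit is deepest
    best <- roots[which.max(depth[pitV[roots]])]
    labels[vx] <- best
    if (length(roots) > 1L) {
      # ridge vertex: try pairwise merges with the dominant basin
      for (other in setdiff(roots, best)) {
        b1 <- findRoot(best); b2 <- findRoot(other)
        if (b1 == b2) next
        R <- min(depth[pitV[b1]], depth[pitV[b2]]) - depth[vx]
        ridgeRec[[length(ridgeRec) + 1L]] <-
          c(b1, b2, vx, R)
        if (R < thrR) {
          D <- pitDist(pitV[b1], pitV[b2])
          if (D < thrD) {
            # merge shallower-pit basin into deeper
            into <- if (depth[pitV[b1]] >= depth[pitV[b2]]) b1 else b2
            from <- if (into == b1) b2 else b1
            parent[from] <- into
            mergeRec[[length(mergeRec) + 1L]] <- list(from, into, "ridge")
          }
        }
      }
    }
  }

  labels <- vapply(labels, findRoot, integer(1))

  # vertex areas
  lm <- cotanLaplacian(mesh)
  va <- lm$mass

  # small-basin area merges: into the neighbour with the longest shared
  # border (sum of crossing edge lengths), iterated to fixpoint
  he <- meshHalfedges(faces(mesh))
  keep <- he[, 1] < he[, 2]
  edges <- he[keep, , drop = FALSE]
  edges <- edges[!duplicated(edgeKeys(edges)), , drop = FALSE]
  elen <- sqrt(rowSums((v[edges[, 1], , drop = FALSE] -
                          v[edges[, 2], , drop = FALSE])^2))
  repeat {
    ids <- sort(unique(labels))
    areas <- vapply(ids, function(b) sum(va[labels == b]), numeric(1))
    small <- ids[areas < thrA]
    if (!length(small) || length(ids) == 1L) break
    # smallest basin first
    b <- small[which.min(areas[match(small, ids)])]
    l1 <- labels[edges[, 1]]; l2 <- labels[edges[, 2]]
    crossE <- (l1 == b & l2 != b) | (l2 == b & l1 != b)
    if (!any(crossE)) break
    nbLab <- ifelse(l1[crossE] == b, l2[crossE], l1[crossE])
    border <- tapply(elen[crossE], nbLab, sum)
    target <- as.integer(names(border)[which.max(border)])
    labels[labels == b] <- target
    mergeRec[[length(mergeRec) + 1L]] <- list(b, target, "area")
  }

  ids <- sort(unique(labels))
  pitVertex <- vapply(ids, function(b) {
    vb <- which(labels == b)
    vb[which.max(depth[vb])]
  }, integer(1))
  areas <- vapply(ids, function(b) sum(va[labels == b]), numeric(1))

  ridges <- if (length(ridgeRec)) {
    m <- do.call(rbind, ridgeRec)
    data.frame(basin1 = as.integer(m[, 1]), basin2 = as.integer(m[, 2]),
               ridgeVertex = as.integer(m[, 3]), ridgeHeight = m[, 4])
  } else data.frame(basin1 = integer(0), basin2 = integer(0),
                    ridgeVertex = integer(0), ridgeHeight = numeric(0))
  mergeLog <- if (length(mergeRec)) {
    data.frame(from = vapply(mergeRec, function(x) as.integer(x[[1]]),
                             integer(1)),
               into = vapply(mergeRec, function(x) as.integer(x[[2]]),
                             integer(1)),
               reason = vapply(mergeRec, function(x) x[[3]], character(1)))
  } else data.frame(from = integer(0), into = integer(0),
                    reason = character(0))

  new("BasinSegmentation", labels = labels, pitVertex = pitVertex,
      basinArea = areas, ridges = ridges, mergeLog = mergeLog,
      basinIds = as.integer(ids))
}

#' Extract sulcal pits from a basin segmentation
#'
#' One pit per basin, at the basin's depth-maximal vertex, carrying the
#' basin id, the pit depth and the basin area.
#'
#' @param segmentation a \linkS4class{BasinSegmentation}.
#' @param mesh the surface the segmentation was computed on.
#' @param depth the depth map used (vector or \code{\link{dpf}} result).
#' @return a \linkS4class{PitCloud}.
#' @export
extractPits <- function(segmentation, mesh, depth) {
  if (is.list(depth)) depth <- depth$depth
  pv <- segmentation@pitVertex
  if (!length(pv)) stop("empty segmentation: no pits to extract")
  PitCloud(vertices(mesh)[pv, , drop = FALSE],
           basinId = segmentation@basinIds,
           depth = depth[pv],
           basinArea = segmentation@basinArea)
}

#' Run the full pit-extraction pipeline on a surface
#'
#' Convenience wrapper: DPF depth map, watershed basins, pit extraction.
#'
#' @param mesh white-matter \linkS4class{SurfaceMesh}.
#' @param alpha DPF regularization.
#' @param thrR,thrD,thrA watershed thresholds (see
#'   \code{\link{watershedByFlooding}}).
#' @param distance pit-distance metric.
#' @return list with \code{pits} (\linkS4class{PitCloud}),
#'   \code{segmentation} and \code{depth}.
#' @export
extractPitsFromSurface <- function(mesh, alpha = 0.03, thrR = 1.5,
                                   thrD = 20, thrA = 50,
                                   distance = "geodesic") {
  d <- dpf(mesh, alpha)
  seg <- watershedByFlooding(mesh, d, thrR, thrD, thrA, distance)
  if (!length(seg@pitVertex))
    return(list(pits = PitCloud(matrix(numeric(0), 0, 3)),
                segmentation = seg, depth = d))
  list(pits = extractPits(seg, mesh, d), segmentation = seg, depth = d)
}
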