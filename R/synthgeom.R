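#' @include mesh-core.R
NULL

# run expr with a local RNG state seeded by `seed`
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# ---- geodesic sphere --------------------------------------------------------

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  # enforce outward orientation
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c_ <- v[f[i, 3], ]
    n <- c((b - a)[2] * (c_ - a)[3] - (b - a)[3] * (c_ - a)[2],
           (b - a)[3] * (c_ - a)[1] - (b - a)[1] * (c_ - a)[3],
           (b - a)[1] * (c_ - a)[2] - (b - a)[2] * (c_ - a)[1])
    if (sum(n * (a + b + c_)) < 0) f[i, ] <- f[i, c(1, 3, 2)]
  }
  list(vertices = v, faces = f)
}

#' Geodesic sphere mesh
#'
#' Frequency-n subdivision of the icosahedron projected to the unit sphere:
#' each icosahedral edge is divided into \code{freq} segments, giving
#' 20*freq^2 near-equilateral triangles (10*freq^2 + 2 vertices), then scaled
#' by \code{radius}.
#'
#' @param radius sphere radius (mm).
#' @param freq subdivision frequency (positive integer).
#' @return a \linkS4class{SurfaceMesh}.
#' @export
geodesicSphere <- function(radius = 1, freq = 8) {
  freq <- as.integer(freq)
  if (freq < 1) stop("freq must be >= 1")
  ico <- icosahedron()
  keyOf <- function(face, i, j, k) {
    w <- c(i, j, k); cs <- face
    use <- w > 0
    ord <- order(cs[use])
    paste(cs[use][ord], w[use][ord], sep = ":", collapse = "|")
  }
  vmap <- new.env(hash = TRUE, parent = emptyenv())
  verts <- list(); nv <- 0L
  getVert <- function(face, i, j, k) {
    key <- keyOf(face, i, j, k)
    id <- vmap[[key]]
    if (!is.null(id)) return(id)
    p <- (i * ico$vertices[face[1], ] + j * ico$vertices[face[2], ] +
          k * ico$vertices[face[3], ]) / freq
    p <- p / sqrt(sum(p^2))
    nv <<- nv + 1L
    verts[[nv]] <<- p
    vmap[[key]] <- nv
    nv
  }
  fl <- vector("list", 20L * freq^2)
  nf <- 0L
  for (t in seq_len(nrow(ico$faces))) {
    face <- ico$faces[t, ]
    # rows indexed by i (weight of corner 1) descending
    idx <- matrix(0L, freq + 1, freq + 1)
    for (i in 0:freq) for (j in 0:(freq - i)) {
      idx[i + 1, j + 1] <- getVert(face, i, j, freq - i - j)
    }
    for (i in 0:(freq - 1)) for (j in 0:(freq - 1 - i)) {
      nf <- nf + 1L
      fl[[nf]] <- c(idx[i + 2, j + 1], idx[i + 1, j + 2], idx[i + 1, j + 1])
      if (j < freq - 1 - i) {
        nf <- nf + 1L
        fl[[nf]] <- c(idx[i + 2, j + 1], idx[i + 2, j + 2], idx[i + 1, j + 2])
      }
    }
  }
  v <- do.call(rbind, verts) * radius
  f <- do.call(rbind, fl[seq_len(nf)])
  m <- SurfaceMesh(v, f)
  # fix orientation if the subdivision scheme flipped it
  if (enclosedVolume(m) < 0) m@faces <- m@faces[, c(1, 3, 2)]
  m
}

# ---- synthetic brain --------------------------------------------------------

#' Specification of a synthetic brain-like surface
#'
#' @param semiAxes 3-vector of ellipsoid semi-axes in mm (fetal hemisphere
#'   scale, roughly 30-45 mm).
#' @param undulationModes list of c(frequency, amplitude_mm) pairs defining
#'   smooth primary-fold-like radial undulations.
#' @param corticalThickness cortical layer thickness in mm (default 1.4).
#' @param targetEdgeLength target triangle edge length in mm.
#' @param seed integer seed fixing all randomness.
#' @return a list of class \code{SyntheticBrainSpec}.
#' @export
syntheticBrainSpec <- function(semiAxes = c(40, 33, 28),
                               undulationModes = list(c(3, 2.5), c(5, 1.5)),
                               corticalThickness = 1.4,
                               targetEdgeLength = 1.5,
                               seed = 1L) {
  amps <- vapply(undulationModes, function(m) m[2], numeric(1))
  if (length(amps) && max(amps) >= min(semiAxes) / 4)
    stop("undulation amplitudes must stay below min(semiAxes)/4 ",
         "(embedding invariant)")
  structure(list(semiAxes = as.numeric(semiAxes),
                 undulationModes = undulationModes,
                 corticalThickness = corticalThickness,
                 targetEdgeLength = targetEdgeLength,
                 seed = as.integer(seed)),
            class = "SyntheticBrainSpec")
}

# smooth radial undulation field over unit directions; deterministic in seed
undulationField <- function(dirs, modes, seed) {
  g <- numeric(nrow(dirs))
  if (!length(modes)) return(g)
  withSeed(seed, {
    for (m in modes) {
      freq <- m[1]; amp <- m[2]
      for (t in 1:3) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        ph <- stats::runif(1, 0, 2 * pi)
        ang <- acos(pmin(1, pmax(-1, dirs %*% u)))
        g <- g + (amp / 3) * cos(freq * ang + ph)
      }
    }
  })
  g
}

#' Generate a smooth brain-like surface
#'
#' Builds a closed genus-0 triangle mesh: a geodesic sphere mapped to the
#' requested ellipsoid, with spherical-harmonic-style radial undulations
#' emulating primary folds. Deterministic given the spec seed.
#'
#' @param spec a \code{\link{syntheticBrainSpec}}.
#' @return a \linkS4class{SurfaceMesh}.
#' @export
makeSmoothBrain <- function(spec) {
  stopifnot(inherits(spec, "SyntheticBrainSpec"))
  ax <- spec$semiAxes
  rMean <- prod(ax)^(1 / 3)
  freq <- max(1L, as.integer(round(1.10715 * rMean / spec$targetEdgeLength)))
  sph <- geodesicSphere(1, freq)
  dirs <- vertices(sph)
  p <- sweep(dirs, 2, ax, `*`)
  g <- undulationField(dirs, spec$undulationModes, spec$seed)
  if (any(abs(g) > 0)) {
    r <- sqrt(rowSums(p^2))
    p <- p * (1 + g / r)
  }
  SurfaceMesh(p, faces(sph))
}

# ---- pit-cloud cohorts ------------------------------------------------------

randomRotation <- function(maxAngleDeg) {
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  ang <- stats::runif(1, 0, maxAngleDeg * pi / 180)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

samplePitsShell <- function(n, semiAxes, shell = c(0.85, 1.0)) {
  d <- matrix(stats::rnorm(3 * n), n, 3)
  d <- d / sqrt(rowSums(d^2))
  r <- stats::runif(n, shell[1], shell[2])
  sweep(d, 2, semiAxes, `*`) * r
}

applyHalfAxisScale <- function(p, factors) {
  # factors: fx+, fx-, fy+, fy-, fz+, fz-
  out <- p
  for (ax in 1:3) {
    fp <- factors[2 * ax - 1]; fm <- factors[2 * ax]
    pos <- p[, ax] >= 0
    out[pos, ax] <- p[pos, ax] * fp
    out[!pos, ax] <- p[!pos, ax] * fm
  }
  out
}

#' Generate a two-timepoint synthetic pit-cloud cohort
#'
#' Emulates longitudinal growth of sulcal-pit configurations: the
#' second-timepoint cloud of each subject is its first-timepoint cloud under
#' anisotropic per-half-axis scaling (six independent factors), a small rigid
#' motion, isotropic Gaussian positional jitter, and newly born pits placed
#' near existing inter-pit boundaries. All brains share the anatomical origin.
#' Ground-truth correspondences and the applied transform are recorded.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param nPitsRange integer range for the first-timepoint pit count
#'   (default 30-60, emulating per-hemisphere sulcal-pit counts of
#'   later-gestation fetal brains).
#' @param scaleRange range of the six half-axis growth factors.
#' @param jitterSd isotropic positional jitter sd in mm.
#' @param maxRotationDeg upper bound of the random rigid rotation angle.
#'   Longitudinal scans are registered to a common atlas space with a shared
#'   anatomical origin, so the residual rigid motion between timepoints is
#'   small (default 3 degrees).
#' @param maxTranslation upper bound (mm) of each translation component
#'   (default 1 mm, residual atlas-registration error).
#' @param birthFraction fraction of new pits born at the second timepoint.
#' @param birthNearBoundaries place new pits near midpoints between existing
#'   pits (emulating secondary sulci branching); otherwise uniform in shell.
#' @param semiAxes brain-scale ellipsoid semi-axes in mm.
#' @param seed integer seed.
#' @return list of subjects; each has \code{pitsT0}, \code{pitsT1}
#'   (\linkS4class{PitCloud}s), \code{truthPairs} (k x 2 index matrix) and
#'   \code{growthTruth} (factors, rotation, translation, jitterSd).
#' @export
makePitCloudCohort <- function(nSubjects, nPitsRange = c(30, 60),
                               scaleRange = c(1.1, 1.5), jitterSd = 1,
                               maxRotationDeg = 3, maxTranslation = 1,
                               birthFraction = 0.2,
                               birthNearBoundaries = TRUE,
                               semiAxes = c(40, 33, 28), seed = 1L) {
  if (nSubjects < 2) stop("nSubjects must be >= 2")
  if (nPitsRange[1] > nPitsRange[2] || nPitsRange[1] < 1)
    stop("degenerate nPitsRange")
  withSeed(seed, {
    lapply(seq_len(nSubjects), function(s) {
      n0 <- sample(nPitsRange[1]:nPitsRange[2], 1)
      p0 <- samplePitsShell(n0, semiAxes)
      factors <- stats::runif(6, scaleRange[1], scaleRange[2])
      R <- if (maxRotationDeg > 0) randomRotation(maxRotationDeg) else diag(3)
      tr <- if (maxTranslation > 0)
        stats::runif(3, -maxTranslation, maxTranslation) else numeric(3)
      p1 <- applyHalfAxisScale(p0, factors)
      p1 <- p1 %*% t(R)
      p1 <- sweep(p1, 2, tr, `+`)
      if (jitterSd > 0)
        p1 <- p1 + matrix(stats::rnorm(length(p1), 0, jitterSd), nrow(p1), 3)
      nNew <- round(birthFraction * n0)
      if (nNew > 0) {
        if (birthNearBoundaries && n0 >= 2) {
          newPits <- t(vapply(seq_len(nNew), function(i) {
            a <- sample(n0, 1)
            d2 <- rowSums(sweep(p1[seq_len(n0), , drop = FALSE], 2,
                                p1[a, ], `-`)^2)
            d2[a] <- Inf
            b <- which.min(d2)
            mid <- (p1[a, ] + p1[b, ]) / 2
            mid + stats::rnorm(3, 0, max(jitterSd, 1))
          }, numeric(3)))
        } else {
          newPits <- applyHalfAxisScale(samplePitsShell(nNew, semiAxes),
                                        factors)
          newPits <- sweep(newPits %*% t(R), 2, tr, `+`)
        }
        p1 <- rbind(p1, newPits)
      }
      list(pitsT0 = PitCloud(p0),
           pitsT1 = PitCloud(p1),
           truthPairs = cbind(seq_len(n0), seq_len(n0)),
           growthTruth = list(factors = factors, rotation = R,
                              translation = tr, jitterSd = jitterSd))
    })
  })
}

# ---- depth phantom ----------------------------------------------------------

#' Spherical depth phantom with known basins
#'
#' A geodesic sphere carrying an analytic depth field built as a sum of
#' localized Gaussian bumps with prescribed pit depths and saddle (ridge)
#' depths, plus ground-truth basin labels (dominant bump) and ridge heights.
#' Used to validate watershed basin extraction.
#'
#' @param nBasins number of bumps/basins (0 gives a constant zero field).
#' @param pitDepths per-basin peak depth (recycled).
#' @param ridgeDepths target saddle depth between adjacent bumps (recycled);
#'   each must be smaller than the adjacent pit depths.
#' @param radius sphere radius in mm.
#' @param freq geodesic-sphere subdivision frequency.
#' @param centers optional k x 3 matrix of unit directions for bump centres
#'   (default: poles for k = 2, Fibonacci points otherwise).
#' @param seed integer seed (kept for interface symmetry; the phantom is
#'   fully deterministic).
#' @return list with \code{mesh} (\linkS4class{SurfaceMesh}), \code{depth}
#'   (per-vertex), \code{labels} (per-vertex ground truth, 0 when no basin),
#'   \code{pitVertices}, \code{ridgeHeight} (known pit - ridge gap, 2-basin
#'   case) and \code{centers}.
#' @export
makeDepthPhantom <- function(nBasins, pitDepths = 3, ridgeDepths = 1,
                             radius = 10, freq = 12, centers = NULL,
                             seed = 1L) {
  mesh <- geodesicSphere(radius, freq)
  nv <- nVertices(mesh)
  if (nBasins == 0) {
    return(list(mesh = mesh, depth = numeric(nv),
                labels = integer(nv), pitVertices = integer(0),
                ridgeHeight = numeric(0), centers = NULL))
  }
  pd <- rep_len(pitDepths, nBasins)
  rd <- rep_len(ridgeDepths, max(1, nBasins - 1))
  if (nBasins >= 2 && any(rep_len(rd, nBasins) >= min(pd)))
    stop("inconsistent depths: ridge depths must be below pit depths")
  if (is.null(centers)) {
    if (nBasins == 1) {
      centers <- matrix(c(0, 0, 1), 1, 3)
    } else if (nBasins == 2) {
      centers <- rbind(c(0, 0, 1), c(0, 0, -1))
    } else {
      i <- seq_len(nBasins)
      ga <- pi * (3 - sqrt(5))
      z <- 1 - (2 * i - 1) / nBasins
      r <- sqrt(pmax(0, 1 - z^2))
      centers <- cbind(r * cos(ga * i), r * sin(ga * i), z)
    }
  }
  centers <- centers / sqrt(rowSums(centers^2))
  dirs <- vertices(mesh) / radius
  cosang <- dirs %*% t(centers)
  ang <- acos(matrix(pmin(1, pmax(-1, cosang)), nrow(dirs))) # nv x k
  if (nBasins == 1) {
    sigma <- pi / 4
  } else {
    cosSep <- tcrossprod(centers)
    diag(cosSep) <- -1
    minAng <- acos(max(cosSep[upper.tri(cosSep) | lower.tri(cosSep)]))
    # saddle midway between two equal bumps: 2 pd exp(-(a/2)^2 / 2 s^2) = rd
    sigma <- sqrt((minAng / 2)^2 / (2 * log(2 * mean(pd) / mean(rd))))
  }
  bumps <- sweep(exp(-ang^2 / (2 * sigma^2)), 2, pd, `*`)
  depth <- rowSums(bumps)
  labels <- max.col(bumps)
  pitVertices <- vapply(seq_len(nBasins), function(k) {
    vk <- which(labels == k)
    vk[which.max(depth[vk])]
  }, integer(1))
  ridgeHeight <- if (nBasins == 2) {
    max(pd) - min(depth[abs(ang[, 1] - ang[, 2]) ==
                          min(abs(ang[, 1] - ang[, 2]))])
  } else numeric(0)
  list(mesh = mesh, depth = depth, labels = as.integer(labels),
       pitVertices = pitVertices, ridgeHeight = ridgeHeight,
       centers = centers)
}
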