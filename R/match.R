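#' @include mesh-core.R
NULL

asPitMatrix <- function(x) {
  if (is(x, "PitCloud")) return(pitPositions(x))
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("pit cloud must be a p x 3 matrix or PitCloud")
  x
}

#' Gaussian-kernel affinity between two pit clouds
#'
#' A(i, j) = exp(-||Pi - Qj||^2 / sigma): squared Euclidean distance scaled
#' by sigma (default 100, distances in mm so sigma is mm^2).
#'
#' @param P,Q pit clouds (\linkS4class{PitCloud} or p x 3 matrices).
#' @param sigma kernel scale (> 0).
#' @return I x J affinity matrix with entries in (0, 1].
#' @export
pitAffinity <- function(P, Q, sigma = 100) {
  P <- asPitMatrix(P); Q <- asPitMatrix(Q)
  if (nrow(P) == 0 || nrow(Q) == 0) stop("empty pit cloud")
  if (sigma <= 0) stop("sigma must be positive")
  d2 <- outer(rowSums(P^2), rowSums(Q^2), `+`) - 2 * tcrossprod(P, Q)
  d2[d2 < 0] <- 0
  exp(-d2 / sigma)
}

# ---- linear assignment (Jonker-Volgenant shortest augmenting path) ----------

# minimizes total cost over one-to-one assignments; rectangular matrices are
# padded. Returns, for each row of the (original) matrix, the assigned column
# (NA for unassigned rows when nrow > ncol).
solveAssignment <- function(cost) {
  n0 <- nrow(cost); m0 <- ncol(cost)
  n <- max(n0, m0)
  big <- max(abs(cost[is.finite(cost)]), 1) * 2 + 1
  C <- matrix(big, n, n)
  C[seq_len(n0), seq_len(m0)] <- cost
  C[!is.finite(C)] <- big
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); vdual <- numeric(n + 1)
  p <- integer(n + 1) # p[j]: row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L # column index + 0 offset; use index 1 as virtual start
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in 2:(n + 1)) {
        if (used[j]) next
        cur <- C[i0, j - 1] - u[i0] - vdual[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          vdual[j] <- vdual[j] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assign <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) assign[p[j]] <- j - 1L
  out <- assign[seq_len(n0)]
  out[out > m0] <- NA_integer_
  if (n0 > m0) {
    # keep only the min(n0, m0) cheapest real assignments
    real <- which(!is.na(out))
    if (length(real) > m0) {
      cst <- cost[cbind(real, out[real])]
      drop <- real[order(cst, decreasing = TRUE)][seq_len(length(real) - m0)]
      out[drop] <- NA_integer_
    }
  }
  out
}

# ---- RRWM -------------------------------------------------------------------

#' Reweighted random walk matching
#'
#' Matches two pit clouds through a reweighted random walk over candidate
#' correspondences. With the Gaussian affinities as node weights, the walk
#' alternates an affinity-weighted propagation step with a reweighting jump
#' (exponential inflation followed by Sinkhorn row/column normalization),
#' mixed by the jump probability, and iterates to a fixed tolerance. The
#' resulting matching matrix M is discretized to a one-to-one matching of
#' size min(I, J) by the Hungarian method on -log M. Optional pairwise
#' geometric-consistency terms exp(-(dP(i,i') - dQ(j,j'))^2 / sigma) can be
#' enabled.
#'
#' @param A I x J affinity matrix (finite, positive), e.g. from
#'   \code{\link{pitAffinity}}.
#' @param jumpProb reweighting jump probability.
#' @param inflation exponent of the reweighting jump.
#' @param sinkhornIter Sinkhorn normalization sweeps per jump.
#' @param tol convergence tolerance on the iterate.
#' @param maxIter maximum iterations.
#' @param pairwise optional list(P = , Q = , sigma = ) enabling the pairwise
#'   consistency walk (off by default).
#' @return list with \code{pairs} (k x 2 matrix), \code{matchMatrix} M and
#'   \code{converged}.
#' @export
rrwmMatch <- function(A, jumpProb = 0.2, inflation = 30, sinkhornIter = 10,
                      tol = 1e-8, maxIter = 300, pairwise = NULL) {
  if (any(!is.finite(A)) || any(A < 0))
    stop("affinity matrix must be finite and non-negative")
  A <- pmax(A, 1e-300) # kernel values can underflow for very distant pits
  I <- nrow(A); J <- ncol(A)
  sinkhorn <- function(M, iters) {
    for (k in seq_len(iters)) {
      M <- M / pmax(rowSums(M), 1e-300)
      M <- t(t(M) / pmax(colSums(M), 1e-300))
    }
    M
  }
  x <- A / sum(A)
  usePair <- !is.null(pairwise)
  if (usePair) {
    P <- asPitMatrix(pairwise$P); Q <- asPitMatrix(pairwise$Q)
    sg <- if (is.null(pairwise$sigma)) 100 else pairwise$sigma
    dP <- as.matrix(stats::dist(P)); dQ <- as.matrix(stats::dist(Q))
  }
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    xOld <- x
    # propagation: unary affinity weighting (plus optional pairwise walk)
    y <- A * x
    if (usePair) {
      # y[i,j] += sum_{i',j'} exp(-(dP[i,i']-dQ[j,j'])^2/sg) x[i',j']
      yp <- matrix(0, I, J)
      for (i2 in seq_len(I)) for (j2 in seq_len(J)) {
        if (x[i2, j2] < 1e-12) next
        w <- exp(-(outer(dP[, i2], dQ[, j2], `-`))^2 / sg)
        yp <- yp + w * x[i2, j2]
      }
      y <- y + yp
    }
    y <- y / sum(y)
    # reweighting jump: inflate and make bistochastic
    z <- exp(inflation * y / max(y))
    z <- sinkhorn(z, sinkhornIter)
    z <- z / sum(z)
    x <- (1 - jumpProb) * y + jumpProb * z
    if (max(abs(x - xOld)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("RRWM did not converge within maxIter; returning best iterate")
  M <- x / max(x)
  cost <- -log(pmax(M, 1e-300))
  if (I <= J) {
    asg <- solveAssignment(cost)
    pairs <- cbind(seq_len(I), asg)
  } else {
    asg <- solveAssignment(t(cost))
    pairs <- cbind(asg, seq_len(J))
  }
  pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
  pairs <- refineDiscreteMatching(A, pairs)
  dimnames(pairs) <- NULL
  list(pairs = pairs, matchMatrix = M, converged = converged)
}

# greedy local refinement of a discrete matching: pair swaps and
# replacements of an assigned row/column by an unassigned one, applied
# while they increase the total affinity (standard post-discretization
# polish; removes artefacts of the soft-assign flattening on tiny
# affinities)
refineDiscreteMatching <- function(A, pairs) {
  I <- nrow(A); J <- ncol(A)
  repeat {
    improved <- FALSE
    k <- nrow(pairs)
    # swap partners of two pairs
    if (k >= 2) {
      for (a in seq_len(k - 1)) for (b in (a + 1):k) {
        cur <- A[pairs[a, 1], pairs[a, 2]] + A[pairs[b, 1], pairs[b, 2]]
        alt <- A[pairs[a, 1], pairs[b, 2]] + A[pairs[b, 1], pairs[a, 2]]
        if (alt > cur + 1e-15) {
          tmp <- pairs[a, 2]; pairs[a, 2] <- pairs[b, 2]; pairs[b, 2] <- tmp
          improved <- TRUE
        }
      }
    }
    # replace an assigned row (or column) by an unassigned one
    freeRows <- setdiff(seq_len(I), pairs[, 1])
    for (a in seq_len(k)) {
      if (!length(freeRows)) break
      cand <- freeRows[which.max(A[freeRows, pairs[a, 2]])]
      if (A[cand, pairs[a, 2]] > A[pairs[a, 1], pairs[a, 2]] + 1e-15) {
        pairs[a, 1] <- cand
        freeRows <- setdiff(seq_len(I), pairs[, 1])
        improved <- TRUE
      }
    }
    freeCols <- setdiff(seq_len(J), pairs[, 2])
    for (a in seq_len(k)) {
      if (!length(freeCols)) break
      cand <- freeCols[which.max(A[pairs[a, 1], freeCols])]
      if (A[pairs[a, 1], cand] > A[pairs[a, 1], pairs[a, 2]] + 1e-15) {
        pairs[a, 2] <- cand
        freeCols <- setdiff(seq_len(J), pairs[, 2])
        improved <- TRUE
      }
    }
    # 3-cycles of columns among triples of pairs
    if (!improved && k >= 3 && k <= 24) {
      for (a in seq_len(k - 2)) {
        for (b in (a + 1):(k - 1)) for (cc in (b + 1):k) {
          ra <- pairs[a, 1]; rb <- pairs[b, 1]; rc <- pairs[cc, 1]
          ca <- pairs[a, 2]; cb <- pairs[b, 2]; co <- pairs[cc, 2]
          cur <- A[ra, ca] + A[rb, cb] + A[rc, co]
          alt1 <- A[ra, cb] + A[rb, co] + A[rc, ca]
          alt2 <- A[ra, co] + A[rb, ca] + A[rc, cb]
          if (alt1 > cur + 1e-15 && alt1 >= alt2) {
            pairs[a, 2] <- cb; pairs[b, 2] <- co; pairs[cc, 2] <- ca
            improved <- TRUE
          } else if (alt2 > cur + 1e-15) {
            pairs[a, 2] <- co; pairs[b, 2] <- ca; pairs[cc, 2] <- cb
            improved <- TRUE
          }
        }
        if (improved) break
      }
    }
    if (!improved) break
  }
  pairs
}

# ---- coarse rescaling -------------------------------------------------------

#' Six-factor coarse rescaling of a pit cloud
#'
#' For each axis and sign, the factor is the ratio of the mean absolute
#' coordinate of P's pits on that half-axis to the mean absolute coordinate
#' of Q's pits on the same half-axis; the rescaled P divides each
#' coordinate by the factor of its half-axis, mapping P onto Q's scale.
#' Both clouds must share the anatomical origin. Pits with a coordinate of
#' exactly 0 count to the positive half-axis; a half-axis with no Q pits
#' gets factor 1 with a warning.
#'
#' @param P cloud to be rescaled (early-stage brain).
#' @param Q reference cloud (later-stage brain).
#' @return list with \code{factors} (fx+, fx-, fy+, fy-, fz+, fz-) and
#'   \code{rescaled} (P after rescaling, p x 3 matrix).
#' @export
coarseRescale <- function(P, Q) {
  P <- asPitMatrix(P); Q <- asPitMatrix(Q)
  factors <- numeric(6)
  names(factors) <- c("fx+", "fx-", "fy+", "fy-", "fz+", "fz-")
  out <- P
  for (ax in 1:3) {
    for (s in c(1, -1)) {
      idx <- 2 * ax - 1 + (s == -1)
      selP <- if (s > 0) P[, ax] >= 0 else P[, ax] < 0
      selQ <- if (s > 0) Q[, ax] >= 0 else Q[, ax] < 0
      if (!any(selQ)) {
        if (any(selP))
          warning("half-axis ", names(factors)[idx],
                  " empty in reference cloud; factor set to 1")
        factors[idx] <- 1
      } else if (!any(selP)) {
        factors[idx] <- 1
      } else {
        factors[idx] <- mean(abs(P[selP, ax])) / mean(abs(Q[selQ, ax]))
      }
      if (!is.finite(factors[idx]) || factors[idx] <= 0) factors[idx] <- 1
      out[selP, ax] <- P[selP, ax] / factors[idx]
    }
  }
  list(factors = factors, rescaled = out)
}

# ---- rigid refinement -------------------------------------------------------

#' Refined rigid registration of strongly paired pits
#'
#' Least-squares rigid alignment (orthogonal Procrustes with translation,
#' Kabsch): finds rotation R (det = +1) and translation t minimizing
#' sum ||R p_i + t - q_i||^2 over the paired pits. Falls back to the
#' identity with a warning for fewer than 3 pairs or collinear
#' configurations.
#'
#' @param Ppairs,Qpairs k x 3 matrices of paired pit positions.
#' @return list with \code{rotation} (3 x 3), \code{translation} (length 3)
#'   and \code{valid} (FALSE when the identity fallback was used).
#' @export
refineRegistration <- function(Ppairs, Qpairs) {
  Ppairs <- as.matrix(Ppairs); Qpairs <- as.matrix(Qpairs)
  identityFallback <- function(msg) {
    warning(msg, "; returning identity transform")
    list(rotation = diag(3), translation = numeric(3), valid = FALSE)
  }
  if (nrow(Ppairs) < 3 || nrow(Ppairs) != nrow(Qpairs))
    return(identityFallback("fewer than 3 pairs"))
  cp <- colMeans(Ppairs); cq <- colMeans(Qpairs)
  Pc <- sweep(Ppairs, 2, cp); Qc <- sweep(Qpairs, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-300))
    return(identityFallback("collinear pit configuration"))
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_ <- cq - as.numeric(R %*% cp)
  list(rotation = R, translation = t_, valid = TRUE)
}

# ---- two-stage matching and SDSP --------------------------------------------

pairSimilarity <- function(P, Q, pairs, sigma) {
  d2 <- rowSums((P[pairs[, 1], , drop = FALSE] -
                   Q[pairs[, 2], , drop = FALSE])^2)
  exp(-d2 / sigma)
}

#' Two-stage sulcal-pit matching and SDSP
#'
#' Full pipeline: coarse six-factor rescaling of P onto Q, RRWM matching
#' under the Gaussian affinity, retention of strong pairs
#' (similarity > threshold), refined rigid registration on the strong
#' pairs, re-matching on the registered clouds, final strong-pair filter,
#' and the similarity degree of sulcal pits (SDSP) as the mean similarity
#' over the final strong pairs. SDSP is 0 (with a "no-strong-pairs" flag)
#' when nothing survives the filter.
#'
#' @param P early-stage pit cloud (matched onto Q's scale).
#' @param Q later-stage (reference) pit cloud.
#' @param sigma Gaussian kernel scale (default 100).
#' @param threshold strong-pair similarity threshold (default 0.5, strict
#'   inequality).
#' @param rescale apply the coarse rescaling stage.
#' @param ... further arguments to \code{\link{rrwmMatch}}.
#' @return a \linkS4class{MatchResult}.
#' @export
twoStageMatch <- function(P, Q, sigma = 100, threshold = 0.5,
                          rescale = TRUE, ...) {
  P <- asPitMatrix(P); Q <- asPitMatrix(Q)
  if (nrow(P) == 0 || nrow(Q) == 0) stop("empty pit cloud")
  flags <- character(0)

  if (rescale) {
    cr <- coarseRescale(P, Q)
    P1 <- cr$rescaled
    factors <- cr$factors
  } else {
    P1 <- P
    factors <- rep(1, 6)
  }

  m1 <- rrwmMatch(pitAffinity(P1, Q, sigma), ...)
  sim1 <- pairSimilarity(P1, Q, m1$pairs, sigma)
  strong1 <- sim1 > threshold

  rot <- diag(3); tr <- numeric(3)
  if (sum(strong1) >= 3) {
    reg <- refineRegistration(P1[m1$pairs[strong1, 1], , drop = FALSE],
                              Q[m1$pairs[strong1, 2], , drop = FALSE])
    if (reg$valid) { rot <- reg$rotation; tr <- reg$translation }
    else flags <- c(flags, "refinement-degenerate")
  } else {
    flags <- c(flags, "no-stage1-strong-pairs")
  }
  P2 <- sweep(P1 %*% t(rot), 2, tr, `+`)

  m2 <- rrwmMatch(pitAffinity(P2, Q, sigma), ...)
  sim2 <- pairSimilarity(P2, Q, m2$pairs, sigma)
  strong2 <- sim2 > threshold

  sdspVal <- if (any(strong2)) mean(sim2[strong2]) else 0
  if (!any(strong2)) flags <- c(flags, "no-strong-pairs")

  new("MatchResult",
      pairs = m2$pairs, similarity = sim2, strong = strong2,
      sdsp = sdspVal, matchMatrix = m2$matchMatrix, flags = flags,
      scaleFactors = factors,
      transform = list(rotation = rot, translation = tr))
}
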