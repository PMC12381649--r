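#' @include match.R
NULL

#' Simulate a cohort of folding brains and extract stage-wise pit clouds
#'
#' End-to-end desk-scale workflow: for each subject a smooth brain-like
#' surface with subject-specific primary-fold undulations is generated,
#' offset inward by the cortical thickness, meshed into a conforming
#' bilayer, and grown with the differential-tangential-growth simulator
#' (cortical/white growth-rate ratio \code{ratio}); sulcal pits are
#' extracted from the white-matter surface of every emitted stage
#' (including t0).
#'
#' The geometry is a scaled-down analogue of a fetal hemisphere: ~12 mm
#' semi-axes with the anatomically plausible 1.4 mm cortical layer and a
#' mesh edge close to 1 mm, keeping element counts in the 1e4-1e5 range.
#'
#' @param nSubjects number of subjects.
#' @param seed integer seed; each subject's undulations derive from it.
#' @param semiAxes base ellipsoid semi-axes in mm.
#' @param undulationAmp amplitude (mm) of the primary-fold undulations.
#' @param corticalThickness cortical layer thickness in mm.
#' @param targetEdge mesh edge length in mm.
#' @param ratio cortical/white growth-rate ratio (paper-representative 4).
#' @param thetaSubTarget white-matter growth multiplier at the final stage.
#' @param nSnapshots emitted stages after t0 (default 7).
#' @param nSteps explicit steps of the growth phase.
#' @param pitArgs list of arguments for the pit-extraction pipeline. By
#'   default the dimensional watershed thresholds are scaled with the
#'   geometry (a desk-scale brain is a scaled physical model of a ~40 mm
#'   fetal hemisphere, so the pit-distance and basin-area thresholds scale
#'   by s and s^2 with the linear scale s); the ridge-height threshold is
#'   scale-free and keeps its published value.
#' @return list of subjects, each with \code{trajectory}
#'   (\linkS4class{GrowthTrajectory}) and \code{pitStages} (list of
#'   \linkS4class{PitCloud}s, t0 first).
#' @export
simulateFoldingCohort <- function(nSubjects, seed = 1L,
                                  semiAxes = c(12.5, 11.5, 10.5),
                                  undulationAmp = 1.5,
                                  corticalThickness = 1.4,
                                  targetEdge = 1.1, ratio = 4,
                                  thetaSubTarget = 1.35, nSnapshots = 7,
                                  nSteps = 10000, pitArgs = NULL) {
  if (is.null(pitArgs)) {
    sc <- prod(semiAxes)^(1 / 3) / 40 # linear scale vs a 40 mm hemisphere
    pitArgs <- list(thrR = 1.5, thrD = 20 * sc, thrA = 50 * sc^2,
                    distance = "geodesic")
  }
  lapply(seq_len(nSubjects), function(s) {
    spec <- syntheticBrainSpec(
      semiAxes = semiAxes,
      undulationModes = list(c(3, undulationAmp), c(5, 0.7 * undulationAmp),
                             c(7, 0.35 * undulationAmp)),
      corticalThickness = corticalThickness,
      targetEdgeLength = targetEdge,
      seed = seed + 101L * s)
    pial <- makeSmoothBrain(spec)
    white <- inwardOffset(pial, corticalThickness)
    bl <- buildBilayer(pial, white, targetEdge)
    params <- materialParams(mu = 1, Gctx = ratio, Gsub = 1)
    cfg <- simConfig(nSteps = nSteps, nSnapshots = nSnapshots,
                     settleSteps = 400, settleTol = 2e-4)
    traj <- simulateGrowth(bl, params, cfg, thetaSubTarget = thetaSubTarget)
    pitStages <- lapply(traj@snapshots, function(sn) {
      do.call(extractPitsFromSurface, c(list(sn$white), pitArgs))$pits
    })
    list(trajectory = traj, pitStages = pitStages)
  })
}

#' All-pairs SDSP matrix between two cohorts
#'
#' Entry (i, j) is the SDSP of matching the first-timepoint cloud of
#' subject i against the second-timepoint cloud of subject j; diagonal
#' entries are within-subject similarities.
#'
#' @param cloudsFirst,cloudsSecond equal-length lists of pit clouds.
#' @param ... arguments passed to \code{\link{twoStageMatch}}.
#' @return n x n numeric matrix with entries in [0, 1].
#' @export
pairwiseSDSP <- function(cloudsFirst, cloudsSecond, ...) {
  n <- length(cloudsFirst)
  if (n == 0 || length(cloudsSecond) != n)
    stop("cohorts must be non-empty and of equal length")
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    m[i, j] <- suppressWarnings(
      sdsp(twoStageMatch(cloudsFirst[[i]], cloudsSecond[[j]], ...)))
  }
  m
}

#' Row-wise diagonal dominance of an SDSP matrix
#'
#' A row is flagged when its diagonal entry is the strict row maximum
#' (the later-stage scan is matched to the correct subject); ties count as
#' failures.
#'
#' @param m square SDSP matrix.
#' @return list with \code{flags} (per-row logical), \code{count} and
#'   \code{accuracy} (percent).
#' @export
diagonalDominance <- function(m) {
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  n <- nrow(m)
  flags <- vapply(seq_len(n), function(i) {
    off <- m[i, -i]
    length(off) == 0 || m[i, i] > max(off)
  }, logical(1))
  list(flags = flags, count = sum(flags), accuracy = 100 * sum(flags) / n)
}

#' Per-row off-diagonal exceedance counts
#'
#' For each row, the number of off-diagonal entries strictly greater than
#' the diagonal entry, with the cohort mean and standard deviation.
#'
#' @param m square SDSP matrix.
#' @return list with \code{counts}, \code{mean}, \code{sd}.
#' @export
offDiagonalExceedance <- function(m) {
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  counts <- vapply(seq_len(nrow(m)), function(i)
    sum(m[i, -i] > m[i, i]), numeric(1))
  list(counts = counts, mean = mean(counts), sd = stats::sd(counts))
}

#' Stage-wise SDSP course and adjacent-stage paired t-tests
#'
#' Given per-subject developmental trajectories of pit clouds
#' (t0, t1, ..., tn), computes for every subject the SDSP of each stage
#' against t0, then compares adjacent stages across subjects with paired
#' two-sided t-tests (SDSP(t_i, t0) vs SDSP(t_{i-1}, t0)).
#'
#' @param trajectories list of subjects, each a list of pit clouds ordered
#'   t0 first.
#' @param bonferroni apply Bonferroni correction across the adjacent-stage
#'   comparisons.
#' @param ... arguments passed to \code{\link{twoStageMatch}}.
#' @return list with \code{sdspCourse} (subjects x stages matrix, first
#'   column 1 by self-similarity) and \code{tests} (data.frame with stage,
#'   t, p; p is NA with a note when differences have zero variance).
#' @export
stageCourse <- function(trajectories, bonferroni = FALSE, ...) {
  nSub <- length(trajectories)
  if (nSub < 1) stop("at least one trajectory required")
  nStage <- length(trajectories[[1]])
  course <- t(vapply(trajectories, function(tr) {
    vapply(seq_len(nStage), function(s) {
      suppressWarnings(sdsp(twoStageMatch(tr[[1]], tr[[s]], ...)))
    }, numeric(1))
  }, numeric(nStage)))
  tests <- NULL
  if (nSub >= 2 && nStage >= 2) {
    rows <- lapply(2:nStage, function(s) {
      d <- course[, s] - course[, s - 1]
      if (stats::sd(d) < 1e-15) {
        data.frame(stage = s - 1, t = NA_real_, p = NA_real_,
                   note = "zero-variance differences")
      } else {
        tt <- stats::t.test(course[, s], course[, s - 1], paired = TRUE)
        data.frame(stage = s - 1, t = unname(tt$statistic),
                   p = unname(tt$p.value), note = "")
      }
    })
    tests <- do.call(rbind, rows)
    if (bonferroni) tests$p <- pmin(1, tests$p * nrow(tests))
  }
  list(sdspCourse = course, tests = tests)
}

#' OLS regression of SDSP on a covariate
#'
#' Ordinary least squares with the standard t-test on the slope, as used
#' for SDSP-versus-gestational-week analyses.
#'
#' @param values numeric response (SDSP values).
#' @param covariate numeric covariate (e.g. gestational weeks).
#' @return list with \code{slope}, \code{intercept}, \code{p} (two-sided).
#' @export
regressSDSP <- function(values, covariate) {
  if (length(values) < 3) stop("at least 3 points required")
  if (stats::sd(covariate) < 1e-15) stop("constant covariate")
  fit <- stats::lm(values ~ covariate)
  sm <- suppressWarnings(summary(fit))$coefficients # perfect fits warn
  p <- if (nrow(sm) > 1 && !is.nan(sm[2, 4])) sm[2, 4] else 0
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p = p)
}

#' Moving average of a series
#'
#' Means over sliding windows (defaults: window 3, step 1).
#'
#' @param series numeric vector.
#' @param window window size (<= length of series).
#' @param step step size.
#' @return numeric vector of window means.
#' @export
movingAverage <- function(series, window = 3, step = 1) {
  n <- length(series)
  if (window > n) stop("window larger than series")
  starts <- seq(1, n - window + 1, by = step)
  vapply(starts, function(s) mean(series[s:(s + window - 1)]), numeric(1))
}

#' Pit-count trajectories and two-phase summary
#'
#' Per-stage pit counts for each trajectory plus a two-phase summary: mean
#' per-stage increment over the early half versus the late half of the
#' course (the establishment pattern: near-linear early increase, late
#' stabilisation).
#'
#' @param trajectories list of per-subject stage lists of pit clouds (or a
#'   single such list).
#' @return list with \code{counts} (subjects x stages matrix),
#'   \code{earlyIncrement}, \code{lateIncrement}.
#' @export
pitCountTrajectory <- function(trajectories) {
  if (length(trajectories) >= 1 && is(trajectories[[1]], "PitCloud"))
    trajectories <- list(trajectories)
  if (!length(trajectories)) stop("at least one trajectory required")
  counts <- t(vapply(trajectories, function(tr)
    vapply(tr, nPits, integer(1)), integer(length(trajectories[[1]]))))
  nStage <- ncol(counts)
  if (nStage < 2) stop("at least two stages required")
  # two phases: increments within the first half of the stages versus
  # increments within the second half (the crossing increment is in neither)
  half <- ceiling(nStage / 2)
  diffsIn <- function(block) {
    if (ncol(block) < 2) return(0)
    mean(block[, -1, drop = FALSE] - block[, -ncol(block), drop = FALSE])
  }
  list(counts = counts,
       earlyIncrement = diffsIn(counts[, seq_len(half), drop = FALSE]),
       lateIncrement = diffsIn(counts[, (half + 1):nStage, drop = FALSE]))
}
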