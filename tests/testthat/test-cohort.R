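test_that("pairwise SDSP matrices have unit diagonal against copies", {
  set.seed(4)
  clouds <- lapply(1:3, function(i) PitCloud(matrix(runif(60, -30, 30),
                                                    20, 3)))
  m <- suppressWarnings(pairwiseSDSP(clouds, clouds))
  expect_equal(diag(m), rep(1, 3))
  expect_true(all(m >= 0 & m <= 1))
  m1 <- suppressWarnings(pairwiseSDSP(clouds[1], clouds[1]))
  expect_equal(dim(m1), c(1L, 1L))
  expect_error(pairwiseSDSP(list(), list()), "non-empty")
})

test_that("diagonal dominance flags strict row maxima only", {
  dd <- diagonalDominance(diag(3))
  expect_true(all(dd$flags))
  expect_equal(dd$accuracy, 100)

  m <- diag(3); m[2, 3] <- 2
  dd2 <- diagonalDominance(m)
  expect_equal(dd2$count, 2L)
  expect_false(dd2$flags[2])

  cst <- matrix(1, 4, 4)
  expect_equal(diagonalDominance(cst)$count, 0L) # ties fail
  expect_error(diagonalDominance(matrix(0, 2, 3)), "square")
})

test_that("off-diagonal exceedance counts and summaries", {
  expect_true(all(offDiagonalExceedance(diag(3))$counts == 0))
  m <- rbind(c(0.5, 0.9, 0.8), c(0.3, 0.9, 0.1), c(0.2, 0.1, 0.15))
  ex <- offDiagonalExceedance(m)
  expect_equal(ex$counts, c(2, 0, 1))
  expect_equal(ex$mean, 1)
  expect_true(all(ex$counts <= nrow(m) - 1))
})

test_that("stage courses start at 1 and paired t-tests match closed form", {
  set.seed(6)
  base <- matrix(runif(90, -30, 30), 30, 3)
  mkTraj <- function(drift) {
    lapply(seq(0, 3), function(s)
      PitCloud(base + matrix(rnorm(90, 0, drift * s), 30, 3)))
  }
  trajs <- list(mkTraj(0.6), mkTraj(0.7), mkTraj(0.8))
  sc <- suppressWarnings(stageCourse(trajs))
  expect_equal(sc$sdspCourse[, 1], rep(1, 3))
  # hand-computed paired t statistic for the first adjacent comparison
  d <- sc$sdspCourse[, 2] - sc$sdspCourse[, 1]
  tHand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(sc$tests$t[1], tHand, tolerance = 1e-12)
  pHand <- 2 * pt(abs(tHand), df = 2, lower.tail = FALSE)
  expect_equal(sc$tests$p[1], pHand, tolerance = 1e-12)

  # constant sequences: zero-variance differences are flagged, not crashed
  flat <- lapply(1:2, function(i) lapply(1:3, function(s) PitCloud(base)))
  scf <- suppressWarnings(stageCourse(flat))
  expect_true(all(is.na(scf$tests$p)))
  expect_true(all(scf$tests$note == "zero-variance differences"))
})

test_that("SDSP regression reduces to closed-form OLS", {
  r <- regressSDSP(c(0, 1, 2), c(0, 1, 2))
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0)
  expect_lt(r$p, 1e-10)
  set.seed(7)
  x <- runif(20); y <- 0.3 + 0.5 * x + rnorm(20, 0, 0.05)
  r1 <- regressSDSP(y, x)
  o <- sample(20)
  r2 <- regressSDSP(y[o], x[o])
  expect_equal(r1$slope, r2$slope)
  expect_equal(r1$p, r2$p)
  expect_error(regressSDSP(y, rep(1, 20)), "constant")
  expect_error(regressSDSP(y[1:2], x[1:2]), "3 points")
})

test_that("moving averages follow the window/step definition", {
  expect_equal(movingAverage(c(1, 2, 3, 4), 3, 1), c(2, 3))
  expect_equal(movingAverage(rep(5, 6), 3, 1), rep(5, 4))
  expect_equal(movingAverage(1:5, 5, 1), 3)
  expect_error(movingAverage(1:2, 3, 1), "window")
})

test_that("pit-count trajectories summarise the two-phase pattern", {
  counts <- c(5, 8, 11, 14, 15, 15, 15, 15)
  traj <- list(lapply(counts, function(k)
    PitCloud(matrix(seq_len(3 * k), k, 3))))
  s <- pitCountTrajectory(traj)
  expect_equal(as.integer(s$counts[1, ]), counts)
  expect_equal(s$earlyIncrement, 3)
  expect_equal(s$lateIncrement, 0)

  flat <- list(lapply(rep(4, 5), function(k)
    PitCloud(matrix(seq_len(3 * k), k, 3))))
  sf <- pitCountTrajectory(flat)
  expect_equal(sf$earlyIncrement, 0)
  expect_equal(sf$lateIncrement, 0)
})
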