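test_that("smooth brain with no undulations matches closed-form areas", {
  # sphere: equal semi-axes, area 4 pi r^2
  spec <- syntheticBrainSpec(semiAxes = c(20, 20, 20),
                             undulationModes = list(),
                             targetEdgeLength = 1.5, seed = 1)
  sph <- makeSmoothBrain(spec)
  expect_equal(surfaceArea(sph), 4 * pi * 400, tolerance = 0.01)
  # ellipsoid: Thomsen approximation as oracle (itself ~1% accurate)
  ax <- c(40, 33, 28)
  spec2 <- syntheticBrainSpec(semiAxes = ax, undulationModes = list(),
                              targetEdgeLength = 1.8, seed = 1)
  ell <- makeSmoothBrain(spec2)
  p <- 1.6075
  thomsen <- 4 * pi * ((ax[1]^p * ax[2]^p + ax[1]^p * ax[3]^p +
                          ax[2]^p * ax[3]^p) / 3)^(1 / p)
  expect_equal(surfaceArea(ell), thomsen, tolerance = 0.02)
  # mesh quality and validity
  d <- meshDiagnostics(ell)
  expect_true(d$closed && d$manifold && d$oriented)
  expect_lt(abs(median(edgeLengths(ell)) / 1.8 - 1), 0.2)
})

test_that("brain generation is deterministic and validates amplitudes", {
  spec <- syntheticBrainSpec(seed = 7)
  m1 <- makeSmoothBrain(spec)
  m2 <- makeSmoothBrain(spec)
  expect_identical(vertices(m1), vertices(m2))
  expect_identical(faces(m1), faces(m2))
  expect_error(syntheticBrainSpec(semiAxes = c(30, 30, 30),
                                  undulationModes = list(c(3, 10))),
               "amplitude")
})

test_that("generated brains pass the surface diagnostics", {
  spec <- syntheticBrainSpec(semiAxes = c(30, 26, 24), seed = 3,
                             targetEdgeLength = 2)
  brain <- makeSmoothBrain(spec)
  d <- meshDiagnostics(brain)
  expect_true(d$closed)
  expect_true(d$manifold)
  expect_true(d$oriented)
  expect_gt(enclosedVolume(brain), 0)
})

test_that("pit-cloud cohort transforms follow the recorded ground truth", {
  # identity growth: t1 equals t0 and the truth is the identity map
  coh <- makePitCloudCohort(2, nPitsRange = c(10, 10), scaleRange = c(1, 1),
                            jitterSd = 0, maxRotationDeg = 0,
                            maxTranslation = 0, birthFraction = 0, seed = 2)
  s <- coh[[1]]
  expect_equal(pitPositions(s$pitsT1), pitPositions(s$pitsT0))
  expect_equal(s$truthPairs[, 1], s$truthPairs[, 2])

  # uniform doubling: every coordinate doubles
  coh2 <- makePitCloudCohort(2, nPitsRange = c(12, 12), scaleRange = c(2, 2),
                             jitterSd = 0, maxRotationDeg = 0,
                             maxTranslation = 0, birthFraction = 0, seed = 2)
  expect_equal(pitPositions(coh2[[1]]$pitsT1),
               2 * pitPositions(coh2[[1]]$pitsT0))

  # determinism
  a <- makePitCloudCohort(3, seed = 9)
  b <- makePitCloudCohort(3, seed = 9)
  expect_identical(lapply(a, function(x) pitPositions(x$pitsT1)),
                   lapply(b, function(x) pitPositions(x$pitsT1)))
  expect_error(makePitCloudCohort(1), "nSubjects")
  expect_error(makePitCloudCohort(3, nPitsRange = c(5, 2)), "nPitsRange")
})

test_that("cohort truth pairs are recoverable by nearest neighbour", {
  coh <- makePitCloudCohort(3, jitterSd = 0, birthFraction = 0.2, seed = 4)
  for (s in coh) {
    p0 <- pitPositions(s$pitsT0)
    p1 <- pitPositions(s$pitsT1)
    gt <- s$growthTruth
    mapped <- neurofold:::applyHalfAxisScale(p0, gt$factors)
    mapped <- sweep(mapped %*% t(gt$rotation), 2, gt$translation, `+`)
    nn <- apply(mapped, 1, function(p)
      which.min(colSums((t(p1) - p)^2)))
    expect_equal(nn, s$truthPairs[, 2])
    expect_gte(nPits(s$pitsT1), nPits(s$pitsT0))
  }
})

test_that("depth phantoms carry the advertised ground truth", {
  ph1 <- makeDepthPhantom(1)
  expect_equal(length(unique(ph1$labels)), 1L)
  expect_equal(length(ph1$pitVertices), 1L)

  ph2 <- makeDepthPhantom(2, pitDepths = 3, ridgeDepths = 1)
  expect_equal(ph2$ridgeHeight, 2, tolerance = 0.05)
  # exhaustive local-maxima scan finds exactly the two bump centres
  nbr <- neurofold:::vertexNeighbors(ph2$mesh)
  isMax <- vapply(seq_along(nbr), function(v)
    all(ph2$depth[v] > ph2$depth[nbr[[v]]]), logical(1))
  expect_equal(sum(isMax), 2L)

  ph0 <- makeDepthPhantom(0)
  expect_equal(length(ph0$pitVertices), 0L)
  expect_true(all(ph0$depth == 0))
  expect_error(makeDepthPhantom(2, pitDepths = 1, ridgeDepths = 2),
               "inconsistent depths")
})
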