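test_that("DPF is constant on spheres and maximal at a dent", {
  s <- unitSphere(10)
  d <- dpf(s)
  expect_lt(diff(range(d$depth)), 1e-3)

  ds <- dentedSphere()
  dd <- dpf(ds$mesh)
  expect_equal(which.max(dd$depth), ds$dentVertex)
  expect_gt(max(dd$depth), 0) # concave region positive
})

test_that("DPF is independent of brain size", {
  ds <- dentedSphere()
  d1 <- dpf(ds$mesh)$depth
  d2 <- dpf(SurfaceMesh(2 * vertices(ds$mesh), faces(ds$mesh)))$depth
  expect_lt(max(abs(d2 - d1)) / diff(range(d1)), 0.05)
})

test_that("watershed reproduces phantom ground truth under the thresholds", {
  # well-separated deep bumps, ridge gap 2.0 > 1.5: two basins survive
  ph <- makeDepthPhantom(2, pitDepths = 3, ridgeDepths = 1, radius = 10)
  seg <- watershedByFlooding(ph$mesh, ph$depth, thrR = 1.5, thrD = 20)
  expect_equal(length(seg@pitVertex), 2L)
  expect_setequal(seg@pitVertex, ph$pitVertices)

  # shallow ridge (gap 0.8 < 1.5) and close pits (~10 mm < 20): merged
  cen <- rbind(c(0, 0, 1), c(sin(pi / 3), 0, cos(pi / 3)))
  ph2 <- makeDepthPhantom(2, pitDepths = 3, ridgeDepths = 2.2, radius = 10,
                          centers = cen)
  seg2 <- watershedByFlooding(ph2$mesh, ph2$depth, thrR = 1.5, thrD = 20)
  expect_equal(length(seg2@pitVertex), 1L)

  # same shallow ridge but pits far apart (antipodal, ~31 mm > 20): kept
  ph3 <- makeDepthPhantom(2, pitDepths = 3, ridgeDepths = 2.2, radius = 10)
  seg3 <- watershedByFlooding(ph3$mesh, ph3$depth, thrR = 1.5, thrD = 20)
  expect_equal(length(seg3@pitVertex), 2L)

  expect_warning(
    seg0 <- watershedByFlooding(ph$mesh, rep(1, nVertices(ph$mesh))),
    "constant")
  expect_equal(length(seg0@pitVertex), 0L)
})

test_that("basin labels partition the surface and areas add up", {
  ph <- makeDepthPhantom(4, pitDepths = 4, ridgeDepths = 1, radius = 10,
                         freq = 10)
  seg <- watershedByFlooding(ph$mesh, ph$depth, thrR = 1.5, thrD = 8,
                             thrA = 20)
  expect_true(all(seg@labels > 0))
  expect_equal(sum(seg@basinArea), surfaceArea(ph$mesh), tolerance = 1e-6)
  expect_true(all(seg@basinArea >= 20))
})

test_that("small basins merge into the longest-border neighbour", {
  ph <- makeDepthPhantom(2, pitDepths = c(4, 2.5), ridgeDepths = 1,
                         radius = 10)
  # huge area threshold forces every merge: one basin remains
  seg <- watershedByFlooding(ph$mesh, ph$depth, thrR = 0.5, thrD = 5,
                             thrA = 5000)
  expect_equal(length(seg@pitVertex), 1L)
  expect_true(any(seg@mergeLog$reason == "area"))
})

test_that("pit extraction is a bijection onto basins with maximal depths", {
  ph <- makeDepthPhantom(5, pitDepths = 4, ridgeDepths = 1, radius = 10,
                         freq = 10)
  seg <- watershedByFlooding(ph$mesh, ph$depth, thrR = 1.5, thrD = 5,
                             thrA = 10)
  pits <- extractPits(seg, ph$mesh, ph$depth)
  expect_equal(nPits(pits), length(seg@basinIds))
  for (b in seq_along(seg@basinIds)) {
    inBasin <- seg@labels == seg@basinIds[b]
    expect_gte(pits@depth[b], max(ph$depth[inBasin]))
  }
  expect_error(extractPits(new("BasinSegmentation",
                               labels = integer(10), pitVertex = integer(0),
                               basinArea = numeric(0),
                               ridges = data.frame(),
                               mergeLog = data.frame(),
                               basinIds = integer(0)),
                           ph$mesh, ph$depth), "empty")
})

test_that("pit counts are monotone in the merge thresholds", {
  ph <- makeDepthPhantom(6, pitDepths = c(5, 4, 4.5, 3.5, 4, 5),
                         ridgeDepths = 1.5, radius = 10, freq = 10)
  nR <- vapply(c(0.3, 1, 2, 4), function(r)
    length(watershedByFlooding(ph$mesh, ph$depth, thrR = r, thrD = 50,
                               thrA = 1)@pitVertex), integer(1))
  expect_true(all(diff(nR) <= 0))
  nA <- vapply(c(1, 30, 100, 400), function(a)
    length(watershedByFlooding(ph$mesh, ph$depth, thrR = 0.3, thrD = 50,
                               thrA = a)@pitVertex), integer(1))
  expect_true(all(diff(nA) <= 0))
})
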