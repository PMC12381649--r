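test_that("Taubin smoothing is low-shrinkage and denoises", {
  s <- geodesicSphere(10, 24)
  expect_identical(vertices(taubinSmooth(s, 0)), vertices(s))

  sm <- taubinSmooth(s, 100)
  expect_identical(faces(sm), faces(s))
  expect_lt(abs(mean(sqrt(rowSums(vertices(sm)^2))) / 10 - 1), 0.01)
  expect_lt(abs(enclosedVolume(sm) / enclosedVolume(s) - 1), 0.03)

  set.seed(3)
  v <- vertices(s)
  noisy <- SurfaceMesh(v * (1 + rnorm(nrow(v), 0, 0.05)), faces(s))
  radialSd <- function(m) sd(sqrt(rowSums(vertices(m)^2)))
  sdBefore <- radialSd(noisy)
  # default pass-band: about 4x noise reduction at 100 iterations
  expect_gt(sdBefore / radialSd(taubinSmooth(noisy, 100)), 4)
  # a tighter pass-band (|mu| closer to lambda) removes more of the
  # low-frequency noise while staying low-shrinkage
  tight <- taubinSmooth(noisy, 100, lambda = 0.5, mu = -0.505)
  expect_gt(sdBefore / radialSd(tight), 5)
  expect_lt(abs(mean(sqrt(rowSums(vertices(tight)^2))) / 10 - 1), 0.01)
})

test_that("isotropic remeshing hits the target and is idempotent", {
  s <- unitSphere(10) # radius 10
  r1 <- isotropicRemesh(s, 1)
  expect_true(meshDiagnostics(r1)$closed)
  med <- median(edgeLengths(r1))
  expect_gt(med, 0.75); expect_lt(med, 1.25)
  # output lies on the input surface (radial Hausdorff < target)
  expect_lt(max(abs(sqrt(rowSums(vertices(r1)^2)) - 10)), 1)
  r2 <- isotropicRemesh(r1, 1)
  expect_lt(abs(median(edgeLengths(r2)) / med - 1), 0.05)
  # near-identity resolution change keeps the area
  expect_lt(abs(surfaceArea(r1) / surfaceArea(s) - 1), 0.01)
  expect_error(isotropicRemesh(s, 0.01), "feature size")
})

test_that("inward offset moves the surface by the requested distance", {
  s <- unitSphere(10)
  expect_identical(vertices(inwardOffset(s, 0)), vertices(s))
  off <- inwardOffset(s, 1.4)
  rr <- sqrt(rowSums(vertices(off)^2))
  expect_lt(abs(mean(rr) / 8.6 - 1), 0.01)

  # ellipsoid: brute-force closest-point distance between surfaces
  spec <- syntheticBrainSpec(semiAxes = c(30, 25, 20),
                             undulationModes = list(),
                             targetEdgeLength = 2, seed = 1)
  ell <- makeSmoothBrain(spec)
  out <- inwardOffset(ell, 1.4)
  vo <- vertices(out); vi <- vertices(ell)
  dmin <- vapply(sample(nrow(vo), 200), function(i)
    sqrt(min(colSums((t(vi) - vo[i, ])^2))), numeric(1))
  expect_true(all(abs(dmin - 1.4) < 0.1))
})

test_that("bilayer construction is conforming, positive and layered", {
  pial <- unitSphere(10)
  white <- inwardOffset(pial, 1.4)
  # edge 0.7 -> >= 2 cortical layers; 0.35 -> >= 4
  for (cfg in list(c(0.7, 2), c(0.35, 4))) {
    bl <- buildBilayer(pial, white, cfg[1])
    # count cortex elements crossed by random radial rays
    ctx <- which(bl@region == 1L)
    cent <- (bl@nodes[bl@tets[ctx, 1], ] + bl@nodes[bl@tets[ctx, 2], ] +
               bl@nodes[bl@tets[ctx, 3], ] + bl@nodes[bl@tets[ctx, 4], ]) / 4
    r <- sqrt(rowSums(cent^2))
    set.seed(1)
    for (k in 1:20) {
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      ang <- acos(pmin(1, (cent / r) %*% dir))
      near <- which(ang < 0.05)
      layers <- length(unique(round(r[near], 3)))
      expect_gte(layers, cfg[2])
    }
  }
  bl <- buildBilayer(pial, white, 0.7)
  vols <- neurofold:::tetVolumes(bl@nodes, bl@tets)
  expect_true(all(vols > 0))
  expect_lt(abs(sum(vols) / enclosedVolume(pial) - 1), 0.02)
  # conforming interface: white-surface faces appear in tets of both regions
  expect_equal(sort(unique(bl@region)), c(1L, 2L))
  expect_true(all(sqrt(rowSums(bl@normal0[bl@region == 1L, ]^2)) - 1 < 1e-9))
  expect_error(buildBilayer(white, pial, 0.7), "inside")
})

test_that("curvature and geodesics match closed forms on spheres", {
  s <- unitSphere(10)
  H <- meanCurvature(s)
  expect_true(all(abs(H * 10 - 1) < 0.03))
  # flat patch: open grid has H ~ 0 away from the boundary
  g <- expand.grid(x = 0:6, y = 0:6)
  vv <- cbind(g$x, g$y, 0)
  idx <- function(i, j) i + 7 * (j - 1)
  ff <- do.call(rbind, lapply(1:6, function(j) do.call(rbind,
    lapply(1:6, function(i) rbind(c(idx(i, j), idx(i + 1, j), idx(i, j + 1)),
                                  c(idx(i + 1, j), idx(i + 1, j + 1),
                                    idx(i, j + 1)))))))
  flat <- SurfaceMesh(vv, ff)
  interior <- which(g$x %in% 2:4 & g$y %in% 2:4)
  expect_true(all(abs(meanCurvature(flat)[interior]) < 1e-8))

  d <- geodesicDistance(s, 1L)
  ang <- as.numeric(acos(pmin(1, (vertices(s) / 10) %*%
                                 (vertices(s)[1, ] / 10))))
  far <- ang > 0.3
  expect_lt(max(abs(d[far] - 10 * ang[far]) / (10 * ang[far])), 0.02)
})

test_that("the smooth-remesh-offset pipeline yields a valid bilayer", {
  spec <- syntheticBrainSpec(semiAxes = c(14, 12.5, 11),
                             undulationModes = list(c(3, 1.2)),
                             targetEdgeLength = 1.4, seed = 11)
  brain <- taubinSmooth(makeSmoothBrain(spec), 10)
  brain <- isotropicRemesh(brain, 1.4)
  white <- inwardOffset(brain, 1.4)
  bl <- buildBilayer(brain, white, 1.4)
  expect_true(all(neurofold:::tetVolumes(bl@nodes, bl@tets) > 0))
  d <- meshDiagnostics(extractSurface(bl, which = "pial"))
  expect_true(d$closed && d$manifold)
})
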