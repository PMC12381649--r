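test_that("growth tensors have the prescribed spectra and determinants", {
  expect_equal(growthTensorCortex(1, c(0, 0, 1)), diag(3))
  expect_equal(growthTensorCortex(2, c(0, 0, 1)), diag(c(2, 2, 1)))
  set.seed(1)
  for (k in 1:5) {
    n0 <- rnorm(3); n0 <- n0 / sqrt(sum(n0^2))
    theta <- runif(1, 1, 3)
    Fg <- growthTensorCortex(theta, n0)
    # eigenvalue 1 along n0, theta in-plane; det = theta^2
    expect_equal(as.numeric(Fg %*% n0), n0, tolerance = 1e-12)
    expect_equal(sort(eigen(Fg)$values), sort(c(1, theta, theta)),
                 tolerance = 1e-10)
    expect_equal(det(Fg), theta^2, tolerance = 1e-10)
  }
  expect_error(growthTensorCortex(2, c(0, 0, 2)), "unit")

  expect_equal(growthTensorWhite(1), diag(3))
  expect_equal(growthTensorWhite(8), 2 * diag(3))
  for (theta in c(1.5, 3, 10))
    expect_equal(det(growthTensorWhite(theta)), theta, tolerance = 1e-12)
  expect_error(growthTensorWhite(0), "positive")
})

test_that("elastic part inverts the growth decomposition", {
  Fg <- growthTensorCortex(2, c(0, 0, 1))
  expect_equal(elasticPart(Fg, Fg), diag(3))
  expect_equal(elasticPart(diag(3), Fg), diag(c(0.5, 0.5, 1)))
  set.seed(2)
  for (k in 1:10) {
    F_ <- diag(3) + matrix(runif(9, -0.3, 0.3), 3, 3)
    Fe <- elasticPart(F_, Fg)
    expect_lt(max(abs(Fe %*% Fg - F_)), 1e-12)
  }
  expect_error(elasticPart(diag(3), matrix(0, 3, 3)), "determinant")
})

test_that("Cauchy stress matches its closed forms and the energy oracle", {
  expect_equal(cauchyStress(diag(3), 1, 5), matrix(0, 3, 3))
  expect_equal(cauchyStress(1.1 * diag(3), 0.7, 1),
               (1.1^3 - 1) * diag(3), tolerance = 1e-12)
  # small simple shear: T12 = mu * gamma
  gam <- 1e-4
  Fe <- diag(3); Fe[1, 2] <- gam
  T_ <- cauchyStress(Fe, 1.3, 6.5)
  expect_equal(T_[1, 2], 1.3 * gam, tolerance = 0.01)

  # independent oracle: central differences of the energy density give the
  # first Piola stress; push forward to Cauchy
  mu <- 0.9; k <- 4.5
  for (Fe in randomFe(100, seed = 5)) {
    P <- matrix(0, 3, 3)
    h <- 1e-6
    for (i in 1:3) for (j in 1:3) {
      Fp <- Fe; Fp[i, j] <- Fp[i, j] + h
      Fm <- Fe; Fm[i, j] <- Fm[i, j] - h
      P[i, j] <- (neoHookeanEnergy(Fp, mu, k) -
                    neoHookeanEnergy(Fm, mu, k)) / (2 * h)
    }
    Tfd <- P %*% t(Fe) / det(Fe)
    T_ <- cauchyStress(Fe, mu, k)
    expect_lt(max(abs(T_ - Tfd)) / max(abs(T_), 1e-10), 1e-6)
    expect_lt(max(abs(T_ - t(T_))), 1e-8)
  }
})

test_that("Cauchy stress is objective and zero for rotations", {
  set.seed(8)
  for (k in 1:20) {
    R <- randomRotationMatrix()
    expect_lt(max(abs(cauchyStress(R, 1, 5))), 1e-10)
    Fe <- randomFe(1, seed = k)[[1]]
    T1 <- cauchyStress(R %*% Fe, 1.2, 6)
    T2 <- R %*% cauchyStress(Fe, 1.2, 6) %*% t(R)
    expect_lt(max(abs(T1 - T2)), 1e-10)
  }
})

test_that("growth kinetics are linear and element-wise", {
  p <- materialParams(Gctx = 4, Gsub = 0.5)
  st <- list(thetaCtx = 1, thetaSub = 1)
  st2 <- advanceGrowth(st, 0.25, p)
  expect_equal(st2$thetaCtx, 2)
  expect_equal(st2$thetaSub, 1.125)
  p0 <- materialParams(Gctx = 0, Gsub = 0)
  expect_equal(advanceGrowth(st, 1, p0), st)
  # n steps accumulate exactly
  stn <- list(thetaCtx = rep(1, 5), thetaSub = rep(1, 5))
  for (i in 1:40) stn <- advanceGrowth(stn, 0.1, p)
  expect_equal(stn$thetaCtx, rep(1 + 4 * 4, 5))
  expect_error(advanceGrowth(st, -1, p), "positive")
})

test_that("growth-ratio estimation follows the linear-growth identity", {
  expect_equal(estimateGrowthRatio(1, 2, 1, 1.25), 4)
  expect_equal(estimateGrowthRatio(10, 13, 8, 10.4), 1)
  expect_equal(estimateGrowthRatio(1, 1.31, 1, 1.20), 0.31 / 0.20)
  expect_error(estimateGrowthRatio(1, 2, 1.2, 1.0), "grow")
})

test_that("deformation states satisfy the decomposition invariants", {
  pial <- geodesicSphere(6, 4)
  bl <- buildBilayer(pial, inwardOffset(pial, 1.4), 1.5)
  set.seed(19)
  nodes <- bl@nodes * 1.08 + matrix(rnorm(length(bl@nodes), 0, 0.01),
                                    nrow(bl@nodes), 3)
  st <- deformationState(bl, nodes, thetaCtx = 1.2, thetaSub = 1.1,
                         elements = sample(nrow(bl@tets), 25))
  for (s in st) {
    expect_lt(max(abs(s$Fe %*% s$Fg - s$F)), 1e-10)
    expect_gt(s$Je, 0)
    expect_lt(max(abs(s$T - t(s$T))), 1e-10)
    expect_true(all(eigen(s$be, symmetric = TRUE)$values > 0))
    expect_true(all(eigen(s$Ce, symmetric = TRUE)$values > 0))
  }
})

test_that("zero growth and zero pressure leave the mesh untouched", {
  cube <- makeTetCube(3, 1)
  p <- materialParams(Gctx = 0, Gsub = 0, pressureCoeff = 0)
  cfg <- simConfig(nSteps = 200, nSnapshots = 1, contact = FALSE,
                   settleSteps = 100)
  tr <- simulateGrowth(cube, p, cfg, tEnd = 1)
  s <- tr@snapshots[[2]]
  expect_lt(max(abs(s$nodes - cube@nodes)), 1e-10)
})

test_that("stress-free homogeneous growth doubles a free cube", {
  cube <- makeTetCube(4, 1)
  p <- materialParams(mu = 1, Gctx = 0, Gsub = 7, pressureCoeff = 0)
  cfg <- simConfig(nSteps = 3000, nSnapshots = 2, contact = FALSE,
                   settleSteps = 4000, settleTol = 1e-7)
  tr <- simulateGrowth(cube, p, cfg, thetaSubTarget = 8)
  s <- tr@snapshots[[length(tr@snapshots)]]
  rng <- apply(s$nodes, 2, function(x) diff(range(x)))
  expect_equal(rng, rep(2, 3), tolerance = 0.01)
  expect_lt(max(s$stress_norm), 1e-3)
  expect_equal(s$white_volume_ratio, 8, tolerance = 0.01)
  # quasi-static: inertia negligible at the snapshot
  expect_lt(s$kinetic_energy, 0.01 * max(s$strain_energy, 1e-12))
})
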