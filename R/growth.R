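#' @include surface.R
NULL

#' Material parameters for the growth model
#'
#' Neo-Hookean parameters shared by cortex and white matter (equal shear
#' moduli), linear growth-rate constants, and the pial pressure coefficient.
#' The pressure emulating the meninges/skull constraint is
#' \code{pressureCoeff * mu} (default coefficient 0.7).
#'
#' @param mu shear modulus (arbitrary stress units).
#' @param k bulk modulus; default 5*mu (mildly compressible).
#' @param Gctx cortical in-plane growth rate (1/time).
#' @param Gsub white-matter volumetric growth rate (1/time).
#' @param pressureCoeff dimensionless pial pressure coefficient.
#' @return list of validated parameters.
#' @export
materialParams <- function(mu = 1, k = 5 * mu, Gctx = 4, Gsub = 1,
                           pressureCoeff = 0.7) {
  if (mu <= 0 || k <= 0) stop("mu and k must be positive")
  if (Gctx < 0 || Gsub < 0) stop("growth rates must be >= 0")
  if (pressureCoeff < 0) stop("pressureCoeff must be >= 0")
  list(mu = mu, k = k, Gctx = Gctx, Gsub = Gsub,
       pressureCoeff = pressureCoeff)
}

#' Cortical growth tensor
#'
#' In-plane (tangential) growth: Fg = theta I + (1 - theta) n0 (x) n0.
#' Eigenvalue theta (multiplicity 2) in the tangent plane of the referential
#' pial normal n0, eigenvalue 1 along n0; det Fg = theta^2, so theta is the
#' linear in-plane stretch multiplier and cortical area grows as theta^2.
#'
#' @param theta growth multiplier (>= 1).
#' @param n0 referential unit pial normal.
#' @return 3 x 3 growth tensor.
#' @export
growthTensorCortex <- function(theta, n0) {
  if (theta < 1) stop("theta must be >= 1")
  if (abs(sqrt(sum(n0^2)) - 1) > 1e-8) stop("n0 must be a unit vector")
  theta * diag(3) + (1 - theta) * tcrossprod(n0)
}

#' White-matter growth tensor
#'
#' Isotropic volumetric growth: Fg = theta^(1/3) I with det Fg = theta, so
#' theta is the white-matter volume multiplier.
#'
#' @param theta volumetric growth multiplier (> 0).
#' @return 3 x 3 growth tensor.
#' @export
growthTensorWhite <- function(theta) {
  if (theta <= 0) stop("theta must be positive")
  theta^(1 / 3) * diag(3)
}

#' Elastic part of the deformation gradient
#'
#' Multiplicative decomposition F = Fe Fg, so Fe = F Fg^-1.
#'
#' @param F total deformation gradient (3 x 3).
#' @param Fg growth tensor (3 x 3, det > 0).
#' @return elastic deformation gradient Fe.
#' @export
elasticPart <- function(F, Fg) {
  if (det(Fg) <= 0) stop("Fg must have positive determinant")
  F %*% solve(Fg)
}

#' Neo-Hookean strain energy density
#'
#' W = mu/2 (Je^{-2/3} tr(Fe^T Fe) - 3) + k/2 (Je - 1)^2.
#'
#' @param Fe elastic deformation gradient.
#' @param mu shear modulus.
#' @param k bulk modulus.
#' @return scalar energy density.
#' @export
neoHookeanEnergy <- function(Fe, mu, k) {
  Je <- det(Fe)
  if (Je <= 0) stop("non-positive elastic Jacobian")
  mu / 2 * (Je^(-2 / 3) * sum(Fe^2) - 3) + k / 2 * (Je - 1)^2
}

#' Cauchy stress of the neo-Hookean model
#'
#' T = Je^-1 (dW/dFe) Fe^T
#'   = mu Je^{-5/3} dev(Fe Fe^T) + k (Je - 1) I.
#' Symmetric, zero for any rotation, and pure-dilation response
#' k (Je - 1) I.
#'
#' @param Fe elastic deformation gradient (det > 0).
#' @param mu shear modulus.
#' @param k bulk modulus.
#' @return symmetric 3 x 3 Cauchy stress.
#' @export
cauchyStress <- function(Fe, mu, k) {
  Je <- det(Fe)
  if (Je <= 0)
    stop("non-positive elastic Jacobian (element inversion)")
  B <- tcrossprod(Fe)
  devB <- B - sum(diag(B)) / 3 * diag(3)
  mu * Je^(-5 / 3) * devB + k * (Je - 1) * diag(3)
}

#' Advance growth multipliers by linear kinetics
#'
#' theta_ctx grows at rate Gctx, theta_sub at rate Gsub:
#' theta <- theta + G * dt, element-wise.
#'
#' @param state list with numeric fields \code{thetaCtx} and \code{thetaSub}
#'   (scalars or per-element vectors).
#' @param dt time increment (> 0).
#' @param params \code{\link{materialParams}}.
#' @return updated state.
#' @export
advanceGrowth <- function(state, dt, params) {
  if (dt <= 0) stop("dt must be positive")
  state$thetaCtx <- state$thetaCtx + params$Gctx * dt
  state$thetaSub <- state$thetaSub + params$Gsub * dt
  state
}

#' Estimate the cortical/white growth-rate ratio from measurements
#'
#' Under linear growth over a common scan interval the cortical rate is
#' proportional to the relative surface-area change and the white-matter
#' rate to the relative volume change, so
#' Gctx/Gsub = (A1/A0 - 1) / (V1/V0 - 1).
#'
#' @param areaT0,areaT1 cortical surface areas at the two timepoints.
#' @param volT0,volT1 white-matter volumes at the two timepoints.
#' @return scalar ratio Gctx/Gsub.
#' @export
estimateGrowthRatio <- function(areaT0, areaT1, volT0, volT1) {
  if (min(areaT0, areaT1, volT0, volT1) <= 0)
    stop("areas and volumes must be positive")
  if (volT1 <= volT0) stop("white-matter volume must grow (V1 > V0)")
  (areaT1 / areaT0 - 1) / (volT1 / volT0 - 1)
}

#' Per-element deformation state of a grown bilayer
#'
#' Reconstructs the multiplicative-decomposition fields for a deformed
#' configuration: total gradient F, growth tensor Fg, elastic part
#' Fe = F Fg^-1, elastic Jacobian Je, elastic Cauchy-Green tensors and the
#' Cauchy stress, for each tetrahedron.
#'
#' @param bilayer the reference \linkS4class{BilayerTetMesh}.
#' @param nodes deformed node positions.
#' @param thetaCtx,thetaSub growth multipliers at this state.
#' @param params \code{\link{materialParams}}.
#' @param elements optional subset of element indices.
#' @return list of per-element lists with \code{F}, \code{Fg}, \code{Fe},
#'   \code{Je}, \code{be}, \code{Ce}, \code{T}.
#' @export
deformationState <- function(bilayer, nodes, thetaCtx, thetaSub,
                             params = materialParams(),
                             elements = NULL) {
  tt <- bilayer@tets
  if (is.null(elements)) elements <- seq_len(nrow(tt))
  lapply(elements, function(e) {
    ref <- bilayer@nodes[tt[e, ], ]
    cur <- nodes[tt[e, ], ]
    Dm <- t(ref[2:4, ]) - ref[1, ]
    Ds <- t(cur[2:4, ]) - cur[1, ]
    F_ <- Ds %*% solve(Dm)
    Fg <- if (bilayer@region[e] == 1L)
      growthTensorCortex(thetaCtx, bilayer@normal0[e, ])
    else growthTensorWhite(thetaSub)
    Fe <- elasticPart(F_, Fg)
    Je <- det(Fe)
    if (Je <= 0) stop("element inversion at element ", e)
    list(F = F_, Fg = Fg, Fe = Fe, Je = Je,
         be = tcrossprod(Fe), Ce = crossprod(Fe),
         T = cauchyStress(Fe, params$mu, params$k))
  })
}

#' Simulation configuration
#'
#' Numerical controls of the explicit dynamic-relaxation solver. The
#' fictitious density is mass-scaled automatically from the step count and
#' stability limit; growth is applied slowly and each emitted snapshot is
#' settled until the kinetic energy is a small fraction of the strain
#' energy, so inertia is negligible in the reported states.
#'
#' @param nSteps number of explicit growth steps.
#' @param nSnapshots snapshots evenly spaced in theta_sub (default 7).
#' @param damp per-step velocity retention factor (0-1).
#' @param cfl stability safety factor for mass scaling.
#' @param settleSteps maximum settling steps per snapshot.
#' @param settleTol kinetic/strain energy ratio at which settling stops.
#' @param contact enable pial penalty self-contact.
#' @param contactGap contact activation distance in mm (default set from
#'   the mesh edge length by \code{\link{simulateGrowth}} when NULL).
#' @param contactStiff penalty stiffness in units of mu/mm.
#' @param contactEvery steps between contact-candidate rebuilds.
#' @param stopVolumeRatio target deformed/initial white-matter volume ratio
#'   (NULL: grow to the nominal theta_sub target only).
#' @param stopTol relative tolerance on the volume-ratio stop criterion.
#' @return list of configuration values.
#' @export
simConfig <- function(nSteps = 6000, nSnapshots = 7, damp = 0.97,
                      cfl = 0.35, settleSteps = 1500, settleTol = 5e-4,
                      contact = TRUE, contactGap = NULL, contactStiff = 5,
                      contactEvery = 20, stopVolumeRatio = NULL,
                      stopTol = 0.02) {
  if (nSnapshots < 1) stop("nSnapshots must be >= 1")
  list(nSteps = as.integer(nSteps), nSnapshots = as.integer(nSnapshots),
       damp = damp, cfl = cfl, settleSteps = as.integer(settleSteps),
       settleTol = settleTol, contact = contact, contactGap = contactGap,
       contactStiff = contactStiff, contactEvery = as.integer(contactEvery),
       stopVolumeRatio = stopVolumeRatio, stopTol = stopTol)
}

# k-ring neighbourhoods on the pial shell, used to exclude topological
# neighbours from self-contact
pialExclusionRings <- function(bilayer, rings = 3L) {
  pial <- extractSurface(bilayer, which = "pial")
  A <- vertexAdjacency(pial)
  Ak <- A + Matrix::Diagonal(nrow(A))
  R <- Ak
  for (i in seq_len(rings - 1)) R <- R %*% Ak
  R <- methods::as(R, "CsparseMatrix")
  ids <- bilayer@pialVertices
  lapply(seq_len(ncol(R)), function(j) {
    rows <- if (R@p[j + 1] > R@p[j]) R@i[(R@p[j] + 1):R@p[j + 1]] + 1L
            else integer(0)
    ids[rows]
  })
}

#' Simulate differential tangential growth
#'
#' Explicit quasi-static simulation of the bilayer brain: cortical elements
#' grow tangentially at rate Gctx, white-matter elements volumetrically at
#' rate Gsub; the growth mismatch builds tangential compression in the
#' cortex that buckles into folds. A follower pressure of
#' \code{pressureCoeff * mu} acts on the pial surface and penalty
#' self-contact prevents fold interpenetration. Snapshots are emitted evenly
#' spaced in theta_sub between 1 and \code{thetaSubTarget}; when a
#' stop-volume ratio is set, growth continues until the deformed
#' white-matter volume reaches it within tolerance.
#'
#' @param bilayer a \linkS4class{BilayerTetMesh}.
#' @param params \code{\link{materialParams}}.
#' @param config \code{\link{simConfig}}.
#' @param thetaSubTarget white-matter growth multiplier reached at the final
#'   snapshot.
#' @param tEnd simulated duration; defaults to
#'   (thetaSubTarget - 1)/Gsub (required when Gsub = 0).
#' @return a \linkS4class{GrowthTrajectory}; snapshot 1 is the undeformed
#'   reference (t0), followed by the emitted stages.
#' @export
simulateGrowth <- function(bilayer, params = materialParams(),
                           config = simConfig(), thetaSubTarget = 1.5,
                           tEnd = NULL) {
  if (is.null(tEnd)) {
    if (params$Gsub <= 0)
      stop("tEnd must be given when Gsub = 0")
    tEnd <- (thetaSubTarget - 1) / params$Gsub
  }
  if (tEnd <= 0) stop("simulated duration must be positive")
  gap <- config$contactGap
  if (is.null(gap)) {
    pial <- extractSurface(bilayer, which = "pial")
    gap <- 0.4 * stats::median(edgeLengths(pial))
  }
  excl <- if (config$contact) pialExclusionRings(bilayer) else
    rep(list(integer(0)), length(bilayer@pialVertices))
  par <- list(mu = params$mu, kbulk = params$k, Gctx = params$Gctx,
              Gsub = params$Gsub,
              pressure = params$pressureCoeff * params$mu,
              t_end = tEnd, n_steps = config$nSteps,
              n_snapshots = config$nSnapshots, damp = config$damp,
              cfl = config$cfl, settle_steps = config$settleSteps,
              settle_tol = config$settleTol, contact = config$contact,
              contact_gap = gap, contact_stiff = config$contactStiff * params$mu,
              contact_every = config$contactEvery,
              vol_target = if (is.null(config$stopVolumeRatio)) NA_real_
                           else config$stopVolumeRatio,
              vol_tol = config$stopTol)
  res <- cpp_simulate_growth(bilayer@nodes, bilayer@tets, bilayer@region,
                             bilayer@normal0, bilayer@pialFaces,
                             bilayer@pialVertices, excl, par)
  if (!isTRUE(res$ok))
    stop("growth simulation failed: ", res$message)
  snaps <- res$snapshots
  ref <- list(nodes = bilayer@nodes, theta_ctx = 1, theta_sub = 1,
              je = rep(1, nrow(bilayer@tets)),
              stress_norm = rep(0, nrow(bilayer@tets)),
              kinetic_energy = 0, strain_energy = 0,
              white_volume_ratio = 1, time = 0)
  snaps <- c(list(ref), snaps)
  snaps <- lapply(snaps, function(s) {
    s$pial <- extractSurface(bilayer, s$nodes, "pial")
    s$white <- extractSurface(bilayer, s$nodes, "white")
    s
  })
  new("GrowthTrajectory", bilayer = bilayer, snapshots = snaps,
      params = params, config = config)
}
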