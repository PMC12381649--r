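# shared fixtures, built lazily and cached for the whole test run

nfCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, builder) {
  if (is.null(nfCache[[name]])) nfCache[[name]] <- builder()
  nfCache[[name]]
}

unitSphere <- function(freq = 10) {
  cachedFixture(paste0("sphere_", freq), function() geodesicSphere(10, freq))
}

# all permutations of a vector (for brute-force assignment oracles)
allPerms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in allPerms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

# brute-force optimal total affinity over one-to-one matchings
bruteBestAffinity <- function(A) {
  I <- nrow(A); J <- ncol(A)
  best <- 0
  if (I <= J) {
    for (p in allPerms(seq_len(J)))
      best <- max(best, sum(A[cbind(seq_len(I), p[seq_len(I)])]))
  } else {
    for (p in allPerms(seq_len(I)))
      best <- max(best, sum(A[cbind(p[seq_len(J)], seq_len(J))]))
  }
  best
}

# random elastic deformation gradients with positive determinant
randomFe <- function(n, scale = 0.3, seed = 1) {
  withr_seed <- .Random.seed
  set.seed(seed)
  out <- lapply(seq_len(n), function(i) {
    repeat {
      Fe <- diag(3) + matrix(stats::runif(9, -scale, scale), 3, 3)
      if (det(Fe) > 0.3) return(Fe)
    }
  })
  .Random.seed <<- withr_seed
  out
}

randomRotationMatrix <- function() {
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  ang <- stats::runif(1, 0, pi)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

# the shared 5-subject simulated folding cohort (expensive; built once,
# used by the cohort-level and acceptance tests)
foldingCohort <- function() {
  cachedFixture("folding_cohort", function() simulateFoldingCohort(5, seed = 5))
}

# a dented sphere: one inward Gaussian dent at the north pole
dentedSphere <- function(radius = 10, freq = 10, depthFrac = 0.15,
                         width = 0.3) {
  s <- geodesicSphere(radius, freq)
  v <- vertices(s)
  dirs <- v / radius
  ang <- as.numeric(acos(pmin(1, dirs %*% c(0, 0, 1))))
  dentV <- which.min(ang)
  v2 <- v * (1 - depthFrac * exp(-ang^2 / (2 * width^2)))
  list(mesh = SurfaceMesh(v2, faces(s)), dentVertex = dentV)
}
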