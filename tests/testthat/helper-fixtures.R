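# Shared fixtures: everything is generated in code at test time.

h_acq <- function(dt = 0.032) acquisition_params(dt)

# Independent dense-matrix oracle for the displacement log-likelihood:
# builds the full covariance and evaluates the multivariate normal density
# with generic linear algebra (determinant + solve), no tridiagonal tricks.
dense_loglik <- function(dx, D, sigma, acq) {
  N <- length(dx)
  S <- displacement_covariance(D, sigma, acq, N)
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  -0.5 * (N * log(2 * pi) + ld + as.numeric(t(dx) %*% solve(S, dx)))
}

# Hand-built deterministic track from cumulative displacements
h_track <- function(dx_x, dx_y = dx_x, id = "t") {
  trajectory(id, cbind(cumsum(c(0, dx_x)), cumsum(c(0, dx_y))))
}

# Small simulated two-state population shared by several tests
h_two_state <- function(M = 120, D = c(0.02, 0.5), seed = 42) {
  simulate_tracks(D = D, sigma = 0.05, pi = c(0.5, 0.5), M = M,
                  acq = h_acq(), seed = seed)
}

# Independent per-track CVE oracle (plain arithmetic, one track, one dim)
cve_oracle_1d <- function(dx, dt, R) {
  N <- length(dx)
  msd <- mean(dx^2)
  lag1 <- mean(dx[-N] * dx[-1])
  D <- (msd + 2 * lag1) / (2 * dt)
  c(D = D, sigma2 = msd / 2 - D * dt * (1 - 2 * R))
}
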