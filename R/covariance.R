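# Floors applied to parameters when building a covariance: M-step / CVE raw
# estimates may be negative, but the Gaussian likelihood needs a positive
# definite matrix. Raw values are preserved for reporting; only the matrix
# construction is floored.
.D_FLOOR <- 1e-9    # um^2/s
.S2_FLOOR <- 1e-12  # um^2

#' Set of diffusive states
#'
#' A diffusive state is a normal-diffusion regime characterized by a
#' diffusivity \eqn{D_k} (um^2/s), a static localization noise standard
#' deviation \eqn{\sigma_k} (um), and a population fraction \eqn{\pi_k}.
#'
#' @param D Numeric vector of diffusivities (um^2/s).
#' @param sigma Numeric vector of static localization noises (um), recycled
#'   to \code{length(D)}.
#' @param pi Numeric vector of population fractions summing to 1.
#' @param acquisition \code{\link{acquisition_params}}.
#' @param sort_by_D Report states sorted by ascending diffusivity
#'   (default \code{TRUE}); runs are then comparable across seeds despite
#'   label switching.
#' @return Object of class \code{"diffusive_states"} with fields \code{D},
#'   \code{sigma}, \code{pi}, \code{acquisition}, and \code{K}.
#' @export
diffusive_states <- function(D, sigma, pi = rep(1 / length(D), length(D)),
                             acquisition, sort_by_D = TRUE) {
  stopifnot_acq(acquisition)
  K <- length(D)
  sigma <- rep_len(sigma, K)
  if (length(pi) != K) stop("'pi' must have one fraction per state")
  if (any(!is.finite(D)) || any(!is.finite(sigma)) || any(!is.finite(pi)))
    stop("state parameters must be finite")
  if (any(pi < -1e-12) || abs(sum(pi) - 1) > 1e-9)
    stop("population fractions must be non-negative and sum to 1")
  pi <- pmax(pi, 0); pi <- pi / sum(pi)
  if (sort_by_D) {
    o <- order(D)
    D <- D[o]; sigma <- sigma[o]; pi <- pi[o]
  }
  structure(list(D = D, sigma = sigma, pi = pi,
                 acquisition = acquisition, K = K),
            class = "diffusive_states")
}

#' @export
print.diffusive_states <- function(x, digits = 4, ...) {
  cat(sprintf("%d diffusive state(s):\n", x$K))
  print(data.frame(state = seq_len(x$K),
                   D = signif(x$D, digits),
                   sigma = signif(x$sigma, digits),
                   pi = signif(x$pi, digits)), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.diffusive_states <- function(x, ...) {
  data.frame(state = seq_len(x$K), D = x$D, sigma = x$sigma, pi = x$pi)
}

# (diagonal, off-diagonal) entries of the displacement covariance for one
# state, with positivity floors applied.
state_band <- function(D, sigma2, acq) {
  D <- max(D, .D_FLOOR)
  sigma2 <- max(sigma2, .S2_FLOOR)
  dt <- acq$dt; R <- acq$R
  c(diag = 2 * D * dt + 2 * sigma2 - 4 * R * D * dt,
    off = -sigma2 + 2 * R * D * dt)
}

#' Analytic displacement covariance of a noisy Brownian track
#'
#' For a track undergoing normal diffusion with diffusivity \code{D},
#' static localization noise \code{sigma}, frame interval \eqn{\Delta t} and
#' motion-blur coefficient \eqn{R}, the covariance of the vector of N
#' one-dimensional displacements is symmetric tridiagonal:
#' diagonal \eqn{2D\Delta t + 2\sigma^2 - 4RD\Delta t}, first off-diagonals
#' \eqn{-\sigma^2 + 2RD\Delta t}, zero elsewhere. Static noise induces the
#' negative nearest-neighbour displacement correlation; motion blur reduces
#' the apparent variance.
#'
#' @param D Diffusivity, um^2/s (floored at 1e-9 for construction).
#' @param sigma Static localization noise, um (sigma^2 floored at 1e-12).
#' @param acq \code{\link{acquisition_params}}.
#' @param N Number of displacements (matrix dimension), >= 1.
#' @return Dense symmetric tridiagonal \code{N x N} matrix (um^2). Intended
#'   for inspection and testing; likelihood evaluation uses an O(N)
#'   factorization and never forms this matrix.
#' @examples
#' acq <- acquisition_params(0.032)
#' displacement_covariance(0.1, 0.05, acq, 3)
#' @export
displacement_covariance <- function(D, sigma, acq, N) {
  stopifnot_acq(acq)
  if (N < 1L) stop("'N' must be >= 1")
  b <- state_band(D, sigma^2, acq)
  m <- diag(rep(b[["diag"]], N), nrow = N)
  if (N > 1L) {
    idx <- seq_len(N - 1L)
    m[cbind(idx, idx + 1L)] <- b[["off"]]
    m[cbind(idx + 1L, idx)] <- b[["off"]]
  }
  m
}

# LDL^T (Thomas) pivots of the symmetric tridiagonal Toeplitz matrix with
# diagonal a and off-diagonal b: d[1] = a, d[i] = a - b^2 / d[i-1]. The first
# N pivots factorize the N x N leading principal submatrix, so one pivot
# vector serves all track lengths up to N.
tridiag_pivots <- function(a, b, N) {
  d <- numeric(N)
  d[1L] <- a
  if (N > 1L) for (i in 2L:N) d[i] <- a - b * b / d[i - 1L]
  if (any(d <= 0))
    stop(sprintf(
      "tridiagonal factorization breakdown (diag %.6g, off %.6g): %s",
      a, b, "covariance not positive definite"))
  d
}

#' Log-likelihood of a 1D displacement vector under a diffusive state
#'
#' Evaluates the log multivariate-normal density of a displacement vector
#' with mean zero and the tridiagonal covariance of
#' \code{\link{displacement_covariance}}. Computed in O(N) via the symmetric
#' tridiagonal LDL^T recursion (log-determinant from the pivots, quadratic
#' form by forward substitution); the dense matrix is never formed.
#'
#' @param dx Numeric vector of 1D displacements (um), length >= 1.
#' @param D Diffusivity, um^2/s.
#' @param sigma Static localization noise, um.
#' @param acq \code{\link{acquisition_params}}.
#' @return Log-density in nats.
#' @export
loglik_displacements <- function(dx, D, sigma, acq) {
  stopifnot_acq(acq)
  N <- length(dx)
  if (N < 1L || !all(is.finite(dx)))
    stop("'dx' must be a finite vector of length >= 1")
  bd <- state_band(D, sigma^2, acq)
  d <- tridiag_pivots(bd[["diag"]], bd[["off"]], N)
  # Solve L y = dx with unit lower bidiagonal L, l[i] = off / d[i-1]
  y <- numeric(N)
  y[1L] <- dx[1L]
  if (N > 1L) {
    l <- bd[["off"]] / d[-N]
    for (i in 2L:N) y[i] <- dx[i] - l[i - 1L] * y[i - 1L]
  }
  quad <- sum(y * y / d)
  -0.5 * (N * log(2 * pi) + sum(log(d)) + quad)
}

#' Covariance-based estimator (CVE) of diffusivity and static noise
#'
#' Moment estimator from a single track: per dimension,
#' \deqn{\hat D = (\langle\Delta x^2\rangle +
#'   2\langle\Delta x_n \Delta x_{n+1}\rangle)/(2\Delta t)}
#' \deqn{\hat\sigma^2 = \langle\Delta x^2\rangle/2 -
#'   \hat D \Delta t (1 - 2R)}
#' where the angle brackets are means over the track's displacements and
#' nearest-neighbour displacement products. Raw estimates are unbiased but
#' unbounded: negative values are legal for short tracks and are returned
#' as-is.
#'
#' @param x A \code{"trajectory"} or a \code{"track_set"}.
#' @param acq \code{\link{acquisition_params}}; taken from the track set when
#'   \code{x} is one.
#' @param ... Unused.
#' @return For a trajectory, a one-row data.frame with per-dimension and
#'   dimension-averaged columns \code{D_x, D_y, D, sigma2_x, sigma2_y,
#'   sigma2}; for a track set, one row per track (plus \code{id}).
#' @examples
#' acq <- acquisition_params(0.032)
#' tr <- trajectory("a", cbind(cumsum(c(0, 0.1, 0.1)), c(0, 0, 0)))
#' cve(tr, acq)
#' @export
cve <- function(x, ...) UseMethod("cve")

#' @rdname cve
#' @export
cve.trajectory <- function(x, acq, ...) {
  stopifnot_acq(acq)
  N <- n_steps(x)
  if (N < 2L)
    stop(sprintf("track '%s' has %d displacement(s); CVE needs >= 2 (lag-1 correlation)",
                 x$id, N))
  dt <- acq$dt; R <- acq$R
  est <- function(dx) {
    msd <- mean(dx^2)
    lag1 <- mean(dx[-N] * dx[-1L])
    D <- (msd + 2 * lag1) / (2 * dt)
    c(D = D, sigma2 = msd / 2 - D * dt * (1 - 2 * R))
  }
  ex <- est(displacements(x, 1L))
  ey <- est(displacements(x, 2L))
  data.frame(id = x$id,
             D_x = ex[["D"]], D_y = ey[["D"]],
             D = (ex[["D"]] + ey[["D"]]) / 2,
             sigma2_x = ex[["sigma2"]], sigma2_y = ey[["sigma2"]],
             sigma2 = (ex[["sigma2"]] + ey[["sigma2"]]) / 2,
             n_steps = N, row.names = NULL)
}

#' @rdname cve
#' @export
cve.track_set <- function(x, acq = x$acquisition, ...) {
  do.call(rbind, lapply(x$tracks, cve.trajectory, acq = acq))
}
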