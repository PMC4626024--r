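# Deterministic core of the track-length model: N(Z) for Z in [0,1].
# The real-valued length is floored, so the printed minimum is attainable.
length_from_z <- function(z, n_min = 15L, n_max = 60L, n_mean = 25) {
  r <- (n_max - n_min) / (n_mean - n_min)
  as.integer(floor((n_max - n_min) * exp(-r * z) + n_min))
}

#' Sample trajectory lengths
#'
#' Track lengths (in displacements) follow the truncated-exponential model
#' \eqn{N = \lfloor (N_{max}-N_{min}) e^{-rZ} + N_{min} \rfloor} with
#' \eqn{r = (N_{max}-N_{min})/(\langle N\rangle - N_{min})} and Z uniform on
#' [0, 1], mimicking fluorophore-bleaching-limited track durations. The
#' defaults (min 15, max 60, mean 25) give r = 4.5.
#'
#' @param n Number of lengths to draw.
#' @param n_min,n_max,n_mean Length model constants (displacements).
#' @return Integer vector of lengths in \code{[n_min, n_max]}.
#' @export
sample_track_length <- function(n, n_min = 15L, n_max = 60L, n_mean = 25) {
  stopifnot(n_min < n_mean, n_mean < n_max)
  length_from_z(stats::runif(n), n_min, n_max, n_mean)
}

#' Simulate one Brownian trajectory with motion blur and static noise
#'
#' Positions evolve by the micro-step recursion
#' \eqn{x_{i+1} = x_i + \sqrt{2D\,\delta t}\,W_i} (\eqn{x_1 = 0}, W standard
#' normal) at a micro interval \eqn{\delta t = \Delta t / n_{micro}}, run
#' independently in each of the two dimensions. Each recorded frame position
#' is the average of the micro-positions falling inside the exposure window
#' (motion blur); full-frame exposure averages all \code{n_micro}
#' micro-positions, shorter exposures average only the leading
#' \code{ceiling(n_micro * exposure_dt / dt)}. Static localization noise is
#' added as an independent zero-mean normal with standard deviation
#' \code{sigma} at every frame.
#'
#' @param D Diffusivity, um^2/s.
#' @param sigma Static localization noise, um.
#' @param n_steps Number of displacements (the track has
#'   \code{n_steps + 1} frames).
#' @param acq \code{\link{acquisition_params}}.
#' @param n_micro Micro-steps per frame (default 32; at dt = 0.032 s this is
#'   a 1 ms micro interval).
#' @param id Track identifier.
#' @return A \code{\link{trajectory}}.
#' @export
simulate_track <- function(D, sigma, n_steps, acq, n_micro = 32L,
                           id = "sim") {
  stopifnot_acq(acq)
  if (n_steps < 1L) stop("'n_steps' must be >= 1")
  if (n_micro < 1L) stop("'n_micro' must be >= 1")
  n_frames <- n_steps + 1L
  n_expose <- max(1L, ceiling(n_micro * acq$exposure_dt / acq$dt))
  total <- n_frames * n_micro
  step_sd <- sqrt(2 * D * acq$dt / n_micro)
  pos <- matrix(0, n_frames, 2L)
  for (dd in 1:2) {
    micro <- cumsum(c(0, stats::rnorm(total - 1L, sd = step_sd)))
    blocks <- matrix(micro, n_micro, n_frames)
    pos[, dd] <- colMeans(blocks[seq_len(n_expose), , drop = FALSE])
  }
  if (sigma > 0)
    pos <- pos + matrix(stats::rnorm(2L * n_frames, sd = sigma), n_frames, 2L)
  trajectory(id, pos)
}

#' Simulate a heterogeneous trajectory population with known ground truth
#'
#' For each state k, \code{round(pi[k] * M)} tracks of random length are
#' simulated at \code{(D[k], sigma[k])}; rounding remainders are assigned to
#' the largest-fraction state, the track order is shuffled, and the true
#' generating state of every track is recorded.
#'
#' @param D,sigma,pi State diffusivities (um^2/s), static noises (um;
#'   recycled), and population fractions (sum to 1).
#' @param M Total number of tracks.
#' @param acq \code{\link{acquisition_params}}.
#' @param n_min,n_max,n_mean Track-length model, see
#'   \code{\link{sample_track_length}}.
#' @param n_micro Micro-steps per frame.
#' @param seed Optional seed set before simulation.
#' @return List of class \code{"sim_tracks"} with \code{tracks} (a
#'   \code{\link{track_set}}), \code{truth} (data.frame \code{id},
#'   \code{state}, in track order), and \code{params}.
#' @examples
#' acq <- acquisition_params(0.032)
#' sim <- simulate_tracks(D = c(0.02, 0.5), sigma = 0.05, pi = c(0.5, 0.5),
#'                        M = 10, acq = acq, seed = 1)
#' table(sim$truth$state)
#' @export
simulate_tracks <- function(D, sigma, pi, M, acq,
                            n_min = 15L, n_max = 60L, n_mean = 25,
                            n_micro = 32L, seed = NULL) {
  stopifnot_acq(acq)
  K <- length(D)
  sigma <- rep_len(sigma, K)
  if (length(pi) != K) stop("'pi' must have one fraction per state")
  if (abs(sum(pi) - 1) > 1e-9) stop("'pi' must sum to 1")
  counts <- round(pi * M)
  counts[which.max(pi)] <- counts[which.max(pi)] + (M - sum(counts))
  if (any(counts < 0)) stop("rounding produced a negative state count")
  if (sum(counts > 0) < sum(pi > 0))
    stop("M too small to represent every state with nonzero fraction")
  if (!is.null(seed)) set.seed(seed)
  labels <- rep(seq_len(K), counts)
  lens <- sample_track_length(M, n_min, n_max, n_mean)
  ord <- sample.int(M)
  labels <- labels[ord]
  tracks <- vector("list", M)
  for (m in seq_len(M)) {
    k <- labels[m]
    tracks[[m]] <- simulate_track(D[k], sigma[k], lens[m], acq, n_micro,
                                  id = sprintf("sim_%05d", m))
  }
  ts <- track_set(tracks, acq)
  truth <- data.frame(id = vapply(tracks, `[[`, character(1), "id"),
                      state = labels)
  structure(list(tracks = ts, truth = truth,
                 params = list(D = D, sigma = sigma, pi = pi, M = M,
                               n_min = n_min, n_max = n_max, n_mean = n_mean,
                               n_micro = n_micro, seed = seed)),
            class = "sim_tracks")
}

#' @export
print.sim_tracks <- function(x, ...) {
  cat(sprintf("Simulated population: M = %d tracks, %d state(s)\n",
              x$params$M, length(x$params$D)))
  print(data.frame(state = seq_along(x$params$D), D = x$params$D,
                   sigma = x$params$sigma, pi = x$params$pi,
                   n_tracks = as.vector(table(factor(x$truth$state,
                                                     seq_along(x$params$D))))),
        row.names = FALSE)
  invisible(x)
}

#' Simulate a trajectory that switches between diffusive states
#'
#' The hidden state evolves frame-to-frame by a Markov chain with the given
#' per-frame transition matrix; micro-steps within a frame use that frame's
#' diffusivity, and the static noise added to a frame's position uses that
#' frame's state. Used to probe robustness of the no-transitions assumption.
#'
#' @param D,sigma Per-state diffusivities (um^2/s) and static noises (um;
#'   recycled).
#' @param P K x K transition matrix; rows sum to 1.
#' @param n_steps Number of displacements.
#' @param acq \code{\link{acquisition_params}}.
#' @param n_micro Micro-steps per frame.
#' @param init_state Initial state; default drawn from the stationary
#'   distribution of \code{P}.
#' @param id Track identifier.
#' @return List with \code{trajectory} and \code{states} (per-frame hidden
#'   labels, length \code{n_steps + 1}).
#' @export
simulate_switching_track <- function(D, sigma, P, n_steps, acq,
                                     n_micro = 32L, init_state = NULL,
                                     id = "sim_switch") {
  stopifnot_acq(acq)
  K <- length(D)
  sigma <- rep_len(sigma, K)
  P <- as.matrix(P)
  if (nrow(P) != K || ncol(P) != K || any(abs(rowSums(P) - 1) > 1e-9))
    stop("'P' must be a K x K matrix with rows summing to 1")
  n_frames <- n_steps + 1L
  if (is.null(init_state)) {
    # stationary distribution: left eigenvector of P for eigenvalue 1
    ev <- eigen(t(P))
    v <- abs(Re(ev$vectors[, which.min(abs(ev$values - 1))]))
    init_state <- sample.int(K, 1L, prob = v / sum(v))
  }
  states <- integer(n_frames)
  states[1L] <- init_state
  for (i in seq_len(n_frames - 1L))
    states[i + 1L] <- sample.int(K, 1L, prob = P[states[i], ])
  n_expose <- max(1L, ceiling(n_micro * acq$exposure_dt / acq$dt))
  micro_sd <- sqrt(2 * D[rep(states, each = n_micro)] * acq$dt / n_micro)
  pos <- matrix(0, n_frames, 2L)
  for (dd in 1:2) {
    micro <- cumsum(c(0, stats::rnorm(n_frames * n_micro - 1L) *
                        micro_sd[-1L]))
    blocks <- matrix(micro, n_micro, n_frames)
    pos[, dd] <- colMeans(blocks[seq_len(n_expose), , drop = FALSE])
  }
  pos <- pos + matrix(stats::rnorm(2L * n_frames) * sigma[states],
                      n_frames, 2L)
  list(trajectory = trajectory(id, pos), states = states)
}
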