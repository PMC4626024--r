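# Internal stacked representation of a track set.
#
# Displacement vectors are zero-padded into an Nmax x M matrix per dimension.
# Because the LDL^T pivots of the tridiagonal Toeplitz covariance for length
# N are the first N pivots of the length-Nmax recursion, a single pivot
# vector per state serves every track; the per-track forward-substitution
# sweep over the whole stack is one compiled pass (.tridiag_loglik), which
# uses only the leading N[m] rows of column m.
stack_tracks <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  M <- length(ts)
  N <- vapply(ts$tracks, n_steps, integer(1))
  Nmax <- max(N)
  X <- list(matrix(0, Nmax, M), matrix(0, Nmax, M))
  msd <- matrix(0, M, 2L)
  lag1 <- matrix(0, M, 2L)
  for (m in seq_len(M)) {
    d <- diff(ts$tracks[[m]]$pos)
    n <- N[m]
    X[[1L]][seq_len(n), m] <- d[, 1L]
    X[[2L]][seq_len(n), m] <- d[, 2L]
    msd[m, ] <- colMeans(d * d)
    lag1[m, ] <- if (n >= 2L)
      colMeans(d[-n, , drop = FALSE] * d[-1L, , drop = FALSE])
    else c(0, 0)
  }
  list(X = X, N = N, msd = msd, lag1 = lag1,
       M = M, Nmax = Nmax, acq = ts$acquisition,
       ids = vapply(ts$tracks, `[[`, character(1), "id"))
}

# Per-track log-likelihoods under one state, one dimension: length-M vector.
loglik_state_dim <- function(st, D, sigma2, dim) {
  bd <- state_band(D, sigma2, st$acq)
  .tridiag_loglik(st$X[[dim]], st$N, bd[["diag"]], bd[["off"]])
}

# Row-wise log-sum-exp normalization: returns list(gamma, lse).
row_posteriors <- function(logw) {
  rmax <- logw[, 1L]
  for (k in seq_len(ncol(logw))[-1L]) rmax <- pmax(rmax, logw[, k])
  bad <- !is.finite(rmax)
  if (any(bad)) {
    warning("degenerate responsibilities for ", sum(bad),
            " track(s); using uniform rows")
    logw[bad, ] <- 0
    rmax[bad] <- 0
  }
  e <- exp(logw - rmax)
  s <- rowSums(e)
  list(gamma = e / s, lse = rmax + log(s))
}

e_step_stacked <- function(st, states, posterior = c("average", "product")) {
  posterior <- match.arg(posterior)
  K <- states$K
  logpi <- log(pmax(states$pi, 1e-300))
  lcomp <- array(0, dim = c(st$M, K, 2L))
  for (k in seq_len(K)) for (dd in 1:2)
    lcomp[, k, dd] <- loglik_state_dim(st, states$D[k], states$sigma[k]^2, dd)
  lx <- matrix(lcomp[, , 1L], st$M, K)
  ly <- matrix(lcomp[, , 2L], st$M, K)
  px <- row_posteriors(sweep(lx, 2L, logpi, "+"))
  py <- row_posteriors(sweep(ly, 2L, logpi, "+"))
  loglik <- sum(px$lse) + sum(py$lse)  # sum of per-dimension log-likelihoods
  gamma <- if (posterior == "average") {
    (px$gamma + py$gamma) / 2
  } else {
    row_posteriors(sweep(lx + ly, 2L, logpi, "+"))$gamma
  }
  list(gamma = gamma, gamma_x = px$gamma, gamma_y = py$gamma,
       loglik = loglik)
}

# gamma_by_dim: list of the per-dimension responsibility matrices actually
# driving each dimension's update (identical matrices = the averaged/shared
# convention).
m_step_stacked <- function(st, gamma_by_dim) {
  dt <- st$acq$dt; R <- st$acq$R
  K <- ncol(gamma_by_dim[[1L]])
  Dkd <- matrix(0, K, 2L)
  s2kd <- matrix(0, K, 2L)
  Mkd <- matrix(0, K, 2L)
  for (dd in 1:2) {
    g <- gamma_by_dim[[dd]]
    Mk <- colSums(g)
    Mkd[, dd] <- Mk
    Dkd[, dd] <- as.vector(crossprod(g, st$msd[, dd] + 2 * st$lag1[, dd])) /
      (2 * dt * pmax(Mk, 1e-300))
    s2kd[, dd] <- as.vector(crossprod(g, st$msd[, dd])) /
      (2 * pmax(Mk, 1e-300)) - Dkd[, dd] * dt * (1 - 2 * R)
  }
  D <- rowMeans(Dkd)
  s2 <- rowMeans(s2kd)
  Mk <- rowMeans(Mkd)  # equals colSums of the dimension-averaged gamma
  collapsed <- Mk < 1e-6
  if (any(collapsed)) {
    warning(sprintf("collapsed state(s) %s kept with floored parameters",
                    paste(which(collapsed), collapse = ",")))
    D[collapsed] <- .D_FLOOR
    s2[collapsed] <- .S2_FLOOR
  }
  diffusive_states(D = D, sigma = sqrt(pmax(s2, 0)), pi = Mk / st$M,
                   acquisition = st$acq, sort_by_D = FALSE)
}

#' Expectation step of the diffusive-state mixture
#'
#' Computes the posterior probability \eqn{\gamma_{mk}} that track \eqn{m}
#' realizes state \eqn{k}, separately per spatial dimension and then averaged
#' over the two dimensions (the isotropic-diffusion convention), together
#' with the complete log-likelihood, which sums the per-dimension mixture
#' log-likelihoods. All arithmetic is in the log domain with log-sum-exp
#' normalization.
#'
#' @param tracks A \code{\link{track_set}}.
#' @param states A \code{\link{diffusive_states}} object (fractions
#'   normalized).
#' @param posterior \code{"average"} (default; per-dimension posteriors
#'   averaged, as used throughout) or \code{"product"} (posterior from the
#'   product of the two per-dimension likelihoods, for comparison).
#' @return List with \code{gamma} (M x K matrix, rows summing to 1),
#'   \code{gamma_x} and \code{gamma_y} (the per-dimension posteriors), and
#'   \code{loglik} (nats).
#' @export
e_step <- function(tracks, states, posterior = c("average", "product")) {
  e_step_stacked(stack_tracks(tracks), states, match.arg(posterior))
}

#' Maximization step of the diffusive-state mixture
#'
#' Covariance-based (CVE) update: per dimension,
#' \deqn{D_k = \frac{1}{2\Delta t M_k}\sum_m \gamma_{mk}
#'   (\langle\Delta x_m^2\rangle + 2\langle\Delta x_m(n)\Delta x_m(n+1)\rangle)}
#' \deqn{\sigma_k^2 = \frac{1}{2M_k}\sum_m \gamma_{mk}
#'   \langle\Delta x_m^2\rangle - D_k\Delta t(1-2R)}
#' with \eqn{M_k = \sum_m \gamma_{mk}}; per-dimension estimates are then
#' averaged, and \eqn{\pi_k = M_k/M}. Per-track means weight every track
#' equally regardless of its length (no pooling of displacements). Because
#' this update is a moment (covariance-based) expression rather than the
#' exact maximizer of the EM surrogate, the iteration is a fixed-point
#' scheme: the log-likelihood rises steeply, may overshoot by a small amount,
#' and then relaxes geometrically onto the fixed point, so the trace is not
#' guaranteed to be exactly non-decreasing (see the methods vignette). States
#' whose effective membership \eqn{M_k} collapses below 1e-6 are kept with
#' floored parameters (deleting a state mid-run would change the model size).
#'
#' @param tracks A \code{\link{track_set}}.
#' @param gamma M x K posterior matrix with rows summing to 1, applied to
#'   both spatial dimensions. (Inside \code{\link{run_em}} each dimension is
#'   by default driven by its own per-dimension posterior; supplying one
#'   matrix here corresponds to the shared-gamma convention, and the two
#'   coincide for hard labels or K = 1.)
#' @param acq \code{\link{acquisition_params}}; defaults to the track set's.
#' @return A \code{\link{diffusive_states}} object (unsorted, so state
#'   indices stay aligned with the columns of \code{gamma}).
#' @export
m_step <- function(tracks, gamma, acq = tracks$acquisition) {
  st <- stack_tracks(tracks)
  st$acq <- acq
  gamma <- as.matrix(gamma)
  if (nrow(gamma) != st$M) stop("'gamma' must have one row per track")
  m_step_stacked(st, list(gamma, gamma))
}

#' Run expectation-maximization to convergence
#'
#' Alternates \code{\link{e_step}} and \code{\link{m_step}} from an initial
#' state set until the relative change in the complete log-likelihood falls
#' below \code{tol} or \code{max_iter} iterations are reached.
#'
#' @param tracks A \code{\link{track_set}}.
#' @param init Initial \code{\link{diffusive_states}} (e.g. from
#'   \code{\link{random_init}}).
#' @param tol Relative log-likelihood change threshold (default 1e-7).
#' @param max_iter Maximum number of EM iterations (default 500). With
#'   \code{max_iter = 0} the initial parameters are returned with a
#'   single-point likelihood trace.
#' @param posterior Convention for the REPORTED posterior matrix, passed to
#'   \code{\link{e_step}}.
#' @param gamma_mode Which responsibilities drive each dimension's M-step
#'   update: \code{"per_dim"} (default) uses the posterior computed from
#'   that dimension's own displacements, making each dimension's update a
#'   complete 1D M-step before the parameter estimates are averaged across
#'   dimensions; \code{"averaged"} drives both dimensions with the
#'   dimension-averaged posterior. The averaged variant blurs state
#'   assignments and can merge nearby states (see the methods vignette).
#' @param sort_states Sort the returned states by ascending D (default
#'   \code{TRUE}); posterior columns are permuted to match.
#' @return Object of class \code{"pem_em"}: list with \code{states},
#'   \code{gamma}, \code{loglik}, \code{loglik_trace}, \code{n_iter},
#'   \code{converged}.
#' @export
run_em <- function(tracks, init, tol = 1e-7, max_iter = 500L,
                   posterior = c("average", "product"),
                   gamma_mode = c("per_dim", "averaged"),
                   sort_states = TRUE) {
  st <- stack_tracks(tracks)
  run_em_stacked(st, init, tol, max_iter, match.arg(posterior),
                 match.arg(gamma_mode), sort_states)
}

run_em_stacked <- function(st, init, tol = 1e-7, max_iter = 500L,
                           posterior = "average", gamma_mode = "per_dim",
                           sort_states = TRUE) {
  stopifnot(inherits(init, "diffusive_states"))
  cur <- init
  es <- e_step_stacked(st, cur, posterior)
  if (!is.finite(es$loglik))
    stop("non-finite log-likelihood at initialization; states: ",
         paste(sprintf("(D=%.3g, sigma=%.3g, pi=%.3g)",
                       cur$D, cur$sigma, cur$pi), collapse = " "))
  trace <- es$loglik
  converged <- FALSE
  iter <- 0L
  gbd <- function(es) {
    if (gamma_mode == "per_dim") list(es$gamma_x, es$gamma_y)
    else list(es$gamma, es$gamma)
  }
  while (iter < max_iter) {
    cur <- m_step_stacked(st, gbd(es))
    es <- e_step_stacked(st, cur, posterior)
    iter <- iter + 1L
    if (!is.finite(es$loglik))
      stop("non-finite log-likelihood at iteration ", iter, "; states: ",
           paste(sprintf("(D=%.3g, sigma=%.3g, pi=%.3g)",
                         cur$D, cur$sigma, cur$pi), collapse = " "))
    trace <- c(trace, es$loglik)
    n <- length(trace)
    if (abs(trace[n] - trace[n - 1L]) / max(abs(trace[n]), 1e-300) < tol) {
      converged <- TRUE
      break
    }
  }
  gamma <- es$gamma
  if (sort_states) {
    o <- order(cur$D)
    cur <- diffusive_states(cur$D[o], cur$sigma[o], cur$pi[o],
                            cur$acquisition, sort_by_D = FALSE)
    gamma <- gamma[, o, drop = FALSE]
  }
  rownames(gamma) <- st$ids
  structure(list(states = cur, gamma = gamma,
                 loglik = trace[length(trace)], loglik_trace = trace,
                 n_iter = iter, converged = converged,
                 M = st$M, K = cur$K),
            class = "pem_em")
}

#' @export
print.pem_em <- function(x, ...) {
  cat(sprintf("EM fit: K = %d, M = %d tracks, lnL = %.4f, %d iteration(s)%s\n",
              x$K, x$M, x$loglik, x$n_iter,
              if (x$converged) " (converged)" else " (not converged)"))
  print(x$states)
  invisible(x)
}
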