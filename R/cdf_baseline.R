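#' Multi-component CDF baseline fit to squared displacements
#'
#' The classical alternative to the mixture likelihood: pool the squared 2D
#' frame-to-frame displacements \eqn{\Delta r^2 = \Delta x^2 + \Delta y^2}
#' over all tracks and fit their empirical cumulative distribution with
#' \deqn{CDF(\Delta r^2) = 1 - \sum_{k=1}^{K} \pi_k e^{-\Delta r^2 /(2\rho_k)}}
#' where \eqn{\rho_k = 2 D_k \Delta t + 2\sigma^2 - 4 R D_k \Delta t}. The
#' static noise \eqn{\sigma} must be supplied: the baseline cannot estimate
#' it (this is one of its documented weaknesses). Free parameters are
#' \eqn{\rho_1..\rho_K} and \eqn{\pi_1..\pi_{K-1}} with
#' \eqn{\pi_K = 1 - \sum_{j<K}\pi_j}; diffusivities are back-computed from
#' \eqn{\rho_k}. Fitting uses Levenberg-Marquardt least squares with box
#' constraints (\eqn{\rho_k > 0}, \eqn{0 \le \pi_j \le 1}), evaluated at
#' every observed \eqn{\Delta r^2}.
#'
#' @param tracks A \code{\link{track_set}}.
#' @param K Number of components.
#' @param sigma Known static localization noise (um).
#' @param init Optional starting values: list with \code{D} (length K) and
#'   \code{pi} (length K, summing to 1). Default: CVE diffusivity quantiles
#'   at equally spaced levels and equal fractions.
#' @return Object of class \code{"cdf_fit"}: list with \code{states}
#'   (data.frame \code{D}, \code{pi}, \code{rho}, sorted by ascending D),
#'   \code{residual} (sum of squared CDF residuals), \code{converged},
#'   \code{n_displacements}. Non-convergence is flagged, never thrown: the
#'   last iterate is returned with \code{converged = FALSE}.
#' @examples
#' \donttest{
#' acq <- acquisition_params(0.032)
#' sim <- simulate_tracks(D = 0.5, sigma = 0.05, pi = 1, M = 100, acq = acq,
#'                        seed = 1)
#' fit_cdf(sim$tracks, K = 1, sigma = 0.05)
#' }
#' @export
fit_cdf <- function(tracks, K, sigma, init = NULL) {
  stopifnot(inherits(tracks, "track_set"))
  acq <- tracks$acquisition
  dt <- acq$dt; R <- acq$R
  dr2 <- sort(unlist(lapply(tracks$tracks, function(t) {
    d <- diff(t$pos)
    d[, 1L]^2 + d[, 2L]^2
  }), use.names = FALSE))
  n <- length(dr2)
  emp <- seq_len(n) / n
  rho_of_D <- function(D) 2 * D * dt + 2 * sigma^2 - 4 * R * D * dt
  D_of_rho <- function(rho) (rho - 2 * sigma^2) / (2 * dt * (1 - 2 * R))
  if (is.null(init)) {
    cvD <- cve(tracks)$D
    D0 <- as.numeric(stats::quantile(cvD, probs = (seq_len(K) - 0.5) / K,
                                     type = 1, names = FALSE))
    init <- list(D = D0, pi = rep(1 / K, K))
  }
  rho0 <- pmax(rho_of_D(init$D), 1e-8)
  model_cdf <- function(rho, pifree) {
    piK <- c(pifree, 1 - sum(pifree))
    1 - colSums(piK * exp(-outer(1 / (2 * rho), dr2)))
  }
  resid_fn <- function(par) {
    rho <- par[seq_len(K)]
    pifree <- if (K > 1L) par[K + seq_len(K - 1L)] else numeric(0)
    emp - model_cdf(rho, pifree)
  }
  par0 <- c(rho0, if (K > 1L) init$pi[seq_len(K - 1L)])
  lower <- c(rep(1e-10, K), rep(0, K - 1L))
  upper <- c(rep(Inf, K), rep(1, K - 1L))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    par <- par0
    converged <- FALSE
  } else {
    par <- fit$par
    # info codes 1-3 indicate convergence of the LM iteration
    converged <- fit$info %in% 1:3
  }
  rho <- par[seq_len(K)]
  pifree <- if (K > 1L) par[K + seq_len(K - 1L)] else numeric(0)
  piK <- c(pifree, 1 - sum(pifree))
  o <- order(rho)
  states <- data.frame(D = D_of_rho(rho[o]), pi = piK[o], rho = rho[o])
  structure(list(states = states,
                 residual = sum(resid_fn(par)^2),
                 converged = converged, n_displacements = n,
                 sigma = sigma),
            class = "cdf_fit")
}

#' @export
print.cdf_fit <- function(x, digits = 4, ...) {
  cat(sprintf(
    "CDF baseline fit: %d component(s), %d pooled displacements%s\n",
    nrow(x$states), x$n_displacements,
    if (x$converged) "" else " (NOT converged)"))
  print(data.frame(state = seq_len(nrow(x$states)),
                   D = signif(x$states$D, digits),
                   pi = signif(x$states$pi, digits),
                   rho = signif(x$states$rho, digits)), row.names = FALSE)
  invisible(x)
}
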