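# CVE per-track estimates from the stacked representation (dimension-averaged)
stacked_cve <- function(st) {
  dt <- st$acq$dt; R <- st$acq$R
  Dd <- (st$msd + 2 * st$lag1) / (2 * dt)
  s2d <- st$msd / 2 - Dd * dt * (1 - 2 * R)
  list(D = rowMeans(Dd), sigma2 = rowMeans(s2d))
}

stack_subset <- function(st, idx) {
  list(X = lapply(st$X, function(x) x[, idx, drop = FALSE]), N = st$N[idx],
       msd = st$msd[idx, , drop = FALSE], lag1 = st$lag1[idx, , drop = FALSE],
       M = length(idx), Nmax = st$Nmax, acq = st$acq, ids = st$ids[idx])
}

random_init_stacked <- function(st, K) {
  cv <- stacked_cve(st)
  u <- stats::runif(K)
  pi0 <- u / sum(u)
  # midpoint of region k of the empirical cumulative diffusivity distribution
  levels <- cumsum(pi0) - pi0 / 2
  D0 <- as.numeric(stats::quantile(cv$D, probs = levels, type = 1,
                                   names = FALSE))
  s2bar <- max(mean(cv$sigma2), .S2_FLOOR)
  diffusive_states(D = D0, sigma = rep(sqrt(s2bar), K), pi = pi0,
                   acquisition = st$acq, sort_by_D = FALSE)
}

#' Random initialization for the diffusive-state mixture
#'
#' Draws K uniform numbers and normalizes them into initial population
#' fractions; initial diffusivities are the empirical quantiles of the
#' per-track CVE diffusivity distribution at the midpoints of the K regions
#' the fractions delimit (a non-parametric draw from the observed diffusivity
#' distribution); the initial static noise is the population mean of the
#' per-track CVE noise estimates, identical for all states.
#'
#' @param tracks A \code{\link{track_set}}.
#' @param K Number of diffusive states.
#' @return A \code{\link{diffusive_states}} object (unsorted, in draw order).
#' @export
random_init <- function(tracks, K) {
  random_init_stacked(stack_tracks(tracks), K)
}

#' Monte-Carlo bootstrap resample of a track set
#'
#' Samples M track indices with replacement (M = number of tracks), so some
#' tracks appear multiple times and others not at all. Resampling perturbs
#' the mixture likelihood surface; pEM exploits this to dislodge EM from
#' local maxima.
#'
#' @param tracks A \code{\link{track_set}}.
#' @return A \code{\link{track_set}} of the same size.
#' @export
bootstrap_resample <- function(tracks) {
  M <- length(tracks)
  tracks[sample.int(M, M, replace = TRUE)]
}

pem_fit_stacked <- function(st, K, n_restarts = 10L, n_perturb = 20L,
                            tol = 1e-7, max_iter = 500L,
                            posterior = "average", gamma_mode = "per_dim") {
  best <- NULL
  restart_loglik <- numeric(n_restarts)
  plain_loglik <- numeric(n_restarts)
  n_accepted <- 0L
  for (r in seq_len(n_restarts)) {
    res <- try({
      init <- random_init_stacked(st, K)
      fit <- run_em_stacked(st, init, tol, max_iter, posterior, gamma_mode)
      plain <- fit$loglik
      fruitless <- 0L
      accepted <- 0L
      while (fruitless < n_perturb) {
        idx <- sample.int(st$M, st$M, replace = TRUE)
        bfit <- run_em_stacked(stack_subset(st, idx), fit$states,
                               tol, max_iter, posterior, gamma_mode,
                               sort_states = FALSE)
        # verification: only upward moves on the original likelihood surface.
        # The refit from the candidate parameters is adopted only if its own
        # converged likelihood improves on the incumbent, so the sequence of
        # adopted parameter sets is strictly increasing by construction.
        cand <- e_step_stacked(st, bfit$states, posterior)$loglik
        adopted <- FALSE
        if (is.finite(cand) && cand > fit$loglik) {
          refit <- run_em_stacked(st, bfit$states, tol, max_iter, posterior,
                                  gamma_mode)
          if (refit$loglik > fit$loglik) {
            fit <- refit
            adopted <- TRUE
          }
        }
        if (adopted) {
          accepted <- accepted + 1L
          fruitless <- 0L
        } else {
          fruitless <- fruitless + 1L
        }
      }
      list(fit = fit, plain = plain, accepted = accepted)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      warning(sprintf("restart %d of K=%d failed: %s", r, K,
                      attr(res, "condition")$message))
      restart_loglik[r] <- NA_real_
      plain_loglik[r] <- NA_real_
      next
    }
    restart_loglik[r] <- res$fit$loglik
    plain_loglik[r] <- res$plain
    n_accepted <- n_accepted + res$accepted
    if (is.null(best) || res$fit$loglik > best$loglik) best <- res$fit
  }
  if (is.null(best)) stop("all ", n_restarts, " restarts failed for K = ", K)
  best$restart_loglik <- restart_loglik
  best$plain_loglik <- plain_loglik
  best$n_perturb_accepted <- n_accepted
  best
}

#' Fit a K-state mixture by perturbation expectation-maximization
#'
#' For each random restart, runs EM on the original tracks, then repeatedly
#' perturbs the likelihood surface with a Monte-Carlo bootstrap resample:
#' EM is run on the resample initialized at the current parameters, and the
#' resulting parameters are verified by evaluating their likelihood on the
#' original data. Only verified improvements are adopted (after re-running EM
#' on the original data from the candidate parameters), so the sequence of
#' adopted parameter sets moves strictly upward on the unperturbed likelihood
#' surface. A restart stops after \code{n_perturb} consecutive fruitless
#' trials; the best restart is returned. With \code{n_perturb = 0} this
#' reduces to best-of-restarts plain EM.
#'
#' @inheritParams run_em
#' @param K Number of diffusive states.
#' @param n_restarts Number of random initializations (default 10).
#' @param n_perturb Consecutive fruitless perturbation trials before a
#'   restart stops (default 20).
#' @return A \code{"pem_em"} object (see \code{\link{run_em}}) with extra
#'   fields \code{restart_loglik}, \code{plain_loglik} (per-restart
#'   log-likelihood before any perturbation), and \code{n_perturb_accepted}.
#' @export
pem_fit <- function(tracks, K, n_restarts = 10L, n_perturb = 20L,
                    tol = 1e-7, max_iter = 500L,
                    posterior = c("average", "product"),
                    gamma_mode = c("per_dim", "averaged")) {
  pem_fit_stacked(stack_tracks(tracks), K, n_restarts, n_perturb,
                  tol, max_iter, match.arg(posterior), match.arg(gamma_mode))
}

#' Uncover diffusive states from a trajectory population
#'
#' The main fitting front-end: runs perturbation expectation-maximization
#' (\code{\link{pem_fit}}) for each candidate number of diffusive states and
#' selects the model size by the Bayesian information criterion
#' \deqn{BIC = \ln L - K \ln M,} where M is the number of trajectories; the
#' largest BIC wins and ties break toward smaller K (parsimony).
#'
#' @param tracks A \code{\link{track_set}}.
#' @param K Candidate numbers of diffusive states (default \code{1:6}).
#' @param n_restarts,n_perturb,tol,max_iter,posterior,gamma_mode EM and
#'   perturbation controls, see \code{\link{pem_fit}} and
#'   \code{\link{run_em}}.
#' @param penalty \code{"states"} (default): penalty \eqn{K \ln M} as in the
#'   BIC formula above; \code{"parameters"}: the conventional
#'   \eqn{((3K-1)/2)\ln M} counting all free parameters, for sensitivity
#'   analysis.
#' @param seed Optional integer seed set before the sweep; with a fixed seed
#'   the entire sweep is reproducible.
#' @param verbose Print one progress line per candidate K.
#' @return Object of class \code{"pem"}: list with \code{models} (one
#'   \code{"pem_em"} per K), \code{table} (per-K log-likelihood and BIC),
#'   \code{selected_K}, \code{selected} (best model), \code{cve}
#'   (per-track CVE estimates), \code{M}, \code{acquisition}, \code{call}.
#' @examples
#' \donttest{
#' acq <- acquisition_params(0.032)
#' sim <- simulate_tracks(D = c(0.02, 0.5), sigma = 0.05, pi = c(0.5, 0.5),
#'                        M = 200, acq = acq, seed = 1)
#' fit <- pem(sim$tracks, K = 1:3, n_restarts = 2, n_perturb = 2, seed = 1)
#' fit
#' coef(fit)
#' }
#' @export
pem <- function(tracks, K = 1:6, n_restarts = 10L, n_perturb = 20L,
                tol = 1e-7, max_iter = 500L,
                posterior = c("average", "product"),
                gamma_mode = c("per_dim", "averaged"),
                penalty = c("states", "parameters"),
                seed = NULL, verbose = FALSE) {
  stopifnot(inherits(tracks, "track_set"))
  posterior <- match.arg(posterior)
  gamma_mode <- match.arg(gamma_mode)
  penalty <- match.arg(penalty)
  K <- sort(unique(as.integer(K)))
  if (any(K < 1L)) stop("candidate K must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  st <- stack_tracks(tracks)
  models <- vector("list", length(K))
  names(models) <- paste0("K", K)
  for (i in seq_along(K)) {
    models[[i]] <- pem_fit_stacked(st, K[i], n_restarts, n_perturb,
                                   tol, max_iter, posterior, gamma_mode)
    if (verbose)
      message(sprintf("K = %d: lnL = %.4f (%d perturbation(s) accepted)",
                      K[i], models[[i]]$loglik,
                      models[[i]]$n_perturb_accepted))
  }
  ll <- vapply(models, `[[`, numeric(1), "loglik")
  bic <- bic_score(ll, K, st$M, penalty)
  sel <- which.max(bic)  # first maximum: ties break toward smaller K
  tab <- data.frame(K = K, loglik = ll, BIC = bic,
                    converged = vapply(models, `[[`, logical(1), "converged"),
                    n_iter = vapply(models, `[[`, integer(1), "n_iter"),
                    row.names = NULL)
  structure(list(models = models, table = tab,
                 selected_K = K[sel], selected = models[[sel]],
                 cve = data.frame(id = st$ids, D = stacked_cve(st)$D,
                                  sigma2 = stacked_cve(st)$sigma2),
                 M = st$M, acquisition = tracks$acquisition,
                 penalty = penalty, call = match.call()),
            class = "pem")
}

#' BIC score for a diffusive-state mixture
#'
#' @param loglik Maximized log-likelihood(s).
#' @param K Corresponding number(s) of states.
#' @param M Number of trajectories.
#' @param penalty \code{"states"} for \eqn{\ln L - K\ln M} (the convention
#'   used for model selection here) or \code{"parameters"} for
#'   \eqn{\ln L - ((3K-1)/2)\ln M}.
#' @return Numeric vector of BIC scores (larger is better).
#' @export
bic_score <- function(loglik, K, M, penalty = c("states", "parameters")) {
  penalty <- match.arg(penalty)
  p <- switch(penalty, states = K, parameters = (3 * K - 1) / 2)
  loglik - p * log(M)
}
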