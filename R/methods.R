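#' @export
print.pem <- function(x, digits = 4, ...) {
  cat("Perturbation-EM diffusive-state analysis\n")
  cat(sprintf("  %d trajectories; candidate K = %s; selected K = %d\n",
              x$M, paste(x$table$K, collapse = ", "), x$selected_K))
  cat(sprintf("  lnL = %.4f, BIC = %.4f\n",
              x$selected$loglik, x$table$BIC[x$table$K == x$selected_K]))
  print(x$selected$states, digits = digits)
  invisible(x)
}

#' @export
summary.pem <- function(object, ...) {
  structure(list(table = object$table, selected_K = object$selected_K,
                 states = object$selected$states,
                 M = object$M,
                 classification = map_classify(object$selected$gamma),
                 penalty = object$penalty),
            class = "summary.pem")
}

#' @export
print.summary.pem <- function(x, digits = 4, ...) {
  cat("Model sweep (BIC = lnL - K ln M",
      if (x$penalty == "parameters") ", parameter-counting penalty", "):\n",
      sep = "")
  tab <- x$table
  tab$loglik <- round(tab$loglik, 3)
  tab$BIC <- round(tab$BIC, 3)
  tab$selected <- ifelse(tab$K == x$selected_K, "*", "")
  print(tab, row.names = FALSE)
  cat(sprintf("\nSelected model (K = %d):\n", x$selected_K))
  print(x$states, digits = digits)
  tb <- table(factor(x$classification$state, levels = seq_len(x$states$K)))
  cat("\nMAP classification counts per state:\n")
  print(tb)
  invisible(x)
}

#' @export
coef.pem <- function(object, ...) {
  as.data.frame(object$selected$states)
}

#' @export
logLik.pem <- function(object, ...) {
  K <- object$selected_K
  structure(object$selected$loglik, df = 3 * K - 1, nobs = object$M,
            class = "logLik")
}

#' Posterior state membership or MAP classification for tracks
#'
#' @param object A fitted \code{"pem"} object.
#' @param newdata Optional \code{\link{track_set}} to classify under the
#'   selected model; defaults to the training tracks' stored posteriors.
#' @param type \code{"class"} for MAP labels with confidences (a data.frame),
#'   \code{"posterior"} for the full M x K posterior matrix.
#' @param ... Unused.
#' @return See \code{type}.
#' @export
predict.pem <- function(object, newdata = NULL,
                        type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  gamma <- if (is.null(newdata)) {
    object$selected$gamma
  } else {
    e_step(newdata, object$selected$states)$gamma
  }
  if (type == "posterior") return(gamma)
  map_classify(gamma)
}

#' Plot a fitted diffusive-state analysis
#'
#' \code{which = "bic"} draws the BIC model-selection curve over candidate K;
#' \code{which = "states"} draws the empirical cumulative distribution of the
#' per-track CVE diffusivities with the fitted state diffusivities marked at
#' heights equal to the cumulative population fractions.
#'
#' @param x A \code{"pem"} object.
#' @param which \code{"bic"} or \code{"states"}.
#' @param ... Passed to the underlying plot call.
#' @return \code{x}, invisibly.
#' @export
plot.pem <- function(x, which = c("bic", "states"), ...) {
  which <- match.arg(which)
  if (which == "bic") {
    graphics::plot(x$table$K, x$table$BIC, type = "b", pch = 19,
                   xlab = "number of diffusive states K", ylab = "BIC", ...)
    graphics::abline(v = x$selected_K, lty = 2, col = "grey50")
  } else {
    d <- sort(x$cve$D)
    graphics::plot(d, seq_along(d) / length(d), type = "s",
                   xlab = expression(D ~ (mu * m^2 / s)),
                   ylab = "cumulative probability", ...)
    st <- x$selected$states
    graphics::abline(v = st$D, lty = 3, col = "grey60")
    graphics::points(st$D, cumsum(st$pi) - st$pi / 2, pch = 19)
  }
  invisible(x)
}

#' Simulate trajectory populations from a fitted model
#'
#' Draws synthetic track sets from the selected model's diffusive states,
#' using the same simulator (motion blur + static noise + random track
#' lengths) as \code{\link{simulate_tracks}}.
#'
#' @param object A fitted \code{"pem"} object.
#' @param nsim Number of replicate track sets.
#' @param seed Optional seed.
#' @param M Number of tracks per replicate (default: size of the fitted
#'   data).
#' @param ... Passed to \code{\link{simulate_tracks}}.
#' @return A list of \code{nsim} results of \code{\link{simulate_tracks}}.
#' @export
simulate.pem <- function(object, nsim = 1, seed = NULL, M = object$M, ...) {
  if (!is.null(seed)) set.seed(seed)
  st <- object$selected$states
  lapply(seq_len(nsim), function(i) {
    simulate_tracks(D = st$D, sigma = st$sigma, pi = st$pi, M = M,
                    acq = object$acquisition, ...)
  })
}
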