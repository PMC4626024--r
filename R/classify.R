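#' Maximum-a-posteriori classification of tracks
#'
#' Assigns each track to the diffusive state realizing its maximum posterior
#' probability. Ties break to the lowest state index, deterministically.
#' Definitive classification discards the confidence information carried by
#' the posterior, so the full row maximum is reported alongside the label.
#'
#' @param gamma M x K posterior matrix with rows summing to 1.
#' @return data.frame with columns \code{id} (rownames of \code{gamma}, if
#'   any), \code{state} (MAP label), \code{confidence} (the row maximum,
#'   always >= 1/K).
#' @export
map_classify <- function(gamma) {
  gamma <- as.matrix(gamma)
  state <- max.col(gamma, ties.method = "first")
  conf <- gamma[cbind(seq_len(nrow(gamma)), state)]
  ids <- rownames(gamma)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(gamma)))
  data.frame(id = ids, state = state, confidence = conf, row.names = NULL)
}

#' Posterior-weighted spatial map for one diffusive state
#'
#' Emits one row per track with its spatial centroid and its posterior
#' membership in the chosen state, the data behind posterior-weighted
#' localization heat maps (rendering, e.g. with transparency proportional to
#' the weight, is left to the caller).
#'
#' @param tracks A \code{\link{track_set}}.
#' @param gamma M x K posterior matrix aligned with \code{tracks}.
#' @param state State index k.
#' @return data.frame with columns \code{id}, \code{centroid_x},
#'   \code{centroid_y} (um), \code{weight} (= gamma[, k]).
#' @export
posterior_weighted_map <- function(tracks, gamma, state) {
  stopifnot(inherits(tracks, "track_set"))
  gamma <- as.matrix(gamma)
  if (nrow(gamma) != length(tracks))
    stop("'gamma' must have one row per track")
  if (!(state %in% seq_len(ncol(gamma)))) stop("invalid state index")
  cen <- t(vapply(tracks$tracks, function(t) colMeans(t$pos), numeric(2)))
  data.frame(id = vapply(tracks$tracks, `[[`, character(1), "id"),
             centroid_x = cen[, 1L], centroid_y = cen[, 2L],
             weight = gamma[, state], row.names = NULL)
}

#' Decompose a diffusivity distribution between two reference conditions
#'
#' Finds the weight w in [0, 1] minimizing the squared difference between a
#' target empirical cumulative diffusivity distribution and the convex
#' combination \eqn{w F_a + (1-w) F_b} of two reference distributions, all
#' evaluated on the pooled grid of observed diffusivities (exact empirical
#' CDFs, no binning). Used to express an intermediate population (e.g. wild
#' type) as a mixture of two extreme conditions (e.g. constitutively active
#' vs dominant negative mutants). The one-parameter least squares has the
#' closed form \eqn{w = \sum (F_a-F_b)(F_t-F_b) / \sum (F_a-F_b)^2}, clipped
#' to [0, 1].
#'
#' @param target,ref_a,ref_b Numeric vectors of per-track diffusivity
#'   estimates (e.g. the \code{D} column of \code{\link{cve}}) for the three
#'   populations.
#' @return List with \code{weight} (similarity to \code{ref_a}),
#'   \code{residual} (sum of squared CDF differences at the optimum), and
#'   \code{grid} (evaluation points).
#' @examples
#' a <- c(0.1, 0.2, 0.3); b <- c(1, 2, 3)
#' decompose_activation(a, a, b)$weight  # 1
#' @export
decompose_activation <- function(target, ref_a, ref_b) {
  grid <- sort(unique(c(target, ref_a, ref_b)))
  Ft <- stats::ecdf(target)(grid)
  Fa <- stats::ecdf(ref_a)(grid)
  Fb <- stats::ecdf(ref_b)(grid)
  dab <- Fa - Fb
  denom <- sum(dab^2)
  if (denom < 1e-12) {
    warning("reference distributions are indistinguishable; weight undefined, returning 0.5")
    w <- 0.5
  } else {
    w <- sum(dab * (Ft - Fb)) / denom
    w <- min(max(w, 0), 1)
  }
  list(weight = w, residual = sum((Ft - (w * Fa + (1 - w) * Fb))^2),
       grid = grid)
}
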