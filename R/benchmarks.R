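#' Benchmark diffusive-state configurations
#'
#' Two four-state mixtures used throughout the package's tests and examples,
#' spanning the diffusivity range typical of membrane-protein sptPALM
#' (roughly 0.001-1 um^2/s) with constant static noise 0.05 um and equal,
#' well-represented fractions:
#' \describe{
#'   \item{\code{"separated"}}{four well-separated states whose per-track
#'     CVE diffusivity distributions barely overlap at typical track lengths
#'     (D = 0.002, 0.035, 0.2, 0.7 um^2/s);}
#'   \item{\code{"overlapping"}}{four states with neighbouring diffusivities
#'     within a factor 2-4 of each other, whose single-track distributions
#'     overlap substantially (D = 0.02, 0.08, 0.2, 0.45 um^2/s).}
#' }
#' These are the standard difficulty regimes for model-size recovery: the
#' separated set should be resolved from a few hundred tracks, the
#' overlapping set is harder but still well-represented.
#'
#' @param name \code{"separated"} or \code{"overlapping"}.
#' @return List with \code{D}, \code{sigma}, \code{pi} suitable for
#'   \code{\link{simulate_tracks}}.
#' @examples
#' benchmark_states("separated")
#' @export
benchmark_states <- function(name = c("separated", "overlapping")) {
  name <- match.arg(name)
  switch(name,
         separated = list(D = c(0.002, 0.035, 0.2, 0.7),
                          sigma = rep(0.05, 4), pi = rep(0.25, 4)),
         overlapping = list(D = c(0.02, 0.08, 0.2, 0.45),
                            sigma = rep(0.05, 4), pi = rep(0.25, 4)))
}
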