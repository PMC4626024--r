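#' Acquisition parameters for a tracking experiment
#'
#' Bundles the camera timing constants that enter the displacement covariance
#' model: the frame interval \eqn{\Delta t}, the exposure time
#' \eqn{\Delta t_E}, and the motion-blur coefficient \eqn{R}.
#'
#' For a shutter that stays open during the whole exposure, the apparent
#' position recorded in a frame is the time average of the true position over
#' the exposure, which attenuates the observed displacement variance. Under
#' normal diffusion this effect is captured by a single dimensionless
#' coefficient \eqn{R \approx (1/6)\,\Delta t_E/\Delta t}; full-frame exposure
#' gives the common value \eqn{R = 1/6}.
#'
#' @param dt Frame interval in seconds (time between successive recorded
#'   positions). Must be positive.
#' @param exposure_dt Exposure time in seconds, \code{0 <= exposure_dt <= dt}.
#'   Defaults to \code{dt} (shutter open for the full frame).
#' @param R Motion-blur coefficient. Defaults to
#'   \code{(1/6) * exposure_dt / dt}; may be overridden if known from shutter
#'   calibration. Must lie in \eqn{[0, 1/4]}.
#'
#' @return An object of class \code{"acquisition_params"}: a list with
#'   elements \code{dt}, \code{exposure_dt}, and \code{R}.
#'
#' @examples
#' acq <- acquisition_params(dt = 0.032)
#' acq$R  # 1/6
#' @export
acquisition_params <- function(dt, exposure_dt = dt, R = exposure_dt / dt / 6) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number (seconds)")
  if (!is.numeric(exposure_dt) || length(exposure_dt) != 1L ||
      !is.finite(exposure_dt) || exposure_dt < 0 || exposure_dt > dt)
    stop("'exposure_dt' must lie in [0, dt]")
  if (!is.numeric(R) || length(R) != 1L || !is.finite(R) || R < 0 || R > 0.25)
    stop("motion-blur coefficient 'R' must lie in [0, 1/4]")
  structure(list(dt = dt, exposure_dt = exposure_dt, R = R),
            class = "acquisition_params")
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat(sprintf("Acquisition: dt = %g s, exposure = %g s, R = %.4g\n",
              x$dt, x$exposure_dt, x$R))
  invisible(x)
}

stopifnot_acq <- function(acq) {
  if (!inherits(acq, "acquisition_params"))
    stop("'acquisition' must be created with acquisition_params()")
  invisible(acq)
}
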