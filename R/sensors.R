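#' Sensor configuration
#'
#' Describes the measurement chain: electromagnetic flowmeters whose
#' signals are denoised with a first-order low-pass filter, and a
#' camera-based reservoir level readout emulated as additive Gaussian
#' noise followed by quantisation (the pixel resolution of the image
#' analysis).
#'
#' @param flow_noise_sd Flowmeter noise standard deviation, L/min.
#' @param lowpass_cutoff Low-pass filter cutoff for flow signals, Hz.
#' @param level_noise_sd Level readout noise standard deviation, L.
#' @param level_quantum Level quantisation step, L (0 disables
#'   quantisation).
#' @return An object of class `sensor_config`.
#' @export
sensor_config <- function(flow_noise_sd = 0.05, lowpass_cutoff = 1,
                          level_noise_sd = 0.002, level_quantum = 0.005) {
  if (flow_noise_sd < 0 || level_noise_sd < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  if (lowpass_cutoff <= 0) stop("lowpass_cutoff must be > 0", call. = FALSE)
  if (level_quantum < 0) stop("level_quantum must be >= 0", call. = FALSE)
  structure(list(flow_noise_sd = flow_noise_sd,
                 lowpass_cutoff = lowpass_cutoff,
                 level_noise_sd = level_noise_sd,
                 level_quantum = level_quantum),
            class = "sensor_config")
}

#' Initialise a flow low-pass filter
#'
#' First-order low-pass discretised by pole matching:
#' `alpha = 1 - exp(-2 * pi * fc * dt)`, so the discrete pole equals the
#' continuous pole and the -3 dB point sits at the configured cutoff.
#'
#' @param sensor A [sensor_config()].
#' @param dt Sample interval, seconds.
#' @param initial Initial filter output, L/min (start at the true signal
#'   to avoid an artificial warm-up transient).
#' @return A filter state list with elements `y` and `alpha`.
#' @export
flow_filter_init <- function(sensor, dt, initial = 0) {
  stopifnot(inherits(sensor, "sensor_config"), dt > 0)
  list(y = initial, alpha = 1 - exp(-2 * pi * sensor$lowpass_cutoff * dt))
}

#' Measure a flow signal
#'
#' Adds Gaussian flowmeter noise, then applies the first-order low-pass
#' filter. Noise is drawn from R's RNG stream unless `noise` is supplied,
#' so seeding the stream (or pre-drawing the noise) makes the measurement
#' chain fully reproducible.
#'
#' @param true_flow True flow, L/min.
#' @param sensor A [sensor_config()].
#' @param filter_state State from [flow_filter_init()].
#' @param noise Optional pre-drawn standard-normal deviate (scaled by
#'   `flow_noise_sd` internally); if `NULL`, one is drawn with
#'   [stats::rnorm()].
#' @return A list with `value` (measured flow, L/min) and `state`.
#' @export
sense_flow <- function(true_flow, sensor, filter_state, noise = NULL) {
  if (is.null(noise)) noise <- stats::rnorm(1L)
  x <- true_flow + sensor$flow_noise_sd * noise
  filter_state$y <- filter_state$y + filter_state$alpha * (x - filter_state$y)
  list(value = filter_state$y, state = filter_state)
}

#' Measure the reservoir level
#'
#' Adds Gaussian readout noise, then rounds to the nearest quantisation
#' step (camera pixel resolution emulation).
#'
#' @param true_volume True reservoir volume, L (>= 0).
#' @param sensor A [sensor_config()].
#' @param noise Optional pre-drawn standard-normal deviate; if `NULL`, one
#'   is drawn with [stats::rnorm()].
#' @return Measured level, L.
#' @export
sense_level <- function(true_volume, sensor, noise = NULL) {
  if (true_volume < 0) stop("true_volume must be >= 0", call. = FALSE)
  if (is.null(noise)) noise <- stats::rnorm(1L)
  y <- true_volume + sensor$level_noise_sd * noise
  if (sensor$level_quantum > 0)
    y <- round(y / sensor$level_quantum) * sensor$level_quantum
  y
}
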