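#' Initialise the plant state
#'
#' The plant state tracks the effective occluder opening (the output of the
#' FOPDT actuator), a ring buffer of commanded openings spanning the dead
#' time, the reservoir volume, and the simulation clock.
#'
#' @param params A [plant_params()] object.
#' @param dt Fixed integration step, seconds.
#' @param opening Initial effective opening, percent (also used to fill the
#'   dead-time buffer so the plant starts at equilibrium).
#' @param volume Initial reservoir volume, L.
#' @return An object of class `plant_state`.
#' @export
plant_state_init <- function(params, dt, opening = 0, volume = 0.45) {
  stopifnot(inherits(params, "plant_params"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a positive scalar", call. = FALSE)
  if (opening < 0 || opening > 100)
    stop("opening must be within [0, 100]", call. = FALSE)
  if (volume < 0) stop("volume must be >= 0", call. = FALSE)
  nbuf <- as.integer(round(params$dead_time / dt))
  structure(list(
    opening  = opening,
    buffer   = rep(opening, nbuf),  # oldest first
    volume   = volume,
    time     = 0,
    dt       = dt,
    empty    = FALSE
  ), class = "plant_state")
}

#' Advance the occluder actuator one step
#'
#' Pushes the commanded opening into the dead-time buffer, pops the command
#' issued `dead_time` seconds ago, and advances the effective opening one
#' forward-Euler step of the first-order lag
#' \eqn{dO'/dt = (u_{delayed} - O') / T}. Commands are clamped to
#' \[0, 100\] %.
#'
#' @param state A `plant_state`.
#' @param command Commanded opening ratio, percent.
#' @param params A [plant_params()] object.
#' @return The updated `plant_state`.
#' @export
actuator_step <- function(state, command, params) {
  stopifnot(inherits(state, "plant_state"), inherits(params, "plant_params"))
  if (!is.finite(command)) stop("command must be finite", call. = FALSE)
  command <- min(100, max(0, command))
  if (length(state$buffer)) {
    delayed <- state$buffer[1L]
    state$buffer <- c(state$buffer[-1L], command)
  } else {
    delayed <- command
  }
  state$opening <- state$opening +
    state$dt * (delayed - state$opening) / params$tau
  state$opening <- min(100, max(0, state$opening))
  state$time <- state$time + state$dt
  state
}

#' Advance the reservoir volume one step
#'
#' Mass balance of the venous reservoir: the level (expressed as a volume
#' in liters) integrates the difference between inflow (venous return plus
#' any venting/suction disturbance returned from the operative field) and
#' outflow (arterial flow). Flows are in L/min, the step in seconds, hence
#' the division by 60. A reservoir drained to zero is floored and flagged
#' (the air-embolism hazard condition) rather than raised, so that ablation
#' runs complete and can be scored.
#'
#' @param volume Current volume, L.
#' @param q_in Venous inflow, L/min.
#' @param q_out Arterial outflow, L/min.
#' @param disturbance_in Additional inflow from venting/suction, L/min.
#' @param dt Step, seconds.
#' @return A list with `volume` (L) and `empty` (logical flag).
#' @export
reservoir_step <- function(volume, q_in, q_out, disturbance_in = 0, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a positive scalar", call. = FALSE)
  if (!all(is.finite(c(volume, q_in, q_out, disturbance_in))))
    stop("flows and volume must be finite", call. = FALSE)
  v <- volume + (q_in - q_out + disturbance_in) * dt / 60
  if (v < 0) list(volume = 0, empty = TRUE) else list(volume = v, empty = FALSE)
}
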