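#' IMC tuning of the flow-loop PID from the identified FOPDT dynamics
#'
#' The feedforward path inverts the static map exactly, so the feedback
#' controller sees an approximately linear FOPDT plant whose gain is the
#' local slope of the static map. Internal-model-control rules for a
#' first-order-plus-dead-time plant with desired closed-loop time constant
#' `lambda` give \eqn{K_p = T / (k (\lambda + L))}, \eqn{K_i = K_p / T},
#' with the representative gain \eqn{k} taken as the static-map slope at
#' the half-flow operating point (the slope varies with operating point;
#' the feedforward removes most of that variation).
#'
#' @param params A [plant_params()] object.
#' @param lambda Desired closed-loop time constant, seconds (defaults to
#'   the reference-model time constant of 1 s).
#' @return A list with `kp` (%/(L/min)), `ki` (%/(L/min)/s), `kd` (= 0;
#'   PI suffices once the statics are inverted).
#' @export
tune_flow_pid <- function(params, lambda = 1) {
  stopifnot(inherits(params, "plant_params"), lambda > 0)
  o_half <- occluder_static_inverse(params$Q0 / 2, params)
  h <- 1e-4
  k <- (occluder_static_flow(min(100, o_half + h), params) -
        occluder_static_flow(max(0, o_half - h), params)) / (2 * h)
  kp <- params$tau / (k * (lambda + params$dead_time))
  list(kp = kp, ki = kp / params$tau, kd = 0)
}

#' Controller configuration
#'
#' Gains and limits of the nested controller: the two-degree-of-freedom
#' model-matching arterial flow loop (reference-model filter, static-map
#' feedforward, feedback PID), and the outer I-PD reservoir level loop
#' whose output is an additive correction to the venous-derived flow
#' reference.
#'
#' Flow-loop gains default to the IMC tuning of [tune_flow_pid()] for the
#' supplied plant. Level-loop defaults (`level_ki` = 4 (L/min)/(L s),
#' `level_kp` = 28 (L/min)/L, `level_kd` = 5 (L/min)/(L/s)) place the
#' outer loop's closed-loop poles at natural frequency ~0.25 rad/s with
#' damping ~0.87, i.e. a 2 % settling time near 19 s — at least five times
#' slower than the inner flow loop, preserving the bandwidth separation
#' the nested design relies on.
#'
#' @param plant A [plant_params()] used to tune the flow PID defaults.
#' @param ref_model_tau Reference-model (matching-model) time constant,
#'   seconds.
#' @param flow_kp,flow_ki,flow_kd Flow-loop PID gains; `NULL` means IMC
#'   defaults.
#' @param flow_deriv_tau Flow-loop derivative filter time constant, s;
#'   also the lead-filter time constant of the feedforward lag inversion
#'   (see [flow_control_step()]).
#' @param level_ki,level_kp,level_kd Level-loop I-PD gains.
#' @param level_deriv_tau Level-loop derivative filter time constant, s.
#' @param flow_correction_limit Saturation of the level-loop output,
#'   L/min.
#' @param occ_min,occ_max Occluder command limits, percent.
#' @param sample_time Controller sample interval, seconds.
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(plant = plant_preset("glycerin"),
                              ref_model_tau = 1,
                              flow_kp = NULL, flow_ki = NULL, flow_kd = NULL,
                              flow_deriv_tau = 0.1,
                              level_ki = 4, level_kp = 28, level_kd = 5,
                              level_deriv_tau = 0.5,
                              flow_correction_limit = 1,
                              occ_min = 0, occ_max = 100,
                              sample_time = 0.01) {
  imc <- tune_flow_pid(plant, lambda = max(ref_model_tau, 1e-3))
  cfg <- list(
    ref_model_tau = ref_model_tau,
    flow_kp = if (is.null(flow_kp)) imc$kp else flow_kp,
    flow_ki = if (is.null(flow_ki)) imc$ki else flow_ki,
    flow_kd = if (is.null(flow_kd)) imc$kd else flow_kd,
    flow_deriv_tau = flow_deriv_tau,
    level_ki = level_ki, level_kp = level_kp, level_kd = level_kd,
    level_deriv_tau = level_deriv_tau,
    flow_correction_limit = flow_correction_limit,
    occ_min = occ_min, occ_max = occ_max,
    sample_time = sample_time)
  validate_controller_config(cfg)
  structure(cfg, class = "controller_config")
}

validate_controller_config <- function(cfg) {
  gains <- c("flow_kp", "flow_ki", "flow_kd",
             "level_ki", "level_kp", "level_kd")
  for (g in gains)
    if (!is.finite(cfg[[g]]) || cfg[[g]] < 0)
      stop("controller gain '", g, "' must be >= 0", call. = FALSE)
  if (cfg$sample_time <= 0) stop("sample_time must be > 0", call. = FALSE)
  if (cfg$flow_correction_limit <= 0)
    stop("flow_correction_limit must be > 0", call. = FALSE)
  if (cfg$ref_model_tau < 0) stop("ref_model_tau must be >= 0", call. = FALSE)
  if (cfg$occ_min < 0 || cfg$occ_max > 100 || cfg$occ_min >= cfg$occ_max)
    stop("occluder limits must satisfy 0 <= occ_min < occ_max <= 100",
         call. = FALSE)
  invisible(cfg)
}

#' Initialise the controller state
#'
#' @param cfg A [controller_config()].
#' @param q_ref0 Initial value of the shaped reference, L/min (start at
#'   the initial venous flow for a bumpless start).
#' @return An object of class `controller_state`.
#' @export
controller_state_init <- function(cfg, q_ref0 = 0) {
  stopifnot(inherits(cfg, "controller_config"))
  structure(list(
    ref_y = q_ref0,            # shaped reference (matching-model output)
    flow_i = 0,                # flow-loop integral of error, (L/min) s
    flow_prev_e = 0,
    flow_d = 0,                # filtered derivative of flow error
    flow_sat = 0L,             # -1 low, 0 unsaturated, +1 high (last step)
    ff_prev_o = NA_real_,      # last matching opening, for the lead term
    ff_d = 0,                  # filtered derivative of the matching opening
    qm_buf = NULL,             # dead-time buffer of the matching target
    qm_match = NA_real_,       # achievable matched response (FB target)
    ff_infeasible = FALSE,
    level_i = 0,               # integral of (level - target), L s
    level_prev_y = NA_real_,
    level_d = 0,               # filtered derivative of measured level, L/s
    level_anchor = NA_real_,   # bumpless PD anchor (first measured level)
    level_sat = 0L,
    q_m = q_ref0               # last shaped reference, for logging
  ), class = "controller_state")
}

#' Shape the raw flow reference through the matching model
#'
#' First-order filter with time constant `ref_model_tau` applied to the
#' raw (venous-derived) reference. Both the feedforward and feedback
#' paths of the flow loop target this matching-model output \eqn{Q_m}, so
#' the closed loop is asked to follow a realisable trajectory rather than
#' the raw, possibly stepping, reference. `ref_model_tau = 0` degenerates
#' to a pass-through.
#'
#' @param raw_reference Raw reference flow, L/min (>= 0).
#' @param cfg A [controller_config()].
#' @param state A [controller_state_init()] state.
#' @return A list with `value` (\eqn{Q_m}, L/min) and `state`.
#' @export
shape_reference <- function(raw_reference, cfg, state) {
  if (raw_reference < 0) stop("raw_reference must be >= 0", call. = FALSE)
  if (cfg$ref_model_tau <= 0) {
    state$ref_y <- raw_reference
  } else {
    a <- 1 - exp(-cfg$sample_time / cfg$ref_model_tau)
    state$ref_y <- state$ref_y + a * (raw_reference - state$ref_y)
  }
  list(value = state$ref_y, state = state)
}

#' One step of the two-degree-of-freedom flow controller
#'
#' Occluder command = feedforward + feedback, clamped to the occluder
#' limits. The feedforward realises the model-matching inverse of the
#' plant: the static map is inverted exactly at the matching-model output
#' \eqn{Q_m} (giving the matching opening \eqn{o_m}), and the first-order
#' actuator lag is inverted by a realisable lead,
#' \eqn{u_{ff} = o_m + T \dot o_{m,f}} with \eqn{\dot o_{m,f}} a filtered
#' derivative (time constant `flow_deriv_tau`). The dead time is not
#' invertible, and the lead leaves a first-order residual
#' \eqn{1/(1 + \tau_f s)}; both are therefore folded into the matching
#' target the feedback compares against, so the PID acts on the error
#' between the measured flow and the *achievable* matched response,
#' \eqn{Q_m(t-L)} filtered by \eqn{1/(1+\tau_f s)}. Under perfect
#' feedforward this error stays near zero, so the integrator does not
#' wind up during reference transients and the feedback is left to
#' reject model mismatch and disturbances — the two-degree-of-freedom
#' separation. The integrator is held while the command
#' saturates in the direction the error pushes (conditional-integration
#' anti-windup). An infeasible \eqn{Q_m} (at or above the static map's
#' supremum) saturates the feedforward at 100 % and sets the
#' `ff_infeasible` flag.
#'
#' @param q_m Matching-model reference flow, L/min.
#' @param q_measured Measured arterial flow, L/min.
#' @param params A [plant_params()].
#' @param cfg A [controller_config()].
#' @param state A [controller_state_init()] state.
#' @return A list with `command` (percent) and `state`.
#' @export
flow_control_step <- function(q_m, q_measured, params, cfg, state) {
  dt <- cfg$sample_time
  # feedforward: exact static-model inversion plus lag inversion (lead)
  if (q_m >= 0.999 * params$Q0) {
    o_m <- cfg$occ_max
    state$ff_infeasible <- TRUE
  } else {
    o_m <- occluder_static_inverse(q_m, params)
    state$ff_infeasible <- FALSE
    if (o_m > cfg$occ_max) { o_m <- cfg$occ_max; state$ff_infeasible <- TRUE }
  }
  if (is.na(state$ff_prev_o)) state$ff_prev_o <- o_m
  state$ff_d <- state$ff_d + dt / (cfg$flow_deriv_tau + dt) *
    ((o_m - state$ff_prev_o) / dt - state$ff_d)
  state$ff_prev_o <- o_m
  ff <- o_m + (params$tau - cfg$flow_deriv_tau) * state$ff_d
  # matching target: q_m through the dead time and the lead residual
  nbuf <- as.integer(round(params$dead_time / dt))
  if (is.null(state$qm_buf)) state$qm_buf <- rep(q_m, nbuf)
  if (nbuf > 0L) {
    q_m_del <- state$qm_buf[1L]
    state$qm_buf <- c(state$qm_buf[-1L], q_m)
  } else q_m_del <- q_m
  if (is.na(state$qm_match)) state$qm_match <- q_m_del
  state$qm_match <- state$qm_match +
    dt / (cfg$flow_deriv_tau + dt) * (q_m_del - state$qm_match)
  e <- state$qm_match - q_measured
  # conditional integration: hold while saturated in the error's direction
  if (!((state$flow_sat > 0L && e > 0) || (state$flow_sat < 0L && e < 0)))
    state$flow_i <- state$flow_i + e * dt
  state$flow_d <- state$flow_d + dt / (cfg$flow_deriv_tau + dt) *
    ((e - state$flow_prev_e) / dt - state$flow_d)
  state$flow_prev_e <- e
  u <- ff + cfg$flow_kp * e + cfg$flow_ki * state$flow_i +
    cfg$flow_kd * state$flow_d
  if (u > cfg$occ_max) {
    state$flow_sat <- 1L; u <- cfg$occ_max
  } else if (u < cfg$occ_min) {
    state$flow_sat <- -1L; u <- cfg$occ_min
  } else state$flow_sat <- 0L
  list(command = u, state = state)
}

#' One step of the I-PD reservoir level controller
#'
#' Produces the additive correction to the arterial flow reference:
#' \deqn{u = K_{i,L} \int (Y_L - R_L)\,dt
#'        + K_{p,L} (Y_L - Y_0) + K_{d,L}\, \dot Y_{L,f},}
#' clamped at `flow_correction_limit`. Only the integral sees the target
#' \eqn{R_L}; the P and D terms act on the measured level alone (no
#' setpoint kick — the defining I-PD property). \eqn{Y_0} is the level at
#' the first call (bumpless start) and \eqn{\dot Y_{L,f}} a filtered
#' derivative of the measurement. Signs follow the reservoir physics: the
#' correction raises arterial outflow, which drains the reservoir, so a
#' level below target must produce a negative correction, which the
#' integral of \eqn{(Y_L - R_L)} delivers.
#'
#' @param target_level Target level \eqn{R_L}, L.
#' @param measured_level Measured level \eqn{Y_L}, L.
#' @param cfg A [controller_config()].
#' @param state A [controller_state_init()] state.
#' @return A list with `correction` (L/min) and `state`.
#' @export
level_control_step <- function(target_level, measured_level, cfg, state) {
  dt <- cfg$sample_time
  y <- measured_level
  if (is.na(state$level_anchor)) {
    state$level_anchor <- y
    state$level_prev_y <- y
  }
  e <- y - target_level            # positive when the reservoir is too full
  if (!((state$level_sat > 0L && e > 0) || (state$level_sat < 0L && e < 0)))
    state$level_i <- state$level_i + e * dt
  state$level_d <- state$level_d + dt / (cfg$level_deriv_tau + dt) *
    ((y - state$level_prev_y) / dt - state$level_d)
  state$level_prev_y <- y
  u <- cfg$level_ki * state$level_i +
    cfg$level_kp * (y - state$level_anchor) +
    cfg$level_kd * state$level_d
  lim <- cfg$flow_correction_limit
  if (u > lim) {
    state$level_sat <- 1L; u <- lim
  } else if (u < -lim) {
    state$level_sat <- -1L; u <- -lim
  } else state$level_sat <- 0L
  list(correction = u, state = state)
}

#' One step of the full nested controller
#'
#' The reservoir level loop corrects the venous-derived flow reference,
#' the matching model shapes it, and the two-degree-of-freedom flow loop
#' turns it into an occluder command:
#' `q_ref = max(0, q_venous + correction)`; `q_m = shape(q_ref)`;
#' `command = flow_control_step(q_m, q_arterial)`. With
#' `level_control = FALSE` (the ablation), the correction is identically
#' zero and the controller reduces to pure venous-flow tracking.
#'
#' @param q_venous_measured Measured venous flow, L/min.
#' @param target_level Target reservoir level, L.
#' @param measured_level Measured reservoir level, L.
#' @param q_arterial_measured Measured arterial flow, L/min.
#' @param params A [plant_params()].
#' @param cfg A [controller_config()].
#' @param state A [controller_state_init()] state.
#' @param level_control Enable the reservoir level loop (`FALSE` =
#'   ablation).
#' @return A list with `command` (percent), `correction` (L/min), `q_m`
#'   (L/min), and `state`.
#' @export
nested_control_step <- function(q_venous_measured, target_level,
                                measured_level, q_arterial_measured,
                                params, cfg, state, level_control = TRUE) {
  if (level_control) {
    lc <- level_control_step(target_level, measured_level, cfg, state)
    corr <- lc$correction
    state <- lc$state
  } else corr <- 0
  sr <- shape_reference(max(0, q_venous_measured + corr), cfg, state)
  state <- sr$state
  fc <- flow_control_step(sr$value, q_arterial_measured, params, cfg, state)
  state <- fc$state
  state$q_m <- sr$value
  list(command = fc$command, correction = corr, q_m = sr$value,
       state = state)
}
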