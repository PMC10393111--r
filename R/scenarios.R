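#' Scenario configuration
#'
#' Describes one closed-loop experiment: duration and step size, target
#' reservoir level, a piecewise-linear venous flow profile, a list of
#' venting/suction episodes (each adding inflow to the reservoir), the
#' sensor model, whether the level loop is enabled, and the RNG seed.
#'
#' @param duration Total simulated time \eqn{s_t}, seconds.
#' @param dt Fixed step \eqn{\Delta t}, seconds.
#' @param target_level Target reservoir level \eqn{L_T}, L.
#' @param venous_profile Data frame with columns `time` (s, sorted) and
#'   `flow` (L/min); linearly interpolated, held constant outside the
#'   knot range.
#' @param disturbance Data frame with columns `start`, `stop` (s) and
#'   `magnitude` (L/min) — venting/suction episodes returning blood to
#'   the reservoir. May have zero rows.
#' @param sensor A [sensor_config()].
#' @param level_control Enable the reservoir level loop (`FALSE` =
#'   ablation).
#' @param seed Integer seed driving all measurement noise.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(duration, dt = 0.01, target_level = 0.45,
                            venous_profile,
                            disturbance = data.frame(start = numeric(),
                                                     stop = numeric(),
                                                     magnitude = numeric()),
                            sensor = sensor_config(),
                            level_control = TRUE, seed = 1) {
  if (duration <= 0 || dt <= 0) stop("duration and dt must be > 0",
                                     call. = FALSE)
  if (target_level <= 0) stop("target_level must be > 0", call. = FALSE)
  if (!all(c("time", "flow") %in% names(venous_profile)))
    stop("venous_profile needs columns time and flow", call. = FALSE)
  if (is.unsorted(venous_profile$time))
    stop("venous_profile knots must be time-sorted", call. = FALSE)
  if (any(venous_profile$flow < 0))
    stop("venous_profile flows must be >= 0", call. = FALSE)
  if (nrow(disturbance)) {
    if (!all(c("start", "stop", "magnitude") %in% names(disturbance)))
      stop("disturbance needs columns start, stop, magnitude", call. = FALSE)
    if (any(disturbance$start < 0 | disturbance$stop > duration |
            disturbance$start >= disturbance$stop))
      stop("disturbance episodes must satisfy 0 <= start < stop <= duration",
           call. = FALSE)
  }
  structure(list(duration = duration, dt = dt, target_level = target_level,
                 venous_profile = venous_profile, disturbance = disturbance,
                 sensor = sensor, level_control = level_control,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Perfusion-process scenario preset
#'
#' A 400 s run covering the CPB flow-up and flow-down phases: the venous
#' flow ramps 0.5 to 4.0 L/min over the first 150 s, holds to 250 s, and
#' ramps back down to 0.5 L/min by 400 s. No venting/suction. Sampling
#' at 0.01 s; target level 0.45 L.
#'
#' @param preset Preset name; only `"default"` is defined.
#' @param seed Integer seed.
#' @param sensor A [sensor_config()].
#' @param level_control Enable the reservoir level loop.
#' @return A [scenario_config()].
#' @export
perfusion_scenario <- function(preset = "default", seed = 1,
                               sensor = sensor_config(),
                               level_control = TRUE) {
  if (!identical(preset, "default"))
    stop("unknown perfusion preset '", preset, "'; available: default",
         call. = FALSE)
  scenario_config(
    duration = 400, dt = 0.01, target_level = 0.45,
    venous_profile = data.frame(time = c(0, 150, 250, 400),
                                flow = c(0.5, 4, 4, 0.5)),
    sensor = sensor, level_control = level_control, seed = seed)
}

#' Venting/suction disturbance scenario preset
#'
#' A 200 s run at a constant venous flow of 4 L/min with two suction
#' episodes returning blood to the reservoir: +0.5 L/min for 20 s
#' starting at 50 s and at 150 s.
#'
#' @inheritParams perfusion_scenario
#' @return A [scenario_config()].
#' @export
disturbance_scenario <- function(preset = "default", seed = 1,
                                 sensor = sensor_config(),
                                 level_control = TRUE) {
  if (!identical(preset, "default"))
    stop("unknown disturbance preset '", preset, "'; available: default",
         call. = FALSE)
  scenario_config(
    duration = 200, dt = 0.01, target_level = 0.45,
    venous_profile = data.frame(time = c(0, 200), flow = c(4, 4)),
    disturbance = data.frame(start = c(50, 150), stop = c(70, 170),
                             magnitude = c(0.5, 0.5)),
    sensor = sensor, level_control = level_control, seed = seed)
}

venous_at <- function(profile, t) {
  if (nrow(profile) == 1L) return(rep(profile$flow, length(t)))
  stats::approx(profile$time, profile$flow, xout = t, rule = 2)$y
}

disturbance_at <- function(episodes, t) {
  d <- numeric(length(t))
  if (nrow(episodes))
    for (k in seq_len(nrow(episodes)))
      d <- d + episodes$magnitude[k] *
        (t >= episodes$start[k] & t < episodes$stop[k])
  d
}

#' Run one closed-loop trial
#'
#' Simulates the full closed loop for `duration / dt` steps at fixed
#' step: venous flow from the profile, both flows and the level passed
#' through the sensor models, the nested controller issuing occluder
#' commands, the FOPDT actuator and reservoir mass balance advancing the
#' plant. The loop body is an inlined, allocation-free transcription of
#' the exported step primitives ([sense_flow()], [nested_control_step()],
#' [actuator_step()], [reservoir_step()]) for speed; equivalence of the
#' two routes is pinned by the test suite. Noise is pre-drawn from
#' `set.seed(scenario$seed)` in the fixed order venous, arterial, level,
#' so a (config, seed) pair fully determines every logged sample.
#'
#' The plant starts at equilibrium: effective opening at the static
#' inverse of the initial venous flow, reservoir at the target level.
#'
#' @param scenario A [scenario_config()].
#' @param plant A [plant_params()].
#' @param controller A [controller_config()]; its `sample_time` is forced
#'   to the scenario's `dt`.
#' @return An object of class `trial_result`: `ts` (the logged data
#'   frame, schema of [write_timeseries()]), `j_q_percent`,
#'   `j_l_percent`, `n_excluded`, `empty_reservoir`, `seed`.
#' @export
run_trial <- function(scenario, plant, controller = controller_config(plant)) {
  stopifnot(inherits(scenario, "scenario_config"),
            inherits(plant, "plant_params"),
            inherits(controller, "controller_config"))
  dt <- scenario$dt
  cfg <- controller
  cfg$sample_time <- dt
  n <- as.integer(round(scenario$duration / dt))
  t <- (seq_len(n) - 1L) * dt
  sen <- scenario$sensor

  qv_true <- venous_at(scenario$venous_profile, t)
  dist <- disturbance_at(scenario$disturbance, t)

  set.seed(scenario$seed)
  zv <- stats::rnorm(n); za <- stats::rnorm(n); zl <- stats::rnorm(n)

  # plant constants hoisted out of the loop
  cR <- plant$R; cdR0 <- plant$dR0; cQ0 <- plant$Q0
  cA <- plant$A; cK <- plant$K
  num_c <- (1 + cdR0 / cR) * cQ0 * cR * cA
  den_c <- (cR + cdR0) * cA
  inv_c <- cA * (cR + cdR0)

  alpha_f <- 1 - exp(-2 * pi * sen$lowpass_cutoff * dt)
  a_ref <- if (cfg$ref_model_tau > 0) 1 - exp(-dt / cfg$ref_model_tau) else 1
  quant <- sen$level_quantum
  sd_f <- sen$flow_noise_sd; sd_l <- sen$level_noise_sd
  lvl_on <- isTRUE(scenario$level_control)
  RL <- scenario$target_level
  lim <- cfg$flow_correction_limit
  occ_lo <- cfg$occ_min; occ_hi <- cfg$occ_max

  # initial equilibrium
  q0v <- qv_true[1L]
  E0 <- q0v / (inv_c * (cQ0 - q0v))
  opening <- min(occ_hi, log1p(E0) / cK)
  vol <- RL
  nbuf <- as.integer(round(plant$dead_time / dt))
  buf <- rep(opening, max(1L, nbuf))  # length-1 dummy when nbuf == 0
  bidx <- 1L
  fv <- q0v                      # venous flow filter state
  fa <- num_c * E0 / (1 + den_c * E0)  # arterial filter at true flow
  ref_y <- q0v
  flow_i <- 0; flow_prev_e <- 0; flow_d <- 0; flow_sat <- 0L
  ff_prev_o <- NA_real_; ff_d <- 0
  qm_buf <- rep(NA_real_, max(1L, nbuf)); qidx <- 1L; qm_match <- NA_real_
  level_i <- 0; level_prev_y <- NA_real_; level_d <- 0
  level_anchor <- NA_real_; level_sat <- 0L
  empty <- FALSE

  log_qv <- numeric(n); log_qm <- numeric(n); log_qa <- numeric(n)
  log_cmd <- numeric(n); log_eff <- numeric(n)
  log_vol <- numeric(n); log_lm <- numeric(n)

  for (i in seq_len(n)) {
    # true arterial flow through the occluder
    E <- exp(cK * opening) - 1
    qa_true <- num_c * E / (1 + den_c * E)

    # sensors: noise then first-order low-pass; level noise then quantise
    fv <- fv + alpha_f * (qv_true[i] + sd_f * zv[i] - fv)
    fa <- fa + alpha_f * (qa_true + sd_f * za[i] - fa)
    lm <- vol + sd_l * zl[i]
    if (quant > 0) lm <- round(lm / quant) * quant

    # outer I-PD level loop -> flow-reference correction
    if (lvl_on) {
      if (is.na(level_anchor)) { level_anchor <- lm; level_prev_y <- lm }
      e_l <- lm - RL
      if (!((level_sat > 0L && e_l > 0) || (level_sat < 0L && e_l < 0)))
        level_i <- level_i + e_l * dt
      level_d <- level_d + dt / (cfg$level_deriv_tau + dt) *
        ((lm - level_prev_y) / dt - level_d)
      level_prev_y <- lm
      corr <- cfg$level_ki * level_i + cfg$level_kp * (lm - level_anchor) +
        cfg$level_kd * level_d
      if (corr > lim) { level_sat <- 1L; corr <- lim }
      else if (corr < -lim) { level_sat <- -1L; corr <- -lim }
      else level_sat <- 0L
    } else corr <- 0

    # matching model shapes the corrected venous reference
    raw <- fv + corr
    if (raw < 0) raw <- 0
    ref_y <- ref_y + a_ref * (raw - ref_y)

    # inner 2-DOF flow loop: model-inverse FF (statics + lag lead) + PID FB
    if (ref_y >= 0.999 * cQ0) o_m <- occ_hi
    else {
      o_m <- log1p(ref_y / (inv_c * (cQ0 - ref_y))) / cK
      if (o_m > occ_hi) o_m <- occ_hi
    }
    if (is.na(ff_prev_o)) ff_prev_o <- o_m
    ff_d <- ff_d + dt / (cfg$flow_deriv_tau + dt) *
      ((o_m - ff_prev_o) / dt - ff_d)
    ff_prev_o <- o_m
    ff <- o_m + (plant$tau - cfg$flow_deriv_tau) * ff_d
    if (nbuf > 0L) {
      if (is.na(qm_buf[1L])) qm_buf[] <- ref_y  # lazy init, matches the op
      qm_del <- qm_buf[qidx]
      qm_buf[qidx] <- ref_y
      qidx <- if (qidx == nbuf) 1L else qidx + 1L
    } else qm_del <- ref_y
    if (is.na(qm_match)) qm_match <- qm_del
    qm_match <- qm_match + dt / (cfg$flow_deriv_tau + dt) * (qm_del - qm_match)
    e <- qm_match - fa
    if (!((flow_sat > 0L && e > 0) || (flow_sat < 0L && e < 0)))
      flow_i <- flow_i + e * dt
    flow_d <- flow_d + dt / (cfg$flow_deriv_tau + dt) *
      ((e - flow_prev_e) / dt - flow_d)
    flow_prev_e <- e
    cmd <- ff + cfg$flow_kp * e + cfg$flow_ki * flow_i +
      cfg$flow_kd * flow_d
    if (cmd > occ_hi) { flow_sat <- 1L; cmd <- occ_hi }
    else if (cmd < occ_lo) { flow_sat <- -1L; cmd <- occ_lo }
    else flow_sat <- 0L

    log_qv[i] <- fv; log_qm[i] <- ref_y; log_qa[i] <- fa
    log_cmd[i] <- cmd; log_eff[i] <- opening
    log_vol[i] <- vol; log_lm[i] <- lm

    # FOPDT actuator: dead-time ring buffer + forward-Euler lag
    if (nbuf > 0L) {
      delayed <- buf[bidx]
      buf[bidx] <- cmd
      bidx <- if (bidx == nbuf) 1L else bidx + 1L
    } else delayed <- cmd
    opening <- opening + dt * (delayed - opening) / plant$tau
    if (opening > 100) opening <- 100 else if (opening < 0) opening <- 0

    # reservoir mass balance (flows L/min, step s)
    vol <- vol + (qv_true[i] - qa_true + dist[i]) * dt / 60
    if (vol < 0) { vol <- 0; empty <- TRUE }
  }

  ts <- data.frame(time_s = t, q_venous = log_qv, q_ref = log_qm,
                   q_arterial = log_qa, occ_cmd = log_cmd,
                   occ_eff = log_eff, level_L = log_vol,
                   level_meas_L = log_lm, disturbance = dist)
  jq <- j_q_percent(ts$q_ref, ts$q_arterial)
  structure(list(ts = ts,
                 j_q_percent = as.numeric(jq),
                 j_l_percent = j_l_percent(ts$level_meas_L, RL),
                 n_excluded = attr(jq, "n_excluded"),
                 empty_reservoir = empty,
                 seed = scenario$seed),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("Trial (seed %d): J_Q%% = %.3f, J_L%% = %.3f over %d samples%s\n",
              x$seed, x$j_q_percent, x$j_l_percent, nrow(x$ts),
              if (x$empty_reservoir) " [RESERVOIR EMPTIED]" else ""))
  invisible(x)
}

#' Run a batch of seeded trials
#'
#' Runs `n_trials` independent trials with seeds `base_seed + 0, 1, ...`
#' and summarises each metric with the quantile convention used for the
#' boxplots of the physical experiments: minimum, 2.5 %, median, 97.5 %
#' and maximum.
#'
#' @param scenario A [scenario_config()] (its seed is overridden per
#'   trial).
#' @param plant A [plant_params()].
#' @param controller A [controller_config()].
#' @param n_trials Number of trials (>= 1).
#' @param base_seed Seed of the first trial.
#' @return A list of class `batch_result`: `trials` (list of
#'   `trial_result`), `summary` (data frame with one row per metric and
#'   columns `min`, `q2.5`, `median`, `q97.5`, `max`).
#' @export
run_batch <- function(scenario, plant, controller = controller_config(plant),
                      n_trials = 10, base_seed = 1) {
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  trials <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    sc <- scenario
    sc$seed <- as.integer(base_seed + k - 1L)
    trials[[k]] <- run_trial(sc, plant, controller)
  }
  qs <- function(v) stats::quantile(v, c(0, 0.025, 0.5, 0.975, 1),
                                    names = FALSE, type = 7)
  jq <- vapply(trials, `[[`, numeric(1), "j_q_percent")
  jl <- vapply(trials, `[[`, numeric(1), "j_l_percent")
  summary <- data.frame(metric = c("j_q_percent", "j_l_percent"),
                        rbind(qs(jq), qs(jl)))
  names(summary)[-1] <- c("min", "q2.5", "median", "q97.5", "max")
  structure(list(trials = trials, summary = summary),
            class = "batch_result")
}

#' @export
print.batch_result <- function(x, ...) {
  cat(sprintf("Batch of %d trial(s):\n", length(x$trials)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
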