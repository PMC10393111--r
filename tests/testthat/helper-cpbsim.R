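# shared fixtures: everything is built in code, no files

glycerin <- plant_preset("glycerin")

noiseless_sensor <- function() {
  sensor_config(flow_noise_sd = 0, lowpass_cutoff = 1,
                level_noise_sd = 0, level_quantum = 0)
}

# closed-loop run of the inner flow loop only (no reservoir feedback),
# composing the exported ops; q_m may be a function of time or a constant
simulate_flow_loop <- function(q_m, params, cfg, duration, dt = 0.01,
                               q0 = NULL) {
  qm_fun <- if (is.function(q_m)) q_m else function(t) q_m
  if (is.null(q0)) q0 <- qm_fun(0)
  st <- controller_state_init(cfg, q_ref0 = q0)
  ps <- plant_state_init(params, dt,
                         opening = occluder_static_inverse(q0, params),
                         volume = 0.45)
  n <- as.integer(round(duration / dt))
  q <- numeric(n); cmd <- numeric(n)
  for (i in seq_len(n)) {
    qa <- occluder_static_flow(ps$opening, params)
    fc <- flow_control_step(qm_fun((i - 1) * dt), qa, params, cfg, st)
    st <- fc$state
    ps <- actuator_step(ps, fc$command, params)
    q[i] <- qa; cmd[i] <- fc$command
  }
  list(time = (seq_len(n) - 1) * dt, flow = q, command = cmd, state = st)
}

# noiseless full nested scenario, constant venous flow
nested_scenario <- function(duration, venous = 4, target = 0.45,
                            disturbance = NULL, level_control = TRUE,
                            seed = 1) {
  scenario_config(
    duration = duration, dt = 0.01, target_level = target,
    venous_profile = data.frame(time = c(0, duration),
                                flow = c(venous, venous)),
    disturbance = if (is.null(disturbance))
      data.frame(start = numeric(), stop = numeric(),
                 magnitude = numeric()) else disturbance,
    sensor = noiseless_sensor(), level_control = level_control, seed = seed)
}
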