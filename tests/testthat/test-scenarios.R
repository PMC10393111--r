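test_that("scenario presets match the experimental protocol constants", {
  sc <- perfusion_scenario()
  expect_equal(sc$duration, 400)
  expect_equal(sc$dt, 0.01)
  expect_equal(sc$target_level, 0.45)
  expect_equal(round(sc$duration / sc$dt), 40000)
  # profile continuous (piecewise linear) and non-negative
  t <- seq(0, 400, by = 0.5)
  v <- cpbsim:::venous_at(sc$venous_profile, t)
  expect_true(all(v >= 0))
  expect_lt(max(abs(diff(v))), 0.05)
  expect_equal(nrow(sc$disturbance), 0L)

  sd <- disturbance_scenario()
  expect_equal(sd$duration, 200)
  expect_equal(nrow(sd$disturbance), 2L)
  expect_true(all(sd$disturbance$start < sd$disturbance$stop))
  expect_true(all(sd$disturbance$stop <= 200))
  # episodes do not overlap
  expect_lt(sd$disturbance$stop[1], sd$disturbance$start[2])
  # total disturbed volume: sum(magnitude * duration) / 60
  vol <- with(sd$disturbance, sum(magnitude * (stop - start)) / 60)
  expect_equal(vol, 2 * 0.5 * 20 / 60)

  expect_error(perfusion_scenario("nope"), "default")
  expect_error(disturbance_scenario("nope"), "default")
})

test_that("run_trial is bit-reproducible from (config, seed)", {
  p <- glycerin
  sc <- disturbance_scenario(seed = 7)
  sc$duration <- 20
  a <- run_trial(sc, p)
  b <- run_trial(sc, p)
  expect_identical(a$ts, b$ts)
  expect_identical(a$j_q_percent, b$j_q_percent)
  sc8 <- disturbance_scenario(seed = 8)
  sc8$duration <- 20
  c <- run_trial(sc8, p)
  expect_false(identical(a$j_q_percent, c$j_q_percent))
})

test_that("inlined trial loop matches the composition of the exported ops", {
  p <- glycerin
  sc <- scenario_config(
    duration = 6, dt = 0.01, target_level = 0.45,
    venous_profile = data.frame(time = c(0, 3, 6), flow = c(3, 4, 3.5)),
    disturbance = data.frame(start = 2, stop = 4, magnitude = 0.5),
    sensor = sensor_config(), seed = 13)
  cfg <- controller_config(p)
  tr <- run_trial(sc, p, cfg)

  # independent route: the same loop assembled from the exported step
  # primitives, with the same pre-drawn noise
  dt <- sc$dt
  n <- as.integer(round(sc$duration / dt))
  t <- (seq_len(n) - 1) * dt
  qv_true <- cpbsim:::venous_at(sc$venous_profile, t)
  dist <- cpbsim:::disturbance_at(sc$disturbance, t)
  set.seed(sc$seed)
  zv <- rnorm(n); za <- rnorm(n); zl <- rnorm(n)

  cfg$sample_time <- dt
  sen <- sc$sensor
  opening0 <- occluder_static_inverse(qv_true[1], p)
  ps <- plant_state_init(p, dt, opening = opening0, volume = 0.45)
  fv <- flow_filter_init(sen, dt, initial = qv_true[1])
  fa <- flow_filter_init(sen, dt,
                         initial = occluder_static_flow(opening0, p))
  st <- controller_state_init(cfg, q_ref0 = qv_true[1])
  out <- matrix(NA_real_, n, 4)
  vol <- 0.45
  for (i in seq_len(n)) {
    qa_true <- occluder_static_flow(ps$opening, p)
    rv <- sense_flow(qv_true[i], sen, fv, noise = zv[i]); fv <- rv$state
    ra <- sense_flow(qa_true, sen, fa, noise = za[i]); fa <- ra$state
    lm <- sense_level(vol, sen, noise = zl[i])
    nc <- nested_control_step(rv$value, sc$target_level, lm, ra$value,
                              p, cfg, st)
    st <- nc$state
    out[i, ] <- c(rv$value, nc$q_m, ra$value, nc$command)
    ps <- actuator_step(ps, nc$command, p)
    vol <- reservoir_step(vol, qv_true[i], qa_true, dist[i], dt)$volume
  }
  expect_equal(tr$ts$q_venous, out[, 1], tolerance = 1e-12)
  expect_equal(tr$ts$q_ref, out[, 2], tolerance = 1e-12)
  expect_equal(tr$ts$q_arterial, out[, 3], tolerance = 1e-12)
  expect_equal(tr$ts$occ_cmd, out[, 4], tolerance = 1e-12)
})

test_that("ablation: an unrejected disturbance shifts the level by its volume", {
  p <- glycerin
  dist <- data.frame(start = 10, stop = 40, magnitude = 0.5)
  off <- run_trial(nested_scenario(60, venous = 4, disturbance = dist,
                                   level_control = FALSE), p)
  on <- run_trial(nested_scenario(60, venous = 4, disturbance = dist,
                                  level_control = TRUE), p)
  # without level control the deviation equals the episode volume
  # (0.5 L/min * 30 s / 60 = 0.25 L) and never recovers
  expect_equal(tail(off$ts$level_L, 1) - 0.45, 0.25, tolerance = 0.01)
  # with level control it decays back below 1e-3 L
  expect_lt(abs(tail(on$ts$level_L, 1) - 0.45), 1e-3)
  expect_gt(off$j_l_percent, on$j_l_percent)
})

test_that("empty reservoir is flagged and the run completes", {
  p <- glycerin
  # draining disturbance (negative inflow) with no level control
  sc <- nested_scenario(60, venous = 4,
                        disturbance = data.frame(start = 5, stop = 60,
                                                 magnitude = -0.5),
                        level_control = FALSE)
  tr <- run_trial(sc, p)
  expect_true(tr$empty_reservoir)
  expect_equal(nrow(tr$ts), 6000L)
  expect_true(all(tr$ts$level_L >= 0))
})

test_that("run_batch: seeding, quantile ordering, degenerate cases", {
  p <- glycerin
  sc <- disturbance_scenario()
  sc$duration <- 15
  b <- run_batch(sc, p, n_trials = 4, base_seed = 1)
  expect_length(b$trials, 4)
  # per-trial seeds are base_seed + 0:3
  expect_identical(vapply(b$trials, `[[`, integer(1), "seed"), 1:4)
  s <- b$summary
  expect_true(all(s$min <= s$q2.5 & s$q2.5 <= s$median &
                    s$median <= s$q97.5 & s$q97.5 <= s$max))

  # a single trial: summary equals that trial's metrics
  b1 <- run_batch(sc, p, n_trials = 1, base_seed = 5)
  expect_equal(unname(unlist(b1$summary[1, -1])),
               rep(b1$trials[[1]]$j_q_percent, 5))

  # noiseless sensors: all trials identical despite different seeds
  sc0 <- nested_scenario(10, venous = 4)
  b0 <- run_batch(sc0, p, n_trials = 3, base_seed = 1)
  jq <- vapply(b0$trials, `[[`, numeric(1), "j_q_percent")
  expect_identical(jq[1], jq[2])
  expect_identical(jq[1], jq[3])
})

test_that("scenario validation rejects malformed configurations", {
  expect_error(scenario_config(duration = -1, venous_profile =
                                 data.frame(time = 0, flow = 4)), "> 0")
  expect_error(scenario_config(duration = 10, venous_profile =
                                 data.frame(time = c(5, 0), flow = c(4, 4))),
               "sorted")
  expect_error(scenario_config(
    duration = 10,
    venous_profile = data.frame(time = c(0, 10), flow = c(4, 4)),
    disturbance = data.frame(start = 5, stop = 20, magnitude = 1)),
    "episode")
})
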