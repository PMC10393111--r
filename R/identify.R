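#' Generate a synthetic occluder-sweep dataset
#'
#' Emulates the premeasured opening-ratio/steady-state-flow pairs used to
#' identify the static plant parameters: openings on a uniform grid over
#' \[0, 100\] %, flows from the static map plus Gaussian measurement
#' noise.
#'
#' @param params True [plant_params()].
#' @param n_points Number of grid points (>= 6).
#' @param noise_sd Flow noise standard deviation, L/min.
#' @param seed Integer seed.
#' @return A data frame with columns `opening_pct` and `flow_lpm`, class
#'   `sweep_dataset`.
#' @export
generate_sweep <- function(params, n_points = 25, noise_sd = 0.05, seed = 1) {
  stopifnot(inherits(params, "plant_params"))
  if (n_points < 6) stop("n_points must be >= 6", call. = FALSE)
  set.seed(seed)
  opening <- seq(0, 100, length.out = n_points)
  flow <- occluder_static_flow(opening, params) +
    stats::rnorm(n_points, 0, noise_sd)
  structure(data.frame(opening_pct = opening, flow_lpm = flow),
            class = c("sweep_dataset", "data.frame"))
}

#' Generate a synthetic actuator step-response dataset
#'
#' The effective-opening response to an opening-command step, i.e. a
#' delayed first-order rise, sampled on a regular grid with optional
#' Gaussian noise. Used to exercise [fit_dynamic_params()].
#'
#' @param params True [plant_params()] (only `dead_time` and `tau` are
#'   used).
#' @param step_from,step_to Command step endpoints, percent.
#' @param duration Record length, seconds (should cover the full
#'   transient).
#' @param dt Sample interval, seconds.
#' @param noise_sd Response noise standard deviation, percent.
#' @param seed Integer seed.
#' @return A data frame with columns `time_s` and `response`, class
#'   `step_dataset`.
#' @export
generate_step_response <- function(params, step_from = 0, step_to = 100,
                                   duration = NULL, dt = 0.01,
                                   noise_sd = 0, seed = 1) {
  stopifnot(inherits(params, "plant_params"))
  if (is.null(duration)) duration <- params$dead_time + 8 * params$tau
  set.seed(seed)
  t <- seq(0, duration, by = dt)
  y <- step_from + (step_to - step_from) *
    (1 - exp(-pmax(0, t - params$dead_time) / params$tau))
  if (noise_sd > 0) y <- y + stats::rnorm(length(t), 0, noise_sd)
  structure(data.frame(time_s = t, response = y),
            class = c("step_dataset", "data.frame"))
}

#' Fit the static plant parameters from a sweep dataset
#'
#' Nonlinear least squares on the static occluder-to-flow map: minimises
#' the sum of squared flow residuals over (R, dR0, Q0, A, K) with
#' positivity bounds. The map is structurally over-parameterised (R, dR0
#' and A enter through products), so individual parameters may trade off
#' against each other; fits are therefore judged on predictive
#' equivalence of the flow curve, and a seeded multi-start (log-normal
#' jitter around the initial guess) guards against local minima.
#'
#' @param data A sweep dataset (`opening_pct`, `flow_lpm`), at least 6
#'   points.
#' @param init Initial guess: a [plant_params()] or a named list with
#'   R, dR0, Q0, A, K.
#' @param n_starts Number of multi-start restarts (first start is the
#'   unperturbed guess).
#' @param seed Seed for the restart jitter.
#' @return A list of class `static_fit`: `params` (a [plant_params()]
#'   carrying the fitted statics and the initial guess's dynamics),
#'   `residual_norm`, `converged`, `n_points`.
#' @export
fit_static_params <- function(data, init, n_starts = 5, seed = 1) {
  if (!all(c("opening_pct", "flow_lpm") %in% names(data)))
    stop("data must have columns opening_pct and flow_lpm", call. = FALSE)
  if (nrow(data) < 6) stop("need at least 6 sweep points", call. = FALSE)
  if (any(data$opening_pct < 0 | data$opening_pct > 100))
    stop("openings must lie within [0, 100]", call. = FALSE)
  if (stats::sd(data$flow_lpm) < 1e-12)
    stop("degenerate sweep: flow is constant, parameters not identifiable",
         call. = FALSE)
  g <- unlist(init[c("R", "dR0", "Q0", "A", "K")])
  if (any(!is.finite(g)) || any(g <= 0))
    stop("initial guess must supply positive R, dR0, Q0, A, K",
         call. = FALSE)

  o <- data$opening_pct
  q <- data$flow_lpm
  # optimise on the log scale: enforces positivity and evens out scales
  obj <- function(lp) {
    p <- exp(lp)
    E <- exp(p[5] * o) - 1
    pred <- (1 + p[2] / p[1]) * p[3] * p[1] * p[4] * E /
      (1 + (p[1] + p[2]) * p[4] * E)
    if (any(!is.finite(pred))) return(1e12)
    sum((q - pred)^2)
  }

  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- log(g)
    if (s > 1) start <- start + stats::rnorm(5, 0, 0.4)
    fit <- stats::nlminb(start, obj,
                         control = list(iter.max = 500, eval.max = 1000))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  p <- exp(best$par)
  # nlminb reports "false convergence" when started at an exact optimum;
  # a residual that is negligible against the data spread is a success
  tss <- sum((q - mean(q))^2)
  converged <- best$convergence == 0 || best$objective < 1e-8 * tss
  params <- plant_params(R = p[1], dR0 = p[2], Q0 = p[3], A = p[4], K = p[5],
                         dead_time = if (!is.null(init$dead_time))
                           init$dead_time else 0,
                         tau = if (!is.null(init$tau)) init$tau else 1)
  structure(list(params = params,
                 residual_norm = sqrt(best$objective),
                 converged = converged,
                 n_points = length(o)),
            class = "static_fit")
}

#' @export
print.static_fit <- function(x, ...) {
  cat(sprintf("Static fit on %d points: residual norm %.4g (%s)\n",
              x$n_points, x$residual_norm,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  invisible(x)
}

#' Fit the actuator dead time and time constant from a step response
#'
#' Least-squares fit of a delayed first-order step response
#' \eqn{y(t) = y_0 + \Delta (1 - e^{-\max(0, t - L)/T})} to the recorded
#' transient, jointly over \eqn{(y_0, \Delta, L, T)}. The full trajectory
#' is used rather than the two-point 63.2 % method, for noise robustness;
#' the dead time is seeded from a small grid because the loss has a kink
#' in L.
#'
#' @param data A step dataset (`time_s`, `response`) covering the full
#'   transient.
#' @return A list of class `dynamic_fit`: `dead_time`, `tau`,
#'   `residual_norm`, `converged`.
#' @export
fit_dynamic_params <- function(data) {
  if (!all(c("time_s", "response") %in% names(data)))
    stop("data must have columns time_s and response", call. = FALSE)
  t <- data$time_s
  y <- data$response
  if (is.unsorted(t, strictly = TRUE))
    stop("time must be strictly increasing", call. = FALSE)
  y0 <- mean(y[seq_len(max(1L, floor(length(y) * 0.02)))])
  yf <- mean(y[seq.int(ceiling(length(y) * 0.9), length(y))])
  if (abs(yf - y0) < 1e-9)
    stop("degenerate step record: no transient detected", call. = FALSE)

  obj <- function(par) {
    # par = (y0, delta, L, T); L, T kept positive through the bounds below
    pred <- par[1] + par[2] * (1 - exp(-pmax(0, t - par[3]) / par[4]))
    sum((y - pred)^2)
  }
  span <- max(t) - min(t)
  # crude L guess: first time the response covers 2% of the step
  risen <- which(abs(y - y0) >= 0.02 * abs(yf - y0))
  L0 <- if (length(risen)) t[risen[1L]] else 0
  T0 <- max(span / 10, 10 * (t[2] - t[1]))
  best <- NULL
  for (Lg in unique(pmax(0, c(L0, 0, L0 / 2, 2 * L0)))) {
    fit <- stats::nlminb(c(y0, yf - y0, Lg, T0), obj,
                         lower = c(-Inf, -Inf, 0, 1e-6),
                         upper = c(Inf, Inf, span / 2, span),
                         control = list(iter.max = 500))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (!is.finite(best$objective) ||
      best$objective > 0.25 * sum((y - mean(y))^2))
    return(structure(list(dead_time = NA_real_, tau = NA_real_,
                          residual_norm = sqrt(best$objective),
                          converged = FALSE),
                     class = "dynamic_fit"))
  structure(list(dead_time = best$par[3], tau = best$par[4],
                 residual_norm = sqrt(best$objective),
                 converged = best$convergence == 0),
            class = "dynamic_fit")
}

#' @export
print.dynamic_fit <- function(x, ...) {
  cat(sprintf("FOPDT fit: dead time L = %.4g s, time constant T = %.4g s (%s)\n",
              x$dead_time, x$tau,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}
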