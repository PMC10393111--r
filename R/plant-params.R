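#' Plant parameters for the occluder/flow model
#'
#' Bundles the seven constants of the CPB hydraulic model: a nonlinear
#' static map from arterial-occluder opening ratio to arterial flow, in
#' series with first-order-plus-dead-time (FOPDT) actuator dynamics.
#'
#' The static map is
#' \deqn{Q(O') = \frac{(1 + \Delta R_0 / R)\, Q_0\, R\, A\, E}{1 + R A E + \Delta R_0 A E},
#'       \qquad E = e^{K O'} - 1,}
#' where \eqn{O'} is the effective opening ratio in percent. \eqn{Q} is zero
#' at \eqn{O' = 0}, strictly increasing, and approaches (never attains) the
#' full-open flow \eqn{Q_0} as \eqn{O' \to \infty}. The commanded opening
#' reaches the effective opening through a dead time `dead_time` and a
#' first-order lag with time constant `tau`.
#'
#' @param R Hydraulic resistance of the circuit excluding the occluder
#'   channel (consistent arbitrary units, > 0).
#' @param dR0 Resistance of the occluder channel (same units, > 0).
#' @param Q0 Flow at 100 % occluder opening, L/min (> 0).
#' @param A Dimensionless tube-crush shape parameter (> 0).
#' @param K Exponential rate per percent opening (> 0).
#' @param dead_time Actuator dead time L, seconds (>= 0).
#' @param tau First-order actuator time constant T, seconds (> 0).
#' @return An object of class `plant_params`.
#' @seealso [plant_preset()], [occluder_static_flow()]
#' @examples
#' p <- plant_params(R = 1, dR0 = 0.1, Q0 = 5, A = 0.01, K = 0.08,
#'                   dead_time = 0.3, tau = 1.5)
#' occluder_static_flow(50, p)
#' @export
plant_params <- function(R, dR0, Q0, A, K, dead_time = 0, tau = 1) {
  p <- list(R = R, dR0 = dR0, Q0 = Q0, A = A, K = K,
            dead_time = dead_time, tau = tau)
  validate_plant_params(p)
  structure(p, class = "plant_params")
}

validate_plant_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("R", "dR0", "Q0", "A", "K", "dead_time", "tau")) {
    if (!num1(p[[f]]))
      stop("plant parameter '", f, "' must be a finite numeric scalar",
           call. = FALSE)
  }
  pos <- c("R", "dR0", "Q0", "A", "K", "tau")
  bad <- pos[vapply(pos, function(f) p[[f]] <= 0, logical(1))]
  if (length(bad))
    stop("plant parameter(s) must be > 0: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (p$dead_time < 0) stop("dead_time must be >= 0", call. = FALSE)
  invisible(p)
}

#' @export
print.plant_params <- function(x, ...) {
  cat("CPB plant parameters\n")
  cat(sprintf("  static : R = %g, dR0 = %g, Q0 = %g L/min, A = %g, K = %g /%%\n",
              x$R, x$dR0, x$Q0, x$A, x$K))
  cat(sprintf("  dynamic: dead time L = %g s, time constant T = %g s\n",
              x$dead_time, x$tau))
  invisible(x)
}

#' Named plant parameter presets
#'
#' Returns a synthetic but physically plausible parameter set for a
#' glycerin-primed or bovine-blood-primed circuit. The presets are
#' stand-ins chosen so that the full-open flow, the opening ratio needed
#' for a typical adult flow of 4 L/min, and the actuator response times
#' are realistic for an adult CPB circuit; they are not measurements.
#'
#' @param name `"glycerin"` or `"blood"`.
#' @return A [plant_params()] object.
#' @export
plant_preset <- function(name = c("glycerin", "blood")) {
  name <- match.arg(name)
  switch(name,
    glycerin = plant_params(R = 1,   dR0 = 0.1,  Q0 = 5,   A = 0.01,
                            K = 0.08,  dead_time = 0.3,  tau = 1.5),
    blood    = plant_params(R = 1.2, dR0 = 0.15, Q0 = 4.8, A = 0.012,
                            K = 0.075, dead_time = 0.35, tau = 1.8))
}

#' Static occluder-to-flow map
#'
#' Evaluates the nonlinear static map from effective occluder opening
#' ratio to arterial flow rate (see [plant_params()] for the formula).
#' Vectorised over `opening`.
#'
#' @param opening Effective opening ratio in percent, in \[0, 100\].
#' @param params A [plant_params()] object.
#' @return Flow rate(s), L/min, in \[0, Q0).
#' @export
occluder_static_flow <- function(opening, params) {
  stopifnot(inherits(params, "plant_params"))
  if (any(!is.finite(opening)) || any(opening < 0) || any(opening > 100))
    stop("opening must be within [0, 100]", call. = FALSE)
  E <- exp(params$K * opening) - 1
  num <- (1 + params$dR0 / params$R) * params$Q0 * params$R * params$A * E
  den <- 1 + params$R * params$A * E + params$dR0 * params$A * E
  q <- num / den
  if (any(!is.finite(q)))
    stop("static map overflowed (exp(K * opening) not representable); ",
         "check shape parameters", call. = FALSE)
  q
}

#' Invert the static occluder-to-flow map
#'
#' Closed-form inverse of [occluder_static_flow()], used by the
#' feedforward path of the flow controller. Solving the static map for
#' \eqn{E} gives \eqn{E = Q / (A (R + \Delta R_0)(Q_0 - Q))} and
#' \eqn{O' = \log(E + 1) / K}.
#'
#' @param flow Flow rate(s), L/min; must satisfy `0 <= flow < Q0`.
#' @param params A [plant_params()] object.
#' @return Effective opening ratio(s), percent.
#' @export
occluder_static_inverse <- function(flow, params) {
  stopifnot(inherits(params, "plant_params"))
  if (any(!is.finite(flow)) || any(flow < 0))
    stop("flow must be finite and >= 0", call. = FALSE)
  if (any(flow >= params$Q0))
    stop("infeasible setpoint: flow must be below the full-open flow Q0 = ",
         params$Q0, " L/min (supremum of the static map)", call. = FALSE)
  E <- flow / (params$A * (params$R + params$dR0) * (params$Q0 - flow))
  log1p(E) / params$K
}
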