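#' Flow-tracking error metric J_Q%
#'
#' Mean absolute percentage error between the reference flow
#' \eqn{Q_m(i)} and the measured arterial flow \eqn{Q(i)}:
#' \deqn{J_{Q\%} = \frac{1}{N} \sum_{i=1}^{N}
#'   \left| \frac{Q_m(i) - Q(i)}{Q_m(i)} \right| \times 100.}
#' Samples where \eqn{|Q_m|} falls below `floor_lpm` are excluded from the
#' mean (the relative error is singular at zero reference, as at the very
#' start of flow-up) and their count is reported.
#'
#' @param q_m Reference flow series, L/min.
#' @param q Measured arterial flow series, L/min (same length).
#' @param floor_lpm Exclusion floor on `|q_m|`, L/min.
#' @return Percentage error (scalar) with attribute `n_excluded`.
#' @export
j_q_percent <- function(q_m, q, floor_lpm = 0.1) {
  if (length(q_m) != length(q) || length(q_m) < 1L)
    stop("q_m and q must be non-empty series of equal length", call. = FALSE)
  keep <- abs(q_m) >= floor_lpm
  if (!any(keep))
    stop("undefined metric: every sample fell below the |q_m| floor of ",
         floor_lpm, " L/min", call. = FALSE)
  val <- mean(abs((q_m[keep] - q[keep]) / q_m[keep])) * 100
  attr(val, "n_excluded") <- sum(!keep)
  val
}

#' Reservoir-level error metric J_L%
#'
#' Mean absolute percentage error between the target level \eqn{L_T} and
#' the measured level \eqn{L(i)}:
#' \deqn{J_{L\%} = \frac{1}{N} \sum_{i=1}^{N}
#'   \left| \frac{L_T - L(i)}{L_T} \right| \times 100.}
#'
#' @param level Measured level series, L.
#' @param target_level Target level \eqn{L_T}, L (> 0).
#' @return Percentage error (scalar).
#' @export
j_l_percent <- function(level, target_level) {
  if (!is.numeric(target_level) || length(target_level) != 1L ||
      target_level <= 0)
    stop("target_level must be a positive scalar", call. = FALSE)
  if (length(level) < 1L) stop("level series must be non-empty", call. = FALSE)
  mean(abs((target_level - level) / target_level)) * 100
}

#' Metric report for a logged trial
#'
#' Computes both evaluation metrics from a trial time-series table (see
#' [write_timeseries()] for the schema): J_Q% from the shaped reference
#' `q_ref` against the measured arterial flow `q_arterial`, and J_L% from
#' the measured level `level_meas_L` against the target.
#'
#' @param ts A trial time-series data frame.
#' @param target_level Target level, L.
#' @param skip_initial Seconds to drop from the start before scoring
#'   (default 0: the full record, transients included, is scored).
#' @return A list of class `metric_report` with `j_q_percent`,
#'   `j_l_percent`, `n_samples`, `n_excluded`, `target_level`.
#' @export
metric_report <- function(ts, target_level = 0.45, skip_initial = 0) {
  need <- c("time_s", "q_ref", "q_arterial", "level_meas_L")
  miss <- setdiff(need, names(ts))
  if (length(miss))
    stop("time series is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (skip_initial > 0) ts <- ts[ts$time_s >= skip_initial, , drop = FALSE]
  jq <- j_q_percent(ts$q_ref, ts$q_arterial)
  structure(list(j_q_percent = as.numeric(jq),
                 j_l_percent = j_l_percent(ts$level_meas_L, target_level),
                 n_samples = nrow(ts),
                 n_excluded = attr(jq, "n_excluded"),
                 target_level = target_level),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("J_Q%% = %.3f%%   J_L%% = %.3f%%   (N = %d, %d sample(s) below the q_m floor; L_T = %g L)\n",
              x$j_q_percent, x$j_l_percent, x$n_samples, x$n_excluded,
              x$target_level))
  invisible(x)
}
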