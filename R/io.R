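TS_COLUMNS <- c("time_s", "q_venous", "q_ref", "q_arterial", "occ_cmd",
                "occ_eff", "level_L", "level_meas_L", "disturbance")

#' Write a trial time-series table to CSV
#'
#' Fixed column order:
#' `time_s,q_venous,q_ref,q_arterial,occ_cmd,occ_eff,level_L,level_meas_L,disturbance`.
#'
#' @param ts Data frame containing (at least) the schema columns.
#' @param path Output CSV path.
#' @export
write_timeseries <- function(ts, path) {
  miss <- setdiff(TS_COLUMNS, names(ts))
  if (length(miss))
    stop("time series is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  utils::write.csv(ts[, TS_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read a trial time-series CSV
#'
#' Validates the header against the schema of [write_timeseries()] and
#' checks that time is strictly increasing.
#'
#' @param path CSV path.
#' @return A data frame with the schema columns.
#' @export
read_timeseries <- function(path) {
  ts <- utils::read.csv(path)
  miss <- setdiff(TS_COLUMNS, names(ts))
  if (length(miss))
    stop("file '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (is.unsorted(ts$time_s, strictly = TRUE))
    stop("time_s must be strictly increasing in '", path, "'",
         call. = FALSE)
  ts[, TS_COLUMNS]
}

CONFIG_KEYS <- list(
  plant = c("R", "dR0", "Q0", "A", "K", "dead_time", "tau"),
  sensor = c("flow_noise_sd", "lowpass_cutoff", "level_noise_sd",
             "level_quantum"),
  control = c("ref_model_tau", "flow_kp", "flow_ki", "flow_kd",
              "flow_deriv_tau", "level_ki", "level_kp", "level_kd",
              "level_deriv_tau", "flow_correction_limit", "occ_min",
              "occ_max", "sample_time"))

#' Load and validate a JSON configuration
#'
#' Reads a JSON file with optional top-level sections `plant`, `sensor`
#' and `control`. Unknown sections or keys are rejected with a message
#' naming them; values are validated by the respective constructors.
#' Missing sections fall back to package defaults (the glycerin plant
#' preset and default sensor/controller settings).
#'
#' @param path JSON config path.
#' @return A list with validated `plant` ([plant_params()]), `sensor`
#'   ([sensor_config()]) and `control` ([controller_config()]) objects.
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(raw), names(CONFIG_KEYS))
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (sec in names(CONFIG_KEYS)) {
    extra <- setdiff(names(raw[[sec]]), CONFIG_KEYS[[sec]])
    if (length(extra))
      stop("unknown key(s) in section '", sec, "': ",
           paste(extra, collapse = ", "), call. = FALSE)
  }
  plant <- if (is.null(raw$plant)) plant_preset("glycerin")
    else do.call(plant_params, as.list(raw$plant))
  sensor <- if (is.null(raw$sensor)) sensor_config()
    else do.call(sensor_config, as.list(raw$sensor))
  control <- if (is.null(raw$control)) controller_config(plant = plant)
    else do.call(controller_config,
                 c(list(plant = plant), as.list(raw$control)))
  list(plant = plant, sensor = sensor, control = control)
}

#' Write a plant/sensor/control configuration to JSON
#'
#' @param config A list with any of `plant`, `sensor`, `control` objects
#'   (as returned by [load_config()] or built from the constructors).
#' @param path Output JSON path.
#' @export
write_config <- function(config, path) {
  out <- list()
  for (sec in intersect(names(CONFIG_KEYS), names(config)))
    out[[sec]] <- unclass(config[[sec]])[CONFIG_KEYS[[sec]]]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
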