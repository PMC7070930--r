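# Measurement / configuration file IO.

#' Write a measurement as CSV
#'
#' Columns are `time_s,temp_C` followed by `<mode_id>_freq_Hz` and
#' `<mode_id>_Q` per tracked mode. Units: seconds, degrees C, Hz.
#'
#' @param measurement an `mta_measurement`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurement <- function(measurement, path) {
  stopifnot(inherits(measurement, "mta_measurement"))
  df <- data.frame(time_s = measurement$time, temp_C = measurement$temperature)
  for (id in measurement$mode_ids) {
    df[[paste0(id, "_freq_Hz")]] <- measurement$freq[[id]]
    df[[paste0(id, "_Q")]] <- measurement$quality[[id]]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load a measurement trace from CSV
#'
#' Reads a CSV written by [write_measurement()] (or any file following its
#' header contract) into an `mta_measurement`. Mode identifiers are parsed
#' from the `<id>_freq_Hz` / `<id>_Q` column pairs.
#'
#' @param path CSV path with mandatory header `time_s,temp_C` plus at least
#'   one `<id>_freq_Hz` column.
#' @param P modulation period to associate with the trace, seconds.
#' @return An `mta_measurement`.
#' @export
load_trace <- function(path, P = 20) {
  df <- utils::read.csv(path)
  for (col in c("time_s", "temp_C")) {
    if (!col %in% names(df)) {
      stop(sprintf("missing required column '%s' in %s", col, path))
    }
  }
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    stop("time_s column must be strictly increasing")
  }
  fcols <- grep("_freq_Hz$", names(df), value = TRUE)
  if (!length(fcols)) stop("missing required column '<mode>_freq_Hz'")
  ids <- sub("_freq_Hz$", "", fcols)
  freq <- stats::setNames(lapply(fcols, function(cn) df[[cn]]), ids)
  quality <- stats::setNames(lapply(ids, function(id) {
    qc <- paste0(id, "_Q")
    if (qc %in% names(df)) df[[qc]] else rep(NA_real_, nrow(df))
  }), ids)
  dt <- stats::median(diff(df$time_s))
  structure(list(time = df$time_s, temperature = df$temp_C, freq = freq,
                 quality = quality, mode_ids = ids, dt = dt,
                 program = temperature_program(T0 = df$temp_C[1L], P = P),
                 truth = NULL),
            class = "mta_measurement")
}

#' Write a scenario bundle's configuration and ground truth
#'
#' Writes the flat scenario/program configuration as YAML-compatible
#' `key: value` text and echoes the embedded ground truth into a JSON
#' sidecar.
#'
#' @param bundle an [make_scenario()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
write_bundle_config <- function(bundle, dir) {
  stopifnot(inherits(bundle, "mta_scenario_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- c(list(name = bundle$name, seed = bundle$seed,
                duration_s = bundle$duration, dt_s = bundle$dt),
           unclass(bundle$program),
           stats::setNames(unclass(bundle$scenario),
                           paste0("scenario_", names(unclass(bundle$scenario)))))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  truth <- unclass(bundle$scenario)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(config = cfg_path, truth = truth_path))
}

#' Read a flat YAML configuration
#' @param path YAML file path.
#' @return Named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)
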