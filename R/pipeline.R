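# One-command end-to-end pipeline.

#' Pipeline run configuration
#'
#' @param trace path to a measurement CSV ([load_trace()] contract), or
#'   `NULL` to simulate the named `scenario` instead.
#' @param scenario registered scenario name used when `trace` is `NULL`.
#' @param frames_dir optional directory of numbered PNG frames plus a
#'   `frames.csv` index for the image-analysis stage.
#' @param grid_files optional character vector of mode-grid CSV files for
#'   the mode-classification stage.
#' @param P modulation period, seconds.
#' @param dt sampling interval, seconds.
#' @param prominence_frac reversing-signal / quality peak prominence rule.
#' @param mixedness mode-classification mixedness threshold.
#' @param debounce_n mode-switch debounce, samples.
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return A list of class `mta_run_config`.
#' @export
run_config <- function(trace = NULL, scenario = "indomethacin_default",
                       frames_dir = NULL, grid_files = NULL,
                       P = 20, dt = 0.2, prominence_frac = 0.2,
                       mixedness = 0.3, debounce_n = 3,
                       seed = 1L, out_dir = tempfile("mta_run_")) {
  if (prominence_frac <= 0 || prominence_frac > 1) {
    stop("prominence_frac must lie in (0, 1]")
  }
  if (mixedness <= 0 || mixedness > 1) stop("mixedness must lie in (0, 1]")
  if (debounce_n < 1) stop("debounce_n must be >= 1")
  structure(list(trace = trace, scenario = scenario, frames_dir = frames_dir,
                 grid_files = grid_files, P = P, dt = dt,
                 prominence_frac = prominence_frac, mixedness = mixedness,
                 debounce_n = debounce_n, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "mta_run_config")
}

# Stable hash of a configuration: MD5 of its canonical JSON rendering.
# The output directory is excluded: it determines where results go, not
# what is computed.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Loads (or simulates) a measurement, deconvolves every tracked mode,
#' builds the glass-transition report for the first mode, and -- when the
#' corresponding inputs are present -- tracks image contour levels and
#' classifies mode grids. Writes `report.json`, a `deconvolution.csv`
#' intermediate, and (when applicable) `areas.csv` to `config$out_dir`;
#' every output embeds the configuration hash.
#'
#' @param config an [run_config()].
#' @return List of class `mta_run_result` with `report` (`mta_tg_report`),
#'   `deconv`, optional `contours` and `mode_labels`, `config_hash`, and
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mta_run_config"))
  hash <- config_hash(config)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s (partial outputs in %s)",
                   name, conditionMessage(e), config$out_dir), call. = FALSE)
    })
  }

  measurement <- stage("load", {
    if (!is.null(config$trace)) {
      load_trace(config$trace, P = config$P)
    } else {
      bundle <- make_scenario(config$scenario, seed = config$seed)
      simulate_bundle(bundle)
    }
  })

  deconv <- stage("deconvolve", deconvolve(measurement, P = config$P))
  utils::write.csv(cbind(as.data.frame(deconv), config_hash = hash),
                   file.path(config$out_dir, "deconvolution.csv"),
                   row.names = FALSE)

  report <- stage("detect", {
    build_report(deconv, measurement$quality[[deconv$mode_id]],
                 prominence_frac = config$prominence_frac)
  })

  contours <- NULL
  if (!is.null(config$frames_dir)) {
    contours <- stage("image-track", {
      stack <- read_frames(config$frames_dir)
      frame_dt <- {
        tc <- attr(stack, "temp_C")
        # frame spacing in seconds from the temperature spacing and ramp rate
        if (length(tc) > 1L) {
          mean(diff(tc)) / (measurement$program$rate / 60)
        } else {
          config$dt
        }
      }
      res <- track_levels(stack, px_per_um = 1.5, P = config$P, dt = frame_dt)
      df <- data.frame(frame = seq_len(nrow(res$areas)), temp_C = res$temp_C)
      for (l in seq_len(ncol(res$areas))) {
        df[[paste0("level", l, "_px")]] <- res$areas[, l]
        df[[paste0("level", l, "_px_smooth")]] <- res$smoothed[, l]
      }
      df$config_hash <- hash
      utils::write.csv(df, file.path(config$out_dir, "areas.csv"),
                       row.names = FALSE)
      res
    })
  }

  mode_labels <- NULL
  if (!is.null(config$grid_files)) {
    mode_labels <- stage("modes", {
      lapply(config$grid_files, function(p) {
        classify_mode(read_mode_grid(p), mixedness = config$mixedness)
      })
    })
  }

  elapsed <- proc.time()[["elapsed"]] - t0
  report_body <- list(
    config_hash = hash,
    mode_id = report$mode_id,
    tg_f = report$tg_f,
    rs_maxima = report$rs_maxima,
    tg_q = report$tg_q,
    tg_q_method = report$tg_q_method,
    ufs_onset = report$ufs_onset,
    delta_qf = report$delta_qf,
    detuning = report$detuning,
    flags = report$flags,
    area_minima = if (!is.null(contours)) area_minima(contours),
    mode_labels = if (!is.null(mode_labels)) {
      lapply(mode_labels, function(l) {
        list(harmonic = l$harmonic, descriptor = l$descriptor)
      })
    }
  )
  jsonlite::write_json(report_body, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  message(sprintf("pipeline finished in %.1f s (config %s)", elapsed, hash))
  structure(list(report = report, deconv = deconv, contours = contours,
                 mode_labels = mode_labels, config_hash = hash,
                 out_dir = config$out_dir),
            class = "mta_run_result")
}
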