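# End-to-end pipeline: read -> envelope -> events -> segment -> on/off ->
# components -> (score) -> write artifacts, with a resolved-config record
# for provenance.

#' Default pipeline configuration
#'
#' Defaults follow the reference processing chain: 20 Hz high-pass, 25 Hz
#' low-pass, 4th order, 20 N event threshold, k = 5 clusters, +/-2.57
#' normal window.
#'
#' @param ... overrides of any default field.
#' @return A named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(highpass_hz = 20, lowpass_hz = 25, filter_order = 4,
              threshold_N = 20, debounce_s = 0.05, k = 5,
              window = 2.57, speed_mps = NA_real_,
              emg_is_envelope = FALSE,
              emg = NULL, grf = NULL, sidecar = NULL, norm = NULL,
              out_dir = ".", stem = "amap", seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop_config(sprintf("unknown config field(s): %s",
                        paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  cfg
}

#' Run the full AMAP pipeline for one trial
#'
#' Executes read -> envelope extraction -> event detection -> six-region
#' segmentation -> peak normalization -> k-means on/off -> component
#' computation and, when a normative profile is supplied, z-scoring. Writes
#' the component CSV, the report CSV/JSON and a run log (resolved config
#' plus stride count). Stage failures are re-signalled with the stage name
#' and subject id attached.
#'
#' @param config list from [pipeline_config()], or a path to a JSON file of
#'   overrides.
#' @return Invisibly, a list with `components`, `report` (or NULL),
#'   `paths`, `n_strides`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop_config(sprintf("config file not found: %s", config))
    config <- do.call(pipeline_config,
                      jsonlite::read_json(config, simplifyVector = TRUE))
  }
  subject <- "?"
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "amap_config_error"))
        stop_config(sprintf("[%s, subject %s] %s", name, subject,
                            conditionMessage(e)))
      stop_data(sprintf("[%s, subject %s] %s", name, subject,
                        conditionMessage(e)),
                class(e)[1])
    })
  }
  trial <- stage("read", {
    if (is.null(config$emg) || is.null(config$grf) ||
        is.null(config$sidecar))
      stop_config("emg, grf and sidecar paths are required")
    read_trial(config$emg, config$grf, config$sidecar)
  })
  subject <- trial$emg$subject_id
  env <- stage("preprocess", {
    if (isTRUE(config$emg_is_envelope))
      envelope_recording(trial$emg$signals, trial$emg$rate_hz,
                         trial$emg$channel_names, leg = trial$emg$leg,
                         subject_id = trial$emg$subject_id)
    else
      filter_chain(trial$emg, config$highpass_hz, config$lowpass_hz,
                   config$filter_order)
  })
  events <- stage("events",
                  detect_events(trial$grf, config$threshold_N,
                                config$debounce_s))
  strides <- stage("segment", segment_strides(events, trial$emg$leg))
  env <- stage("normalize", normalize_to_step_peaks(env, strides))
  mask <- stage("onoff", kmeans_onoff(env, k = config$k))
  comp <- stage("components",
                compute_components(env, mask, strides,
                                   speed_mps = config$speed_mps))
  report <- NULL
  if (!is.null(config$norm)) {
    norm <- stage("score", read_normative_profile(config$norm))
    report <- stage("score", score_subject(comp, norm, config$window))
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(components = file.path(config$out_dir,
                                    paste0(config$stem,
                                           "_components.csv")))
  write_exact_csv(components_to_df(comp), paths[["components"]])
  if (!is.null(report)) {
    rp <- file.path(config$out_dir, paste0(config$stem, "_report.csv"))
    write_report(report, rp)
    paths[["report"]] <- rp
  }
  logp <- file.path(config$out_dir, paste0(config$stem, "_run.json"))
  cfg_rec <- config[!vapply(config, is.null, logical(1))]
  jsonlite::write_json(list(config = cfg_rec,
                            config_hash = config_hash(cfg_rec),
                            subject_id = subject,
                            n_strides = comp$n_strides),
                       logp, auto_unbox = TRUE, digits = NA)
  paths[["log"]] <- logp
  invisible(list(components = comp, report = report, paths = paths,
                 n_strides = comp$n_strides))
}

components_to_df <- function(comp) {
  muscles <- rownames(comp$timing)
  grid <- expand.grid(muscle = muscles, region = REGIONS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$timing <- comp$timing[cbind(grid$muscle, grid$region)]
  grid$amplitude <- comp$amplitude[cbind(grid$muscle, grid$region)]
  grid$n_strides <- comp$n_strides
  grid$subject_id <- comp$subject_id
  grid
}

# stable content hash of the resolved configuration (polynomial rolling
# hash over the serialized key=value pairs; provenance only)
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 17), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
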