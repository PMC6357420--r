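# Recording containers and file I/O.
#
# Interchange convention: wide CSV (one column per channel) plus a JSON
# sidecar declaring {rate_hz, channels, leg, subject_id} and, for GRF,
# {grf_rate_hz, belt_map}. All internal time is seconds; sample i (1-based)
# covers the half-open interval [(i-1)/rate, i/rate).

#' EMG recording
#'
#' Container for multi-channel surface EMG from one leg of one subject.
#'
#' @param signals numeric matrix, samples x channels.
#' @param rate_hz sampling frequency in Hz (> 0).
#' @param channel_names unique muscle labels, one per column.
#' @param leg one of `"left"`, `"right"`, `"paretic"`, `"nonparetic"`.
#' @param subject_id opaque subject identifier.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(signals, rate_hz, channel_names = colnames(signals),
                          leg = "left", subject_id = "anon") {
  signals <- as.matrix(signals)
  if (!is.numeric(signals) || anyNA(signals))
    stop_data("EMG signals must be numeric with no missing samples",
              "amap_parse_error")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop_config("rate_hz must be a single positive number")
  if (is.null(channel_names) || length(channel_names) != ncol(signals))
    stop_data("channel_names must match the number of signal columns",
              "amap_schema_error")
  if (anyDuplicated(channel_names))
    stop_data(sprintf("duplicate channel name(s): %s",
                      paste(unique(channel_names[duplicated(channel_names)]),
                            collapse = ", ")),
              "amap_schema_error")
  leg <- match.arg(leg, c("left", "right", "paretic", "nonparetic"))
  colnames(signals) <- channel_names
  structure(list(signals = signals, rate_hz = as.numeric(rate_hz),
                 channel_names = as.character(channel_names),
                 leg = leg, subject_id = as.character(subject_id)),
            class = "emg_recording")
}

#' Ground reaction force recording
#'
#' Bilateral vertical and anterior GRF from a split-belt instrumented
#' treadmill. Columns are named by leg (via `belt_map`); anterior force is
#' positive in the direction of progression (propulsive).
#'
#' @param vertical numeric matrix (N), samples x belts.
#' @param anterior numeric matrix (N), same shape as `vertical`.
#' @param rate_hz sampling frequency in Hz (> 0).
#' @param belt_map character vector of leg ids, one per belt/column.
#' @return An object of class `grf_recording`.
#' @export
grf_recording <- function(vertical, anterior, rate_hz,
                          belt_map = c("left", "right")) {
  vertical <- as.matrix(vertical); anterior <- as.matrix(anterior)
  if (!is.numeric(vertical) || !is.numeric(anterior) ||
      anyNA(vertical) || anyNA(anterior))
    stop_data("GRF samples must be numeric with no missing values",
              "amap_parse_error")
  if (!identical(dim(vertical), dim(anterior)))
    stop_data("vertical and anterior GRF must have identical dimensions",
              "amap_schema_error")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop_config("rate_hz must be a single positive number")
  if (length(belt_map) != ncol(vertical) || anyDuplicated(belt_map))
    stop_data("belt_map must give one unique leg id per belt",
              "amap_schema_error")
  colnames(vertical) <- belt_map; colnames(anterior) <- belt_map
  structure(list(vertical = vertical, anterior = anterior,
                 rate_hz = as.numeric(rate_hz),
                 belt_map = as.character(belt_map)),
            class = "grf_recording")
}

read_numeric_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e)
                   stop_data(sprintf("cannot parse %s: %s", path,
                                     conditionMessage(e)), "amap_parse_error"))
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))) &
                     !is.na(df[[j]]))
      stop_data(sprintf("non-numeric sample in %s, column '%s', row %s",
                        path, names(df)[j],
                        if (length(bad)) bad[1] else "?"),
                "amap_parse_error")
    }
  }
  if (anyNA(df))
    stop_data(sprintf("missing sample values in %s", path),
              "amap_parse_error")
  as.matrix(df)
}

#' Read one gait-lab trial (EMG + GRF + sidecar)
#'
#' Reads wide-format EMG and GRF CSV files together with a JSON sidecar
#' declaring sampling rates and the channel map. EMG and GRF may be sampled
#' at different rates; both are kept on a seconds time base.
#'
#' The sidecar must contain `rate_hz`, `channels`, `leg`, `subject_id`; it
#' may add `grf_rate_hz` (defaults to `rate_hz`) and `belt_map` (defaults to
#' left/right). GRF CSV columns are `vertical_<leg>` and `anterior_<leg>`
#' for each leg in `belt_map`.
#'
#' @param emg_path path to the EMG CSV (one column per muscle).
#' @param grf_path path to the GRF CSV.
#' @param sidecar_path path to the JSON sidecar.
#' @return A list with elements `emg` ([emg_recording]) and `grf`
#'   ([grf_recording]).
#' @export
read_trial <- function(emg_path, grf_path, sidecar_path) {
  for (p in c(emg_path, grf_path, sidecar_path))
    if (!file.exists(p))
      stop_data(sprintf("file not found: %s", p), "amap_io_error")
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  need <- c("rate_hz", "channels", "leg", "subject_id")
  miss <- setdiff(need, names(side))
  if (length(miss))
    stop_data(sprintf("sidecar missing key(s): %s",
                      paste(miss, collapse = ", ")), "amap_schema_error")
  if (anyDuplicated(side$channels))
    stop_data("sidecar lists a channel more than once", "amap_schema_error")

  emg_mat <- read_numeric_csv(emg_path)
  if (!setequal(colnames(emg_mat), side$channels))
    stop_data(sprintf(
      "EMG columns do not match sidecar channels (missing: %s; extra: %s)",
      paste(setdiff(side$channels, colnames(emg_mat)), collapse = ","),
      paste(setdiff(colnames(emg_mat), side$channels), collapse = ",")),
      "amap_schema_error")
  emg_mat <- emg_mat[, side$channels, drop = FALSE]
  emg <- emg_recording(emg_mat, side$rate_hz, side$channels,
                       leg = side$leg, subject_id = side$subject_id)

  belt_map <- if (!is.null(side$belt_map)) unlist(side$belt_map)
              else c("left", "right")
  grf_rate <- if (!is.null(side$grf_rate_hz)) side$grf_rate_hz else side$rate_hz
  grf_mat <- read_numeric_csv(grf_path)
  vcols <- paste0("vertical_", belt_map); acols <- paste0("anterior_", belt_map)
  miss <- setdiff(c(vcols, acols), colnames(grf_mat))
  if (length(miss))
    stop_data(sprintf("GRF CSV missing column(s): %s",
                      paste(miss, collapse = ", ")), "amap_schema_error")
  grf <- grf_recording(grf_mat[, vcols, drop = FALSE],
                       grf_mat[, acols, drop = FALSE],
                       grf_rate, belt_map)
  list(emg = emg, grf = grf)
}

#' Write one gait-lab trial to CSV + sidecar
#'
#' Inverse of [read_trial()]; used by the simulator's CLI output.
#'
#' @param emg an [emg_recording] (or envelope recording with `$signals`
#'   stored in `$envelopes`).
#' @param grf a [grf_recording].
#' @param dir output directory (created if needed).
#' @param stem file stem; writes `<stem>_emg.csv`, `<stem>_grf.csv`,
#'   `<stem>_sidecar.json`.
#' @return Invisibly, the three paths written.
#' @export
write_trial <- function(emg, grf, dir, stem = "trial") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig <- if (!is.null(emg$signals)) emg$signals else emg$envelopes
  emg_path <- file.path(dir, paste0(stem, "_emg.csv"))
  grf_path <- file.path(dir, paste0(stem, "_grf.csv"))
  side_path <- file.path(dir, paste0(stem, "_sidecar.json"))
  write_exact_csv(as.data.frame(sig), emg_path)
  gdf <- cbind(as.data.frame(grf$vertical), as.data.frame(grf$anterior))
  names(gdf) <- c(paste0("vertical_", grf$belt_map),
                  paste0("anterior_", grf$belt_map))
  write_exact_csv(gdf, grf_path)
  jsonlite::write_json(list(rate_hz = emg$rate_hz,
                            channels = emg$channel_names,
                            leg = emg$leg, subject_id = emg$subject_id,
                            grf_rate_hz = grf$rate_hz,
                            belt_map = grf$belt_map),
                       side_path, auto_unbox = TRUE, digits = NA)
  invisible(c(emg = emg_path, grf = grf_path, sidecar = side_path))
}

# CSV writer preserving doubles bit-exactly as decimal strings (%.17g
# round-trips IEEE doubles).
write_exact_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_data(sprintf("cannot write %s", path), "amap_io_error")
  invisible(path)
}

#' Write an AMAP report to CSV + JSON
#'
#' Writes a tidy CSV (one row per muscle x region x component, with the
#' z-score and outlier flag) and a JSON summary holding the per-muscle
#' totals, the window half-width and metadata. Doubles are serialized with
#' 17 significant digits so [read_report()] reproduces them bit-exactly.
#'
#' @param report an `amap_report` from [score_subject()].
#' @param path CSV output path; the JSON summary goes to the same path with
#'   extension `.json`.
#' @return Invisibly, the two paths written.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "amap_report"))
  df <- report_to_df(report)
  write_exact_csv(df, path)
  json_path <- sub("\\.csv$", ".json", path)
  if (identical(json_path, path)) json_path <- paste0(path, ".json")
  totals <- report$totals
  jsonlite::write_json(list(
    subject_id = report$subject_id,
    window_halfwidth = report$window_halfwidth,
    n_strides = report$n_strides,
    speed_band = report$speed_band,
    muscles = rownames(totals),
    totals = list(timing = sprintf("%.17g", totals[, "timing"]),
                  amplitude = sprintf("%.17g", totals[, "amplitude"]))),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = path, json = json_path))
}

report_to_df <- function(report) {
  muscles <- rownames(report$z$timing); regions <- colnames(report$z$timing)
  grid <- expand.grid(muscle = muscles, region = regions,
                      component = c("timing", "amplitude"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$muscle, muscles),
                     match(grid$region, regions), grid$component), ]
  grid$z <- if (nrow(grid)) {
    mapply(function(m, r, comp) report$z[[comp]][m, r],
           grid$muscle, grid$region, grid$component)
  } else numeric(0)
  grid$outlier <- abs(grid$z) > report$window_halfwidth
  rownames(grid) <- NULL
  grid
}

#' Read an AMAP report written by [write_report()]
#'
#' @param path the CSV path given to [write_report()].
#' @return An `amap_report` value-identical to the one written.
#' @export
read_report <- function(path) {
  json_path <- sub("\\.csv$", ".json", path)
  if (identical(json_path, path)) json_path <- paste0(path, ".json")
  for (p in c(path, json_path))
    if (!file.exists(p)) stop_data(sprintf("file not found: %s", p),
                                   "amap_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  muscles <- meta$muscles
  regions <- unique(df$region)
  if (length(regions) == 0) regions <- character(0)
  z <- list()
  for (comp in c("timing", "amplitude")) {
    m <- matrix(NA_real_, length(muscles), length(regions),
                dimnames = list(muscles, regions))
    sub <- df[df$component == comp, ]
    m[cbind(sub$muscle, sub$region)] <- sub$z
    z[[comp]] <- m
  }
  totals <- cbind(timing = as.numeric(meta$totals$timing),
                  amplitude = as.numeric(meta$totals$amplitude))
  rownames(totals) <- muscles
  new_amap_report(z = z, window_halfwidth = meta$window_halfwidth,
                  totals = totals, subject_id = meta$subject_id,
                  n_strides = meta$n_strides, speed_band = meta$speed_band)
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %s, leg %s: %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$leg, ncol(x$signals), nrow(x$signals),
              x$rate_hz))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.grf_recording <- function(x, ...) {
  cat(sprintf("<grf_recording> belts [%s]: %d samples @ %g Hz\n",
              paste(x$belt_map, collapse = ", "), nrow(x$vertical),
              x$rate_hz))
  invisible(x)
}
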