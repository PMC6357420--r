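# The AMAP scores themselves.
#
# Per stride, muscle and region r:
#   timing_r    = 100 * (on time within r) / (duration of r)
#   amplitude_r = 100 * (integrated envelope over on-samples in r) /
#                       (integrated envelope over all on-samples in stride)
# Component values are averaged across strides; amplitude components sum to
# 100 across the six regions whenever the muscle has any on-time in the
# stride. Scores are z-values against a speed-matched healthy profile;
# |z| <= 2.57 (the 99% central normal window) is "normal".

#' Timing and amplitude components per muscle and region
#'
#' Computes, stride by stride, the fraction of each region during which the
#' muscle is "on" (timing, % of region duration) and the share of the
#' stride's integrated on-envelope falling in each region (amplitude, % of
#' the stride total). Values are then averaged across strides. A stride in
#' which a muscle is never on contributes 0 to all its amplitude components
#' (with a warning), so amplitude conservation holds only for strides with
#' nonzero on-time.
#'
#' @param env an `envelope_recording` (normalized or not; amplitude
#'   components are scale-free within a stride).
#' @param mask an `onoff_mask` aligned to `env`.
#' @param strides list of `gait_segmentation` objects.
#' @param speed_mps optional walking speed carried into the result.
#' @return A `component_matrix`: `timing` and `amplitude` (muscle x region
#'   matrices, %), `n_strides`, `subject_id`, `speed_mps`.
#' @export
compute_components <- function(env, mask, strides, speed_mps = NA_real_) {
  stopifnot(inherits(env, "envelope_recording"),
            inherits(mask, "onoff_mask"))
  if (length(strides) < 1)
    stop_data("at least one stride is required", "amap_insufficient_data")
  if (!identical(dim(mask$mask), dim(env$envelopes)))
    stop_data("mask is not aligned to the envelope samples",
              "amap_mismatch_error")
  chans <- env$channel_names
  t <- sample_times(nrow(env$envelopes), env$rate_hz)
  tim_acc <- amp_acc <- matrix(0, length(chans), 6,
                               dimnames = list(chans, REGIONS))
  n_alloff <- 0L
  for (s in strides) {
    b <- s$boundaries
    # region index 1..6 for samples inside [b1, b7), 0/7 outside
    reg <- findInterval(t, b, rightmost.closed = FALSE)
    inside <- reg >= 1 & reg <= 6
    reg_counts <- tabulate(reg[inside], nbins = 6)
    if (any(reg_counts == 0)) {
      warn_amap("stride has an empty region at this sampling rate; skipped")
      next
    }
    for (ci in seq_along(chans)) {
      on <- mask$mask[, ci] & inside
      on_counts <- tabulate(reg[on], nbins = 6)
      tim_acc[ci, ] <- tim_acc[ci, ] + 100 * on_counts / reg_counts
      amp_on <- vapply(1:6, function(r)
        sum(env$envelopes[on & reg == r, ci]), numeric(1))
      tot <- sum(amp_on)
      if (tot > 0) {
        amp_acc[ci, ] <- amp_acc[ci, ] + 100 * amp_on / tot
      } else {
        n_alloff <- n_alloff + 1L
      }
    }
  }
  n_used <- length(strides)
  if (n_alloff > 0)
    warn_amap(sprintf(
      "%d stride/muscle combination(s) had zero on-time; amplitude 0",
      n_alloff), "amap_all_off")
  structure(list(timing = tim_acc / n_used, amplitude = amp_acc / n_used,
                 n_strides = n_used, subject_id = env$subject_id,
                 speed_mps = speed_mps),
            class = "component_matrix")
}

#' Build a normative profile from a healthy cohort
#'
#' Per muscle, region and component, the mean and standard deviation
#' (n - 1 denominator) over the cohort's component matrices. Both legs of a
#' healthy subject may enter as separate observations. The profile is tied
#' to a walking-speed band so subjects are compared to speed-matched norms.
#'
#' @param cohort list of `component_matrix` objects (>= 2).
#' @param speed_band label: `"0.3"`, `"0.6"`, `"0.9"` (m/s) or
#'   `"self-selected"`.
#' @param min_sd variance floor. With the default 0, any cell whose cohort
#'   SD is 0 rejects the profile (a real cohort never produces one). A
#'   positive floor instead regularizes such cells, which arise in clean
#'   synthetic cohorts when a muscle is constitutively on or off in a
#'   region; z-score signs are unaffected.
#' @return A `normative_profile`: `mean` and `sd` (lists with `timing` and
#'   `amplitude` muscle x region matrices), `speed_band`, `n_observations`.
#' @export
build_normative_profile <- function(cohort, speed_band = "self-selected",
                                    min_sd = 0) {
  if (length(cohort) < 2)
    stop_data("at least 2 cohort observations are required",
              "amap_insufficient_data")
  stopifnot(all(vapply(cohort, inherits, logical(1), "component_matrix")))
  ref <- cohort[[1]]
  for (cm in cohort[-1])
    if (!identical(dimnames(cm$timing), dimnames(ref$timing)))
      stop_data("cohort matrices have mismatched muscles/regions",
                "amap_mismatch_error")
  mean_l <- sd_l <- list()
  for (comp in c("timing", "amplitude")) {
    arr <- simplify2array(lapply(cohort, `[[`, comp))
    mean_l[[comp]] <- apply(arr, c(1, 2), mean)
    sd_l[[comp]] <- apply(arr, c(1, 2), stats::sd)
    zero <- which(sd_l[[comp]] <= 0, arr.ind = TRUE)
    if (nrow(zero) && min_sd <= 0)
      stop_data(sprintf(
        "degenerate profile: zero SD for %s of %s in %s",
        comp, rownames(ref$timing)[zero[1, 1]], REGIONS[zero[1, 2]]),
        "amap_degenerate_profile")
    sd_l[[comp]] <- pmax(sd_l[[comp]], min_sd)
  }
  structure(list(mean = mean_l, sd = sd_l,
                 speed_band = as.character(speed_band),
                 n_observations = length(cohort)),
            class = "normative_profile")
}

#' Score a subject against a normative profile
#'
#' Per muscle, region and component, the score is
#' `(subject - healthy mean) / healthy SD`: negative scores mean reduced
#' timing or amplitude relative to the norm, positive scores increased.
#' Cells with `|z|` beyond the window half-width (default 2.57, the 99%
#' central normal window) are flagged as outside the normal pattern. The
#' per-muscle total is the mean of the absolute scores over the six
#' regions.
#'
#' @param subject a `component_matrix`.
#' @param norm a `normative_profile` with the same muscles and regions.
#' @param window window half-width `w`; a cell is an outlier iff `|z| > w`.
#' @return An `amap_report`: `z` (list of timing/amplitude matrices),
#'   `outlier` (logical, same shape), `totals` (muscle x component),
#'   `window_halfwidth`, plus subject metadata.
#' @export
score_subject <- function(subject, norm, window = 2.57) {
  stopifnot(inherits(subject, "component_matrix"),
            inherits(norm, "normative_profile"))
  if (!setequal(rownames(subject$timing), rownames(norm$mean$timing)))
    stop_data(sprintf(
      "muscle set mismatch between subject and profile (subject-only: %s)",
      paste(setdiff(rownames(subject$timing), rownames(norm$mean$timing)),
            collapse = ", ")), "amap_mismatch_error")
  ord <- rownames(norm$mean$timing)
  z <- list()
  for (comp in c("timing", "amplitude"))
    z[[comp]] <- (subject[[comp]][ord, , drop = FALSE] -
                    norm$mean[[comp]]) / norm$sd[[comp]]
  totals <- cbind(timing = rowMeans(abs(z$timing)),
                  amplitude = rowMeans(abs(z$amplitude)))
  new_amap_report(z = z, window_halfwidth = window, totals = totals,
                  subject_id = subject$subject_id,
                  n_strides = subject$n_strides,
                  speed_band = norm$speed_band)
}

new_amap_report <- function(z, window_halfwidth, totals, subject_id,
                            n_strides = NA_integer_, speed_band = NA) {
  outlier <- lapply(z, function(m) abs(m) > window_halfwidth)
  structure(list(z = z, outlier = outlier, totals = totals,
                 window_halfwidth = window_halfwidth,
                 subject_id = subject_id, n_strides = n_strides,
                 speed_band = speed_band),
            class = "amap_report")
}

#' Half-width of the central normal window for a given coverage
#'
#' `qnorm((1 + coverage) / 2)`: e.g. 99% coverage gives 2.5758 (printed in
#' normal tables as 2.576 and conventionally quoted as 2.57), 96% gives
#' 2.05.
#'
#' @param coverage central coverage probability in (0, 1).
#' @return The half-width of the symmetric standard-normal window.
#' @export
normal_window_halfwidth <- function(coverage = 0.99) {
  if (coverage <= 0 || coverage >= 1)
    stop_config("coverage must be in (0, 1)")
  stats::qnorm((1 + coverage) / 2)
}

#' Select the speed-matched normative band
#'
#' Subjects are stratified by self-selected walking speed following the
#' Perry functional-ambulation classes: household ambulators (< 0.4 m/s)
#' are compared to the 0.3 m/s norm, limited community ambulators
#' (0.4-0.8 m/s) to the 0.6 m/s norm, and community ambulators (> 0.8 m/s)
#' to the 0.9 m/s norm.
#'
#' @param self_selected_speed walking speed in m/s (> 0).
#' @return The band label: `"0.3"`, `"0.6"` or `"0.9"`.
#' @export
select_speed_band <- function(self_selected_speed) {
  if (!is.numeric(self_selected_speed) || length(self_selected_speed) != 1 ||
      !is.finite(self_selected_speed) || self_selected_speed <= 0)
    stop_config("self-selected speed must be a single positive number")
  if (self_selected_speed < 0.4) "0.3"
  else if (self_selected_speed <= 0.8) "0.6"
  else "0.9"
}

#' Fraction of scores outside the normal window in a cohort
#'
#' With a `muscle` given, the per-muscle summary: the percentage of
#' subjects for whom ANY of that muscle's six region scores (for the chosen
#' component) falls outside the window. Without a muscle, the cell-level
#' summary: the percentage of all muscle x region cells outside the window,
#' pooled over subjects.
#'
#' @param reports list of `amap_report` objects.
#' @param component `"timing"` or `"amplitude"`.
#' @param muscle optional muscle label for the per-muscle summary.
#' @return The fraction, in percent.
#' @export
cohort_outlier_fraction <- function(reports, component = c("timing",
                                                           "amplitude"),
                                    muscle = NULL) {
  component <- match.arg(component)
  if (length(reports) < 1)
    stop_data("at least one report is required", "amap_insufficient_data")
  stopifnot(all(vapply(reports, inherits, logical(1), "amap_report")))
  if (!is.null(muscle)) {
    bad <- vapply(reports, function(r) {
      if (!muscle %in% rownames(r$outlier[[component]]))
        stop_data(sprintf("unknown muscle '%s'", muscle),
                  "amap_mismatch_error")
      any(r$outlier[[component]][muscle, ])
    }, logical(1))
    return(100 * mean(bad))
  }
  cells <- unlist(lapply(reports, function(r) r$outlier[[component]]))
  100 * mean(cells)
}

#' Correlate per-muscle total scores with a covariate
#'
#' Pearson correlation between one muscle's total score (mean absolute
#' z over the six regions) across subjects and a per-subject covariate such
#' as paretic propulsion (%) or self-selected speed (m/s). The two-sided p
#' comes from the t-distribution with n - 2 degrees of freedom.
#'
#' @param reports list of `amap_report` objects (>= 3).
#' @param covariate numeric vector aligned to `reports`.
#' @param muscle muscle label.
#' @param component `"timing"` or `"amplitude"`.
#' @return A list: `r`, `p`, `n`.
#' @export
correlate_totals <- function(reports, covariate, muscle,
                             component = c("timing", "amplitude")) {
  component <- match.arg(component)
  if (length(reports) < 3)
    stop_data("at least 3 subjects are required", "amap_insufficient_data")
  if (length(covariate) != length(reports))
    stop_data("covariate must align with reports", "amap_mismatch_error")
  totals <- vapply(reports, function(r) {
    if (!muscle %in% rownames(r$totals))
      stop_data(sprintf("unknown muscle '%s'", muscle),
                "amap_mismatch_error")
    r$totals[muscle, component]
  }, numeric(1))
  n <- length(totals)
  if (stats::sd(totals) == 0 || stats::sd(covariate) == 0)
    stop_data("zero variance: correlation undefined",
              "amap_undefined_correlation")
  r <- sum((totals - mean(totals)) * (covariate - mean(covariate))) /
    ((n - 1) * stats::sd(totals) * stats::sd(covariate))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' @export
print.component_matrix <- function(x, ...) {
  cat(sprintf("<component_matrix> %s: %d muscles, %d strides, speed %s\n",
              x$subject_id, nrow(x$timing), x$n_strides,
              ifelse(is.na(x$speed_mps), "?", format(x$speed_mps))))
  cat("timing (%):\n"); print(round(x$timing, 1))
  cat("amplitude (%):\n"); print(round(x$amplitude, 1))
  invisible(x)
}

#' @export
print.normative_profile <- function(x, ...) {
  cat(sprintf(
    "<normative_profile> band %s m/s: %d muscles x 6 regions, n = %d\n",
    x$speed_band, nrow(x$mean$timing), x$n_observations))
  invisible(x)
}

#' @export
print.amap_report <- function(x, ...) {
  cat(sprintf("<amap_report> %s (window +/-%.2f, band %s)\n", x$subject_id,
              x$window_halfwidth, x$speed_band))
  cat("totals (mean |z| over regions):\n")
  print(round(x$totals, 2))
  n_out <- sum(x$outlier$timing) + sum(x$outlier$amplitude)
  cat(sprintf("cells outside window: %d of %d\n", n_out,
              2 * length(x$z$timing)))
  invisible(x)
}

#' Write a normative profile to JSON
#'
#' Schema: `{band, muscles, regions, n, <component>_mean, <component>_sd}`
#' with row-major muscle x region matrices for both components.
#'
#' @param norm a `normative_profile`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_normative_profile <- function(norm, path) {
  stopifnot(inherits(norm, "normative_profile"))
  obj <- list(band = norm$speed_band,
              muscles = rownames(norm$mean$timing),
              regions = colnames(norm$mean$timing),
              n = norm$n_observations)
  as_strings <- function(m) {
    s <- matrix(sprintf("%.17g", m), nrow = nrow(m))
    unname(s)
  }
  for (comp in c("timing", "amplitude")) {
    obj[[paste0(comp, "_mean")]] <- as_strings(norm$mean[[comp]])
    obj[[paste0(comp, "_sd")]] <- as_strings(norm$sd[[comp]])
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a normative profile written by [write_normative_profile()]
#'
#' @param path JSON path.
#' @return A `normative_profile`.
#' @export
read_normative_profile <- function(path) {
  if (!file.exists(path))
    stop_data(sprintf("file not found: %s", path), "amap_io_error")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dn <- list(obj$muscles, obj$regions)
  unpack <- function(x) {
    if (is.list(x)) x <- do.call(rbind, x)
    matrix(as.numeric(x), nrow = length(obj$muscles), dimnames = dn)
  }
  mean_l <- list(timing = unpack(obj$timing_mean),
                 amplitude = unpack(obj$amplitude_mean))
  sd_l <- list(timing = unpack(obj$timing_sd),
               amplitude = unpack(obj$amplitude_sd))
  structure(list(mean = mean_l, sd = sd_l, speed_band = obj$band,
                 n_observations = obj$n),
            class = "normative_profile")
}
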