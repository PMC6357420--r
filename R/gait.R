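# Gait events from vertical GRF, six-region stride segmentation, and
# paretic propulsion from anterior GRF.
#
# The six regions per stride of the analyzed (ipsilateral) leg:
#   DS1: ipsi heel strike -> contra toe off        (first double support)
#   SS1/SS2: single support, split at its temporal midpoint
#   DS2: contra heel strike -> ipsi toe off        (second double support)
#   SW1/SW2: swing, split at its temporal midpoint
# Regions are half-open [start, end); they tile the stride exactly.

REGIONS <- c("DS1", "SS1", "SS2", "DS2", "SW1", "SW2")

#' Detect heel strikes and toe offs from vertical GRF
#'
#' A foot is in contact while its belt's vertical force exceeds
#' `threshold_N`; contact and gap episodes shorter than `debounce_s` are
#' removed (shorter spikes/dropouts are treated as noise). Heel strike is
#' the upward threshold crossing starting a contact, toe off the downward
#' crossing ending it; crossing times are linearly interpolated between
#' samples. Partial contacts at the trace edges are dropped, so each leg's
#' events alternate HS, TO, HS, ... starting with a heel strike.
#'
#' @param grf a [grf_recording].
#' @param threshold_N contact threshold in newtons (default 20, a common
#'   force-plate convention).
#' @param debounce_s minimum episode duration in seconds (default 0.05).
#' @return A `gait_events` object: per-leg lists with `heel_strikes` and
#'   `toe_offs` (seconds).
#' @export
detect_events <- function(grf, threshold_N = 20, debounce_s = 0.05) {
  stopifnot(inherits(grf, "grf_recording"))
  if (threshold_N <= 0) stop_config("threshold_N must be positive")
  dt <- 1 / grf$rate_hz
  min_run <- max(1L, as.integer(round(debounce_s * grf$rate_hz)))
  legs <- grf$belt_map
  out <- lapply(legs, function(leg) {
    v <- grf$vertical[, leg]
    contact <- v > threshold_N
    if (!any(contact) || all(contact))
      stop_data(sprintf(
        "no gait detected on leg '%s' (threshold %g N never/always crossed)",
        leg, threshold_N), "amap_no_gait")
    contact <- debounce_runs(contact, min_run)
    if (!any(contact) || all(contact))
      stop_data(sprintf("no gait detected on leg '%s' after debounce", leg),
                "amap_no_gait")
    r <- rle(contact)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    cs <- starts[r$values]; ce <- ends[r$values]
    # drop partial contacts touching the trace edges
    keep <- cs > 1L & ce < length(v)
    cs <- cs[keep]; ce <- ce[keep]
    if (!length(cs))
      stop_data(sprintf("no complete foot contact on leg '%s'", leg),
                "amap_no_gait")
    hs <- vapply(cs, function(i)
      cross_time(v[i - 1L], v[i], threshold_N, (i - 2L) * dt, dt), numeric(1))
    to <- vapply(ce, function(i)
      cross_time(v[i], v[i + 1L], threshold_N, (i - 1L) * dt, dt), numeric(1))
    ev <- sort(c(hs, to))
    if (!all(diff(ev) > 0) || any(to <= hs))
      stop_data(sprintf("event alternation violated on leg '%s'", leg),
                "amap_event_sequence")
    list(heel_strikes = hs, toe_offs = to)
  })
  names(out) <- legs
  structure(out, class = "gait_events")
}

# Remove runs shorter than min_run: first short contact runs, then short
# gap runs (order matters: spikes removed before dropout gaps are bridged).
debounce_runs <- function(contact, min_run) {
  for (target in c(TRUE, FALSE)) {
    r <- rle(contact)
    short <- r$values == target & r$lengths < min_run
    # never flip edge runs: edge partials are handled by the caller
    short[c(1L, length(r$values))] <- FALSE
    if (any(short)) {
      r$values[short] <- !target
      contact <- inverse.rle(r)
    }
  }
  contact
}

# Linear interpolation of the threshold crossing between adjacent samples
# at times t0 and t0 + dt.
cross_time <- function(v0, v1, thr, t0, dt) {
  if (v1 == v0) return(t0 + dt / 2)
  frac <- (thr - v0) / (v1 - v0)
  t0 + dt * min(max(frac, 0), 1)
}

#' Partition strides of one leg into the six gait regions
#'
#' For each pair of consecutive ipsilateral heel strikes, locates the
#' contralateral toe off, contralateral heel strike and ipsilateral toe off
#' inside the stride and builds the seven region boundaries. Single support
#' and swing are split at their temporal midpoints. Strides whose
#' contralateral events are missing or out of order are skipped with a
#' warning.
#'
#' @param events a `gait_events` object covering both legs.
#' @param leg the ipsilateral leg id (must appear in `events`).
#' @return A list of `gait_segmentation` objects, one per complete stride,
#'   each with `stride_start`, `boundaries` (7 strictly increasing times)
#'   and `region_durations` (named, 6 positive durations summing to the
#'   stride time).
#' @export
segment_strides <- function(events, leg) {
  stopifnot(inherits(events, "gait_events"))
  if (!leg %in% names(events))
    stop_data(sprintf("leg '%s' not present in events", leg),
              "amap_mismatch_error")
  contra <- setdiff(names(events), leg)
  if (length(contra) != 1L)
    stop_data("events must cover exactly two legs", "amap_schema_error")
  ips <- events[[leg]]; con <- events[[contra]]
  if (length(ips$heel_strikes) < 2)
    stop_data("fewer than one complete stride", "amap_insufficient_data")
  segs <- list()
  skipped <- 0L
  for (i in seq_len(length(ips$heel_strikes) - 1L)) {
    t0 <- ips$heel_strikes[i]; t1 <- ips$heel_strikes[i + 1L]
    cto <- con$toe_offs[con$toe_offs > t0 & con$toe_offs < t1]
    chs <- con$heel_strikes[con$heel_strikes > t0 & con$heel_strikes < t1]
    ito <- ips$toe_offs[ips$toe_offs > t0 & ips$toe_offs < t1]
    if (length(cto) < 1 || length(chs) < 1 || length(ito) != 1) {
      skipped <- skipped + 1L; next
    }
    cto <- cto[1]; chs <- chs[1]
    b <- c(t0, cto, (cto + chs) / 2, chs, ito, (ito + t1) / 2, t1)
    if (any(diff(b) <= 0)) { skipped <- skipped + 1L; next }
    segs[[length(segs) + 1L]] <- new_gait_segmentation(b)
  }
  if (skipped > 0)
    warn_amap(sprintf("skipped %d stride(s) with missing/out-of-order %s",
                      skipped, "contralateral events"))
  if (!length(segs))
    stop_data("no complete stride could be segmented",
              "amap_insufficient_data")
  segs
}

new_gait_segmentation <- function(boundaries) {
  durs <- diff(boundaries)
  names(durs) <- REGIONS
  structure(list(stride_start = boundaries[1], boundaries = boundaries,
                 region_durations = durs),
            class = "gait_segmentation")
}

#' Paretic propulsion from anterior GRF
#'
#' Per leg, the propulsive impulse is the trapezoidal integral of the
#' positive part of the anterior GRF; paretic propulsion is the paretic
#' share of the bilateral total, in percent. The analysis window should
#' span complete strides.
#'
#' @param grf a [grf_recording].
#' @param paretic_leg leg id of the paretic (or reference) leg.
#' @param t_range optional `c(start, end)` seconds restricting the window.
#' @return A `propulsion_result`: `paretic_impulse`, `nonparetic_impulse`
#'   (N s) and `pp_percent`.
#' @export
paretic_propulsion <- function(grf, paretic_leg, t_range = NULL) {
  stopifnot(inherits(grf, "grf_recording"))
  if (!paretic_leg %in% grf$belt_map)
    stop_data(sprintf("leg '%s' not present in GRF", paretic_leg),
              "amap_mismatch_error")
  other <- setdiff(grf$belt_map, paretic_leg)[1]
  t <- sample_times(nrow(grf$anterior), grf$rate_hz)
  idx <- if (is.null(t_range)) rep(TRUE, length(t))
         else t >= t_range[1] & t <= t_range[2]
  imp <- function(leg)
    pracma::trapz(t[idx], pmax(grf$anterior[idx, leg], 0))
  p <- imp(paretic_leg); np <- imp(other)
  if (p + np <= 0)
    stop_data("both propulsive impulses are zero; propulsion undefined",
              "amap_undefined_propulsion")
  structure(list(paretic_impulse = p, nonparetic_impulse = np,
                 pp_percent = 100 * p / (p + np)),
            class = "propulsion_result")
}

#' @export
print.gait_events <- function(x, ...) {
  for (leg in names(x))
    cat(sprintf("<gait_events> %s: %d HS, %d TO\n", leg,
                length(x[[leg]]$heel_strikes), length(x[[leg]]$toe_offs)))
  invisible(x)
}

#' @export
print.gait_segmentation <- function(x, ...) {
  cat(sprintf("<gait_segmentation> stride @ %.3f s, %.3f s long\n",
              x$stride_start, sum(x$region_durations)))
  print(round(x$region_durations, 4))
  invisible(x)
}
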