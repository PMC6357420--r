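# Muscle on/off dichotomization of the linear envelope by k-means with
# k = 5 clusters: every sample assigned to the cluster with the lowest mean
# amplitude is "off", all others "on". Clustering the whole trial per
# muscle lets the lowest cluster absorb an elevated baseline, so bursts are
# still separated from raised resting activity.

#' Exact one-dimensional k-means
#'
#' Globally optimal 1-D k-means: in sorted order the optimal clusters are
#' contiguous, so the partition is found exactly by dynamic programming
#' (divide-and-conquer on the argmin, weighted over unique values). The
#' result is deterministic -- no random initialization -- and serves as the
#' oracle for the Lloyd fallback. Ties between equal-cost splits keep the
#' lowest split index.
#'
#' @param values numeric vector (at least `k` distinct values).
#' @param k number of clusters.
#' @return A list: `assignment` (cluster index 1..k per input value, in
#'   increasing order of cluster mean), `centers` (cluster means,
#'   increasing), `sizes` (cluster counts), `sse` (total within-cluster
#'   sum of squares), `boundaries` (k-1 midpoints between adjacent cluster
#'   edges; thresholding at `boundaries[1]` reproduces the off/on split).
#' @export
exact_1d_kmeans <- function(values, k) {
  if (anyNA(values) || !is.numeric(values))
    stop_data("values must be numeric without NAs")
  ux <- sort(unique(values))
  if (length(ux) < k)
    stop_data(sprintf(
      "need at least %d distinct values, got %d (degenerate channel)",
      k, length(ux)), "amap_degenerate_channel")
  cnt <- tabulate(match(values, ux), nbins = length(ux))
  fit <- .kmeans1d_dp(ux, as.numeric(cnt), as.integer(k))
  idx <- findInterval(values, ux)
  assignment <- fit$assignment[idx]
  # midpoint between the largest value of cluster q and smallest of q+1
  upper <- ux[cumsum(rle(fit$assignment)$lengths)]
  lower <- ux[c(1L, head(cumsum(rle(fit$assignment)$lengths), -1L) + 1L)]
  boundaries <- (upper[-k] + lower[-1]) / 2
  list(assignment = assignment, centers = fit$centers,
       sizes = tabulate(assignment, nbins = k), sse = fit$sse,
       boundaries = boundaries)
}

# Deterministic Lloyd iteration initialized at evenly spaced quantiles;
# cross-check for the exact solver, never the default path.
lloyd_1d_kmeans <- function(values, k, max_iter = 200) {
  ux <- sort(unique(values))
  if (length(ux) < k)
    stop_data("fewer distinct values than clusters",
              "amap_degenerate_channel")
  centers <- as.numeric(stats::quantile(values,
                                        probs = (seq_len(k) - 0.5) / k))
  centers <- sort(unique(centers))
  while (length(centers) < k)  # collapse-proof re-seeding from unique values
    centers <- sort(unique(c(centers, ux[which.max(
      vapply(ux, function(u) min(abs(u - centers)), numeric(1)))])))
  for (it in seq_len(max_iter)) {
    cuts <- (head(centers, -1) + tail(centers, -1)) / 2
    assignment <- findInterval(values, cuts) + 1L
    new_centers <- vapply(seq_len(k), function(q) {
      v <- values[assignment == q]
      if (length(v)) mean(v) else centers[q]
    }, numeric(1))
    if (max(abs(new_centers - centers)) < 1e-12) break
    centers <- sort(new_centers)
  }
  sse <- sum((values - centers[assignment])^2)
  list(assignment = assignment, centers = centers, sse = sse)
}

#' Dichotomize envelopes into muscle on/off by k-means
#'
#' Per channel, all trial samples are clustered into `k` groups by exact
#' 1-D k-means; samples in the cluster with the lowest mean amplitude are
#' "off", all others "on". With `k = 5` the lowest cluster tracks the
#' baseline even when resting activity is elevated, so bursts -- including
#' short or spike-like bursts -- are classified "on".
#'
#' @param env an `envelope_recording`.
#' @param k number of clusters (default 5).
#' @param method `"exact"` (deterministic dynamic programming, default) or
#'   `"lloyd"` (deterministic quantile-initialized Lloyd iteration, for
#'   cross-checking).
#' @return An `onoff_mask`: `mask` (logical samples x channels, TRUE =
#'   on), `cluster_means` (k x channels, increasing per column),
#'   `off_cluster_index` (always 1: clusters are reported in increasing
#'   mean order, ties broken toward the lowest index),
#'   `off_boundary` (per-channel amplitude cut between off and the next
#'   cluster), and `sse` per channel.
#' @export
kmeans_onoff <- function(env, k = 5, method = c("exact", "lloyd")) {
  stopifnot(inherits(env, "envelope_recording"))
  method <- match.arg(method)
  if (k < 2) stop_config("k must be at least 2")
  chans <- env$channel_names
  n <- nrow(env$envelopes)
  mask <- matrix(FALSE, n, length(chans), dimnames = list(NULL, chans))
  cm <- matrix(NA_real_, k, length(chans), dimnames = list(NULL, chans))
  bound <- sse <- setNames(numeric(length(chans)), chans)
  for (ch in chans) {
    v <- env$envelopes[, ch]
    if (length(unique(v)) < k)
      stop_data(sprintf(
        "channel '%s' has fewer than %d distinct values", ch, k),
        "amap_degenerate_channel")
    fit <- if (method == "exact") exact_1d_kmeans(v, k)
           else lloyd_1d_kmeans(v, k)
    mask[, ch] <- fit$assignment != 1L
    cm[, ch] <- fit$centers
    bound[ch] <- if (!is.null(fit$boundaries)) fit$boundaries[1]
                 else mean(fit$centers[1:2])
    sse[ch] <- fit$sse
  }
  structure(list(mask = mask, cluster_means = cm, off_cluster_index = 1L,
                 off_boundary = bound, sse = sse, k = k, method = method),
            class = "onoff_mask")
}

#' @export
print.onoff_mask <- function(x, ...) {
  cat(sprintf("<onoff_mask> k = %d (%s): %d channels x %d samples\n",
              x$k, x$method, ncol(x$mask), nrow(x$mask)))
  cat(sprintf("  on fraction: %s\n",
              paste(sprintf("%s %.2f", colnames(x$mask), colMeans(x$mask)),
                    collapse = ", ")))
  invisible(x)
}
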