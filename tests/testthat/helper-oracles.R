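# Independent oracles, implemented without touching the package's own
# computation paths.

# Exhaustive 1-D k-means by O(k n^2) dynamic programming over sorted
# values: every contiguous partition boundary of every subproblem is
# examined, so the minimum equals a literal search over all contiguous
# k-partitions.
naive_kmeans_sse <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  cw <- c(0, cumsum(x))
  cw2 <- c(0, cumsum(x^2))
  cost <- function(i, j) {
    # cluster over x[i..j], 1-based inclusive
    s <- cw[j + 1] - cw[i]
    q <- cw2[j + 1] - cw2[i]
    max(q - s^2 / (j - i + 1), 0)
  }
  D <- vapply(seq_len(n), function(j) cost(1, j), numeric(1))
  for (q in 2:k) {
    Dnew <- rep(Inf, n)
    for (j in q:n)
      Dnew[j] <- min(vapply(q:j, function(i) D[i - 1] + cost(i, j),
                            numeric(1)))
    D <- Dnew
  }
  D[n]
}

# Literal enumeration of all contiguous k-partitions (tiny n only).
enumerate_kmeans_sse <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  sse_of <- function(v) sum((v - mean(v))^2)
  best <- Inf
  for (cut in asplit(utils::combn(n - 1, k - 1), 2)) {
    starts <- c(1, cut + 1)
    ends <- c(cut, n)
    sse <- sum(mapply(function(a, b) sse_of(x[a:b]), starts, ends))
    best <- min(best, sse)
  }
  best
}

# Moving-RMS envelope oracle for the filter chain.
moving_rms <- function(x, width) {
  n <- length(x)
  csum <- c(0, cumsum(x^2))
  half <- floor(width / 2)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  sqrt((csum[hi + 1] - csum[lo]) / (hi - lo + 1))
}

# gait_events constructor for hand-built event times.
make_events <- function(ipsi_hs, ipsi_to, contra_hs, contra_to,
                        ipsi = "left", contra = "right") {
  ev <- list()
  ev[[ipsi]] <- list(heel_strikes = ipsi_hs, toe_offs = ipsi_to)
  ev[[contra]] <- list(heel_strikes = contra_hs, toe_offs = contra_to)
  structure(ev, class = "gait_events")
}

make_segmentation <- function(boundaries)
  amapgait:::new_gait_segmentation(boundaries)

# onoff_mask wrapper for hand-built masks.
make_mask <- function(mask)
  structure(list(mask = mask, cluster_means = NULL, off_cluster_index = 1L,
                 k = 5L, method = "manual"),
            class = "onoff_mask")

# component_matrix from bare timing/amplitude matrices.
make_components <- function(timing, amplitude, subject_id = "x",
                            n_strides = 1L, speed_mps = NA_real_)
  structure(list(timing = timing, amplitude = amplitude,
                 n_strides = n_strides, subject_id = subject_id,
                 speed_mps = speed_mps),
            class = "component_matrix")
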