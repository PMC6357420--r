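regions6 <- c("DS1", "SS1", "SS2", "DS2", "SW1", "SW2")

# one 1 s stride sampled at 1 kHz with textbook boundaries
stride_b <- c(0, .12, .31, .5, .62, .81, 1)

test_that("components follow their definitions on constructed strides", {
  r <- 1000; n <- 1000
  t <- (seq_len(n) - 1) / r
  strides <- list(make_segmentation(stride_b))
  # muscle on for exactly the first half of DS1, constant envelope
  env <- envelope_recording(cbind(SO = rep(1, n)), r, "SO")
  mask <- make_mask(cbind(SO = t < 0.06))
  comp <- compute_components(env, mask, strides)
  expect_equal(unname(comp$timing["SO", ]), c(50, 0, 0, 0, 0, 0))
  expect_equal(unname(comp$amplitude["SO", ]), c(100, 0, 0, 0, 0, 0))
  # always-on muscle with equal-duration regions: timing 100 everywhere,
  # amplitude 100/6 each (regions aligned to whole samples)
  n2 <- 1200
  env2 <- envelope_recording(cbind(SO = rep(1, n2)), r, "SO")
  eq_b <- seq(0, 1.2, length.out = 7)
  comp2 <- compute_components(env2, make_mask(cbind(SO = rep(TRUE, n2))),
                              list(make_segmentation(eq_b)))
  expect_equal(unname(comp2$timing["SO", ]), rep(100, 6))
  expect_equal(unname(comp2$amplitude["SO", ]), rep(100 / 6, 6),
               tolerance = 1e-9)
  # envelope mass split 70/30 between DS2 and SW1
  e <- numeric(n)
  e[t >= 0.5 & t < 0.62] <- 70 / sum(t >= 0.5 & t < 0.62)
  e[t >= 0.62 & t < 0.81] <- 30 / sum(t >= 0.62 & t < 0.81)
  comp3 <- compute_components(envelope_recording(cbind(SO = e), r, "SO"),
                              make_mask(cbind(SO = e > 0)), strides)
  expect_equal(unname(comp3$amplitude["SO", c("DS2", "SW1")]), c(70, 30),
               tolerance = 1)
})

test_that("a stride with zero on-time warns and contributes amplitude 0", {
  r <- 1000; n <- 1000
  env <- envelope_recording(cbind(SO = rep(1, n)), r, "SO")
  mask <- make_mask(cbind(SO = rep(FALSE, n)))
  expect_warning(comp <- compute_components(env, mask,
                                            list(make_segmentation(
                                              stride_b))),
                 class = "amap_all_off")
  expect_equal(unname(comp$amplitude["SO", ]), rep(0, 6))
})

test_that("amplitude conservation holds for every simulated subject", {
  for (res in list(healthy_analysis(),
                   suppressWarnings(analyze_leg(hemiparetic_sim(),
                                                "right")))) {
    comp <- res$components
    on_any <- rowSums(comp$timing) > 0
    expect_true(all(abs(rowSums(comp$amplitude)[on_any] - 100) < 1e-6))
    expect_true(all(comp$amplitude >= 0))
    expect_true(all(comp$timing >= 0 & comp$timing <= 100))
  }
})

test_that("shifting the whole trial in time leaves components unchanged", {
  res <- healthy_analysis()
  comp0 <- res$components
  shift_n <- 100                      # 0.2 s at 500 Hz
  dt <- 1 / res$env$rate_hz
  env2 <- envelope_recording(
    rbind(matrix(res$env$envelopes[1, ], shift_n,
                 ncol(res$env$envelopes), byrow = TRUE),
          res$env$envelopes),
    res$env$rate_hz, res$env$channel_names)
  mask2 <- make_mask(rbind(matrix(FALSE, shift_n, ncol(res$mask$mask),
                                  dimnames = list(NULL,
                                                  colnames(res$mask$mask))),
                           res$mask$mask))
  strides2 <- lapply(res$strides, function(s)
    make_segmentation(s$boundaries + shift_n * dt))
  comp2 <- suppressWarnings(compute_components(env2, mask2, strides2))
  expect_equal(comp2$timing, comp0$timing, tolerance = 1e-10)
  expect_equal(comp2$amplitude, comp0$amplitude, tolerance = 1e-10)
})

make_cell_matrix <- function(vals, muscles = c("SO", "MG")) {
  matrix(vals, length(muscles), 6, dimnames = list(muscles, regions6))
}

test_that("normative profiles take cell-wise mean and n-1 SD", {
  a <- make_components(make_cell_matrix(40), make_cell_matrix(40))
  b <- make_components(make_cell_matrix(60), make_cell_matrix(60))
  norm <- build_normative_profile(list(a, b), "0.6")
  expect_equal(unname(norm$mean$timing[1, 1]), 50)
  expect_equal(unname(norm$sd$timing[1, 1]), sqrt(200), tolerance = 1e-6)
  expect_equal(norm$n_observations, 2)
  # identical cohort -> degenerate
  expect_error(build_normative_profile(list(a, a)),
               class = "amap_degenerate_profile")
  # ... unless a variance floor is requested
  floored <- build_normative_profile(list(a, a), min_sd = 0.5)
  expect_true(all(floored$sd$timing >= 0.5))
})

test_that("cell means are recovered from a Gaussian cohort", {
  set.seed(31)
  muscles <- paste0("M", 1:8)
  mu <- matrix(runif(48, 20, 80), 8, 6, dimnames = list(muscles, regions6))
  sg <- matrix(runif(48, 2, 8), 8, 6, dimnames = list(muscles, regions6))
  cohort <- lapply(1:40, function(i)
    make_components(mu + matrix(rnorm(48), 8, 6) * sg,
                    mu + matrix(rnorm(48), 8, 6) * sg,
                    subject_id = paste0("h", i)))
  norm <- build_normative_profile(cohort, "0.3")
  ok <- abs(norm$mean$timing - mu) <= 3 * sg / sqrt(40)
  expect_gte(mean(ok), 0.95)
})

test_that("z-scores, outlier flags and totals follow their definitions", {
  set.seed(1)
  mu <- make_cell_matrix(50); sg <- make_cell_matrix(5)
  cohort <- lapply(1:10, function(i)
    make_components(mu + matrix(rnorm(12), 2, 6) * sg,
                    mu + matrix(rnorm(12), 2, 6) * sg))
  norm <- build_normative_profile(cohort)
  # subject at the mean -> z = 0, no outlier
  s0 <- make_components(norm$mean$timing, norm$mean$amplitude)
  r0 <- score_subject(s0, norm)
  expect_equal(unname(r0$z$timing), matrix(0, 2, 6), ignore_attr = TRUE)
  expect_false(any(r0$outlier$timing))
  expect_equal(unname(r0$totals[, "timing"]), c(0, 0))
  # mean + 2 SD -> z = 2, inside the 2.57 window
  s2 <- make_components(norm$mean$timing + 2 * norm$sd$timing,
                        norm$mean$amplitude)
  r2 <- score_subject(s2, norm)
  expect_equal(unname(r2$z$timing), matrix(2, 2, 6), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_false(any(r2$outlier$timing))
  expect_true(any(score_subject(s2, norm, window = 1.9)$outlier$timing))
  # muscle mismatch
  s_bad <- make_components(
    make_cell_matrix(50, muscles = c("SO", "TA")),
    make_cell_matrix(50, muscles = c("SO", "TA")))
  expect_error(score_subject(s_bad, norm), class = "amap_mismatch_error")
})

test_that("a known score row averages to its total", {
  # six region amplitude scores for one muscle; total = mean of |z| = 1.96
  so_row <- c(2.89, 0.88, 1.24, 1.68, 1.00, 4.07)
  mu <- make_cell_matrix(0, "SO"); sg <- make_cell_matrix(1, "SO")
  norm <- structure(list(mean = list(timing = mu, amplitude = mu),
                         sd = list(timing = sg, amplitude = sg),
                         speed_band = "self-selected",
                         n_observations = 20),
                    class = "normative_profile")
  subj <- make_components(mu, make_cell_matrix(so_row, "SO"))
  rep <- score_subject(subj, norm)
  expect_equal(unname(rep$totals["SO", "amplitude"]), 1.96)
})

test_that("leave-in self-scoring is bounded by (n-1)/sqrt(n)", {
  set.seed(8)
  n <- 12
  cohort <- lapply(1:n, function(i)
    make_components(make_cell_matrix(rnorm(12, 50, 8)),
                    make_cell_matrix(rnorm(12, 30, 5))))
  norm <- build_normative_profile(cohort)
  bound <- (n - 1) / sqrt(n)
  for (cm in cohort) {
    rep <- score_subject(cm, norm)
    expect_lte(max(abs(rep$z$timing)), bound + 1e-9)
    expect_lte(max(abs(rep$z$amplitude)), bound + 1e-9)
  }
})

test_that("speed bands follow the functional-ambulation strata", {
  expect_identical(select_speed_band(0.30), "0.3")
  expect_identical(select_speed_band(0.39), "0.3")
  expect_identical(select_speed_band(0.40), "0.6")
  expect_identical(select_speed_band(0.80), "0.6")
  expect_identical(select_speed_band(0.81), "0.9")
  expect_identical(select_speed_band(0.90), "0.9")
  expect_error(select_speed_band(0), class = "amap_config_error")
  expect_error(select_speed_band(-1), class = "amap_config_error")
})

test_that("cohort outlier fractions count subjects and cells", {
  z0 <- make_cell_matrix(0)
  mk_rep <- function(z_amp)
    amapgait:::new_amap_report(list(timing = z0, amplitude = z_amp),
                               2.57,
                               cbind(timing = c(0, 0),
                                     amplitude = rowMeans(abs(z_amp))),
                               "s")
  clean <- mk_rep(z0)
  hot <- make_cell_matrix(0); hot["SO", "DS1"] <- 3
  reports <- list(mk_rep(hot), clean, clean, clean)
  expect_equal(cohort_outlier_fraction(reports, "amplitude"), 0 * 100 +
                 100 * 1 / (4 * 12))
  expect_equal(cohort_outlier_fraction(reports, "amplitude",
                                       muscle = "SO"), 25)
  expect_equal(cohort_outlier_fraction(reports, "timing"), 0)
  expect_error(cohort_outlier_fraction(reports, "timing", muscle = "XX"),
               class = "amap_mismatch_error")
})

test_that("the 2.57 window leaves under 1.02% of normal scores outside", {
  expect_lt(2 * pnorm(-2.57), 0.0102)
  expect_equal(floor(normal_window_halfwidth(0.99) * 100) / 100, 2.57)
  expect_equal(round(normal_window_halfwidth(0.96), 2), 2.05)
})

test_that("correlations reproduce Pearson r with t-distributed p", {
  mu <- make_cell_matrix(0); sg <- make_cell_matrix(1)
  norm <- structure(list(mean = list(timing = mu, amplitude = mu),
                         sd = list(timing = sg, amplitude = sg),
                         speed_band = "self-selected", n_observations = 2),
                    class = "normative_profile")
  mk <- function(level)
    score_subject(make_components(make_cell_matrix(level), mu), norm)
  # totals exactly linear (decreasing) in the covariate -> r = -1
  reports <- lapply(c(3, 2, 1, 0.5), mk)
  res <- correlate_totals(reports, c(1, 2, 3, 3.5), "SO", "timing")
  expect_equal(res$r, -1, tolerance = 1e-12)
  expect_lt(res$p, 1e-8)
  # matches the standard implementation on noisy data
  set.seed(4)
  lv <- abs(rnorm(8, 2, 1)); cv <- lv + rnorm(8, 0, 0.5)
  res2 <- correlate_totals(lapply(lv, mk), cv, "SO", "timing")
  ct <- cor.test(vapply(lapply(lv, mk), function(r)
    r$totals["SO", "timing"], numeric(1)), cv)
  expect_equal(res2$r, unname(ct$estimate), tolerance = 1e-9)
  expect_equal(res2$p, ct$p.value, tolerance = 1e-9)
  # constant covariate -> undefined
  expect_error(correlate_totals(reports, rep(1, 4), "SO", "timing"),
               class = "amap_undefined_correlation")
})

test_that("n = 34 cohorts detect a true r = -0.4 most of the time", {
  # Monte-Carlo power oracle on the same r/p formulas via plain arithmetic
  set.seed(99)
  n <- 34; reps <- 1000
  hits <- 0; near <- 0
  for (i in seq_len(reps)) {
    x <- rnorm(n)
    y <- -0.4 * x + sqrt(1 - 0.16) * rnorm(n)
    r <- cor(x, y)
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t), n - 2)
    hits <- hits + (p < 0.05)
    near <- near + (abs(r - (-0.4)) <= 0.3)
  }
  expect_gte(hits / reps, 0.60)
  expect_gte(near / reps, 0.95)
})
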