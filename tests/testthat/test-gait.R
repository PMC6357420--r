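test_that("events are recovered from synthetic GRF within 10 ms", {
  sim <- healthy_sim()   # 20 s, 1.0 s strides
  ev <- detect_events(sim$grf)
  for (leg in c("left", "right")) {
    truth <- sim$truth$events[[leg]]
    for (type in c("heel_strikes", "toe_offs")) {
      det <- ev[[leg]][[type]]
      # every true event inside the detectable range has a match
      for (tt in truth[[type]]) {
        d <- min(abs(det - tt))
        expect_lt(d, 0.010)
      }
    }
    # alternation: HS and TO strictly interleave
    merged <- sort(c(ev[[leg]]$heel_strikes, ev[[leg]]$toe_offs))
    types <- order(c(ev[[leg]]$heel_strikes, ev[[leg]]$toe_offs))
    expect_true(all(diff(merged) > 0))
    expect_equal(length(ev[[leg]]$heel_strikes),
                 length(ev[[leg]]$toe_offs))
  }
})

test_that("standing or an unreachable threshold yields no-gait errors", {
  standing <- grf_recording(matrix(700, 500, 2), matrix(0, 500, 2), 100)
  expect_error(detect_events(standing), class = "amap_no_gait")
  sim <- healthy_sim()
  expect_error(detect_events(sim$grf, threshold_N = 5000),
               class = "amap_no_gait")
})

test_that("six-region boundaries follow the event definitions", {
  # symmetric gait: stance 60% of a 1 s stride, contra TO 0.10, contra HS
  # 0.50 -> boundaries at 0, .10, .30, .50, .60, .80, 1.00
  ev <- make_events(ipsi_hs = c(0, 1, 2), ipsi_to = c(0.6, 1.6, 2.6),
                    contra_hs = c(0.5, 1.5, 2.5),
                    contra_to = c(0.1, 1.1, 2.1))
  segs <- segment_strides(ev, "left")
  expect_length(segs, 2)
  expect_equal(segs[[1]]$boundaries, c(0, .1, .3, .5, .6, .8, 1))
  expect_equal(unname(sum(segs[[1]]$region_durations)), 1)
  # asymmetric: ipsi stance 70% -> DS2 ends 0.70, swing split at 0.85
  ev2 <- make_events(ipsi_hs = c(0, 1), ipsi_to = 0.7,
                     contra_hs = 0.5, contra_to = 0.1)
  seg2 <- segment_strides(ev2, "left")[[1]]
  expect_equal(seg2$boundaries, c(0, .1, .3, .5, .7, .85, 1))
  expect_equal(unname(seg2$region_durations[["DS2"]]), 0.2)
})

test_that("regions tile every stride exactly, however asymmetric", {
  for (sim in list(healthy_sim(), hemiparetic_sim())) {
    ev <- detect_events(sim$grf)
    for (leg in c("left", "right")) {
      segs <- suppressWarnings(segment_strides(ev, leg))
      expect_gt(length(segs), 10)
      for (s in segs) {
        expect_true(all(diff(s$boundaries) > 0))
        expect_equal(unname(sum(s$region_durations)),
                     s$boundaries[7] - s$boundaries[1], tolerance = 1e-12)
      }
    }
  }
})

test_that("strides with missing contralateral events are skipped loudly", {
  ev <- make_events(ipsi_hs = c(0, 1, 2), ipsi_to = c(0.6, 1.6),
                    contra_hs = 0.5, contra_to = 0.1)
  expect_warning(segs <- segment_strides(ev, "left"),
                 class = "amap_warning")
  expect_length(segs, 1)
  short <- make_events(ipsi_hs = 0, ipsi_to = 0.6, contra_hs = 0.5,
                       contra_to = 0.1)
  expect_error(segment_strides(short, "left"),
               class = "amap_insufficient_data")
})

test_that("paretic propulsion is the paretic share of propulsive impulse", {
  t <- seq(0, 10, by = 0.01)
  wave <- pmax(sin(2 * pi * t), 0)
  # mirror symmetry -> 50%
  g <- grf_recording(matrix(700, length(t), 2),
                     cbind(wave, wave), 100, c("paretic", "nonparetic"))
  expect_equal(paretic_propulsion(g, "paretic")$pp_percent, 50)
  # impulses 1 and 3 N s -> 25%
  g2 <- grf_recording(matrix(700, length(t), 2),
                      cbind(wave / pracma::trapz(t, wave),
                            3 * wave / pracma::trapz(t, wave)),
                      100, c("paretic", "nonparetic"))
  r2 <- paretic_propulsion(g2, "paretic")
  expect_equal(r2$paretic_impulse, 1, tolerance = 1e-6)
  expect_equal(r2$pp_percent, 25, tolerance = 1e-6)
  # scale invariance
  g3 <- grf_recording(g2$vertical, 13 * g2$anterior, 100,
                      c("paretic", "nonparetic"))
  expect_equal(paretic_propulsion(g3, "paretic")$pp_percent,
               r2$pp_percent, tolerance = 1e-9)
  # both impulses zero -> undefined
  g0 <- grf_recording(matrix(700, 100, 2), matrix(-1, 100, 2), 100)
  expect_error(paretic_propulsion(g0, "left"),
               class = "amap_undefined_propulsion")
})

test_that("simulated hemiparetic propulsion matches the analytic ratio", {
  sim <- hemiparetic_sim()
  pp <- paretic_propulsion(sim$grf, "right")
  expect_lt(pp$pp_percent, 50)
  expect_equal(pp$pp_percent, sim$truth$pp_percent,
               tolerance = 0.02 * sim$truth$pp_percent)
  # the spec case of a 0.4-scaled propulsion bump with symmetric stance
  m <- gait_model("hemiparetic",
                  stance_fraction = c(left = 0.62, right = 0.62),
                  prop_N = c(left = 150, right = 60), seed = 2)
  expect_equal(amapgait:::true_pp(m), 100 * 0.4 / 1.4, tolerance = 1e-12)
  sim2 <- simulate_trial(m, duration_s = 20, rate_hz = 500)
  pp2 <- paretic_propulsion(sim2$grf, "right")
  expect_equal(pp2$pp_percent, 100 * 0.4 / 1.4,
               tolerance = 0.02 * 100 * 0.4 / 1.4)
})
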