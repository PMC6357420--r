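# Shared simulated fixtures, built once per test run. Trial sizes are kept
# modest (envelope-band content lives below 25 Hz, so a few hundred Hz is
# ample for envelope-level work).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

healthy_sim <- function()
  fixture("healthy_sim", simulate_trial(gait_model("healthy", seed = 11),
                                        duration_s = 20, rate_hz = 500))

hemiparetic_sim <- function()
  fixture("hemi_sim", simulate_trial(gait_model("hemiparetic", seed = 12),
                                     duration_s = 20, rate_hz = 500))

# Full pipeline (events -> segmentation -> normalization -> k-means ->
# components) on a simulated trial's envelopes for one leg.
analyze_leg <- function(sim, leg) {
  ev <- detect_events(sim$grf)
  strides <- suppressWarnings(segment_strides(ev, leg))
  env <- normalize_to_step_peaks(sim$emg[[leg]], strides)
  mask <- kmeans_onoff(env)
  comp <- suppressWarnings(compute_components(env, mask, strides))
  list(events = ev, strides = strides, env = env, mask = mask,
       components = comp)
}

healthy_analysis <- function()
  fixture("healthy_analysis", analyze_leg(healthy_sim(), "left"))

# Healthy pipeline cohort (both legs) and its per-cell statistics.
healthy_cohort_components <- function() {
  fixture("healthy_cohort_components", {
    subs <- simulate_cohort(gait_model("healthy", seed = 21),
                            n_subjects = 6, seed = 21, duration_s = 16,
                            rate_hz = 400)
    unlist(lapply(subs, function(s)
      lapply(c("left", "right"), function(l) {
        res <- analyze_leg(s$sim, l)
        res$components
      })), recursive = FALSE)
  })
}
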