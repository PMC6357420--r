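# Synthetic treadmill gait: parametric GRF and EMG-envelope generator with
# analytic ground truth (events, on/off masks, region components, propulsive
# impulses), so every pipeline stage can be validated without recorded data.
#
# Waveform conventions (all phases in % of the ipsilateral gait cycle):
#  * Bursts are plateaus with raised-cosine shoulders: parameters center,
#    halfwidth (h) and ramp (r). The shape is 1 inside |d| <= h - r/2,
#    falls along a half-cosine to 0 at |d| = h + r/2, and the ground-truth
#    "on" support is |d| <= h -- the half-amplitude point, i.e. the ramp
#    midpoint. The default 3% ramp (~30 ms at a 1 s stride) mimics the
#    transition width of a 25 Hz-smoothed envelope.
#  * Vertical GRF: body weight x edge ramp (raised cosine over rise_s) x a
#    mid-stance dip, giving the classic double bump; the fast rise keeps
#    threshold crossings within a few ms of true foot contact.
#  * Anterior GRF: one sine cycle over stance, braking (negative) first,
#    propulsive second; the propulsive impulse is brake/prop-scaled
#    prop_N * stance_s / pi in closed form.

#' Parametric gait model
#'
#' Bundles the spatiotemporal, GRF and muscle-burst parameters that define
#' a synthetic walker. `preset = "healthy"` places bursts at textbook
#' phasing for the eight recorded leg muscles (TA, SO, MG, VM, RF, LH, MH,
#' GM). `preset = "hemiparetic"` makes the paretic (right) leg's
#' plantarflexors fire prematurely in first double support and fade early
#' in late single support, extends tibialis anterior activity into second
#' double support (co-activation), weakens gluteus medius in early stance,
#' and scales the paretic propulsive GRF bump to 40%.
#'
#' @param preset `"healthy"` or `"hemiparetic"`.
#' @param stride_s stride duration (s).
#' @param stance_fraction named per-leg stance fraction in (0, 1).
#' @param phase_lag contralateral heel-strike offset as fraction of stride.
#' @param noise_sd envelope noise scale. The additive noise SD at signal
#'   level s is `noise_sd * max(s, 0.2)` (constant coefficient of
#'   variation with a floor, as in rectified-and-smoothed EMG); the noisy
#'   envelope is clipped at 0, i.e. truncated Gaussian noise.
#' @param stride_gain_sd lognormal SD of per-stride burst gain jitter.
#' @param bw_N body weight (N); `rise_s` GRF edge-ramp duration (s);
#'   `dip` mid-stance dip depth; `prop_N`, `brake_N` named per-leg anterior
#'   GRF magnitudes (N); `grf_noise_sd` vertical/anterior GRF noise SD (N).
#' @param muscles optional list(left =, right =) of muscle burst sets; each
#'   muscle is `list(baseline =, bursts = list(c(center, halfwidth, amp)))`.
#' @param ramp burst shoulder width (% of cycle).
#' @param seed RNG seed used by [simulate_trial()].
#' @return A `gait_model` list.
#' @export
gait_model <- function(preset = c("healthy", "hemiparetic"),
                       stride_s = 1.0,
                       stance_fraction = NULL,
                       phase_lag = 0.5,
                       noise_sd = 0.02,
                       stride_gain_sd = 0.1,
                       bw_N = 700, rise_s = 0.03, dip = 0.25,
                       prop_N = NULL, brake_N = NULL, grf_noise_sd = 2,
                       muscles = NULL, ramp = 3, seed = 1L) {
  preset <- match.arg(preset)
  if (is.null(stance_fraction))
    stance_fraction <- if (preset == "healthy") c(left = 0.62, right = 0.62)
                       else c(left = 0.66, right = 0.58)
  if (is.null(prop_N))
    prop_N <- if (preset == "healthy") c(left = 150, right = 150)
              else c(left = 150, right = 60)
  if (is.null(brake_N)) brake_N <- c(left = 150, right = 150)
  if (any(stance_fraction <= 0) || any(stance_fraction >= 1))
    stop_config("stance_fraction must lie in (0, 1)")
  if (phase_lag <= 0 || phase_lag >= 1)
    stop_config("phase_lag must lie in (0, 1)")
  # both legs must overlap in stance (double support exists)
  if (phase_lag + stance_fraction[["right"]] <= 1 ||
      (1 - phase_lag) + stance_fraction[["left"]] <= 1)
    stop_config("parameters leave no double-support overlap")
  if (stride_s <= 0 || noise_sd < 0)
    stop_config("stride_s must be positive and noise_sd nonnegative")
  if (is.null(muscles)) {
    healthy <- healthy_muscle_set()
    muscles <- if (preset == "healthy")
      list(left = healthy, right = healthy)
    else list(left = healthy, right = hemiparetic_muscle_set())
  }
  for (leg in names(muscles))
    for (m in names(muscles[[leg]])) {
      spec <- muscles[[leg]][[m]]
      for (b in spec$bursts)
        if (b[["amp"]] < spec$baseline || spec$baseline < 0 ||
            b[["center"]] < 0 || b[["center"]] >= 100)
          stop_config(sprintf("degenerate burst parameters for %s/%s",
                              leg, m))
    }
  structure(list(preset = preset, stride_s = stride_s,
                 stance_fraction = stance_fraction, phase_lag = phase_lag,
                 noise_sd = noise_sd, stride_gain_sd = stride_gain_sd,
                 bw_N = bw_N, rise_s = rise_s, dip = dip,
                 prop_N = prop_N, brake_N = brake_N,
                 grf_noise_sd = grf_noise_sd,
                 muscles = muscles, ramp = ramp, seed = as.integer(seed),
                 paretic_leg = "right"),
            class = "gait_model")
}

burst <- function(center, halfwidth, amp)
  c(center = center, halfwidth = halfwidth, amp = amp)

# Textbook surface-EMG phasing for level walking (stance ~0-62%):
# plantarflexors through single support into push-off, TA in swing and
# loading response, quadriceps and hamstrings around heel strike, GM in
# early-to-mid stance.
healthy_muscle_set <- function() {
  list(
    TA = list(baseline = 0.05,
              bursts = list(burst(82, 17, 0.9), burst(4, 7, 0.7))),
    SO = list(baseline = 0.05, bursts = list(burst(31, 21, 1.0))),
    MG = list(baseline = 0.05, bursts = list(burst(33, 19, 0.95))),
    VM = list(baseline = 0.05, bursts = list(burst(99, 11, 0.8))),
    RF = list(baseline = 0.05,
              bursts = list(burst(2, 9, 0.75), burst(64, 5, 0.5))),
    LH = list(baseline = 0.05, bursts = list(burst(95, 12, 0.8))),
    MH = list(baseline = 0.05, bursts = list(burst(94, 13, 0.8))),
    GM = list(baseline = 0.05, bursts = list(burst(15, 15, 0.8)))
  )
}

# Paretic-side alterations: premature plantarflexor activity in DS1 plus a
# late-swing burst, early termination before late single support; TA
# co-activation extending into DS2; GM weakened in early stance with extra
# activity around DS2/late swing.
hemiparetic_muscle_set <- function() {
  set <- healthy_muscle_set()
  set$SO$bursts <- list(burst(4, 6, 0.6), burst(20, 12, 0.7),
                        burst(92, 5, 0.5))
  set$MG$bursts <- list(burst(5, 6, 0.55), burst(22, 12, 0.65),
                        burst(93, 5, 0.5))
  set$TA$bursts <- list(burst(80, 15, 0.85), burst(4, 7, 0.7),
                        burst(54, 5, 0.6))
  set$GM$bursts <- list(burst(16, 8, 0.45), burst(55, 5, 0.55),
                        burst(90, 5, 0.5))
  set
}

circ_dist <- function(phase, center)
  pmin(abs(phase - center), 100 - abs(phase - center))

# Noiseless burst-sum (above baseline) at gait phase `phase` (0-100).
burst_shape <- function(phase, bursts, ramp) {
  y <- numeric(length(phase))
  for (b in bursts) {
    d <- circ_dist(phase, b[["center"]])
    inner <- b[["halfwidth"]] - ramp / 2
    outer <- b[["halfwidth"]] + ramp / 2
    s <- ifelse(d <= inner, 1,
                ifelse(d >= outer, 0,
                       0.5 * (1 + cos(pi * (d - inner) / ramp))))
    y <- pmax(y, b[["amp"]] * s)
  }
  y
}

# Ground-truth on/off support: within the half-amplitude point of any burst.
true_mask_at <- function(phase, bursts) {
  on <- rep(FALSE, length(phase))
  for (b in bursts)
    on <- on | circ_dist(phase, b[["center"]]) <= b[["halfwidth"]]
  on
}

leg_offset <- function(model, leg)
  if (leg == "left") 0 else model$phase_lag * model$stride_s

# Vertical GRF shape at stance-normalized time u in [0,1], stance_s seconds.
vertical_shape <- function(u, stance_s, rise_s, dip) {
  tsec <- u * stance_s
  edge <- pmin(tsec, stance_s - tsec)
  r <- ifelse(edge <= 0, 0,
              ifelse(edge >= rise_s, 1,
                     0.5 * (1 - cos(pi * edge / rise_s))))
  r * (1 - dip * exp(-((u - 0.5) / 0.18)^2))
}

#' Simulate one treadmill walking trial
#'
#' Builds bilateral GRF traces and per-leg EMG envelopes from a
#' [gait_model()], together with the analytic ground truth: event times,
#' per-muscle on/off masks, per-muscle region components (computed by
#' quadrature of the noiseless waveforms over the analytic region
#' boundaries, independent of the analysis pipeline) and the closed-form
#' paretic propulsion.
#'
#' @param model a `gait_model`.
#' @param duration_s trial length (s); must hold at least 2 strides.
#' @param rate_hz sampling rate for both EMG and GRF (Hz).
#' @param legs which legs to synthesize envelopes for.
#' @param raw_emg if TRUE, additionally emit raw interference-like EMG
#'   (band-limited noise amplitude-modulated by the envelope) for
#'   exercising [filter_chain()].
#' @return A list: `emg` (named list of `envelope_recording`), `raw`
#'   (named list of [emg_recording] if requested), `grf`
#'   ([grf_recording]), and `truth` with `events`, `mask`, `components`,
#'   `pp_percent`, `impulse_per_stride`.
#' @export
simulate_trial <- function(model, duration_s = 40, rate_hz = 1000,
                           legs = c("left", "right"), raw_emg = FALSE) {
  stopifnot(inherits(model, "gait_model"))
  T <- model$stride_s
  if (duration_s < 2 * T)
    stop_config("duration must cover at least 2 strides")
  set.seed(model$seed)
  n <- as.integer(round(duration_s * rate_hz))
  t <- sample_times(n, rate_hz)

  # --- GRF ---------------------------------------------------------------
  both <- c("left", "right")
  vert <- ant <- matrix(0, n, 2, dimnames = list(NULL, both))
  events <- list()
  for (leg in both) {
    off <- leg_offset(model, leg)
    s <- model$stance_fraction[[leg]]
    phi <- ((t - off) %% T) / T          # stride-normalized phase [0,1)
    stance <- phi < s
    u <- phi / s
    v <- numeric(n)
    v[stance] <- model$bw_N *
      vertical_shape(u[stance], s * T, model$rise_s, model$dip)
    a <- numeric(n)
    mag <- ifelse(u < 0.5, model$brake_N[[leg]], model$prop_N[[leg]])
    a[stance] <- (mag * -sin(2 * pi * u))[stance]
    if (model$grf_noise_sd > 0) {
      v <- pmax(v + rnorm(n, 0, model$grf_noise_sd), 0)
      a <- a + rnorm(n, 0, model$grf_noise_sd)
    }
    vert[, leg] <- v; ant[, leg] <- a
    hs <- seq(off - T * ceiling(off / T), duration_s, by = T)
    hs <- hs[hs >= 0 & hs + s * T <= duration_s]
    events[[leg]] <- list(heel_strikes = hs, toe_offs = hs + s * T)
  }
  grf <- grf_recording(vert, ant, rate_hz, both)

  # --- EMG envelopes -----------------------------------------------------
  musc_names <- names(model$muscles[["left"]])
  emg <- list(); raw <- list(); mask_truth <- list()
  for (leg in intersect(both, legs)) {
    off <- leg_offset(model, leg)
    phase <- 100 * ((t - off) %% T) / T
    stride_idx <- floor((t - off) / T)
    env <- matrix(0, n, length(musc_names),
                  dimnames = list(NULL, musc_names))
    msk <- matrix(FALSE, n, length(musc_names),
                  dimnames = list(NULL, musc_names))
    for (m in musc_names) {
      spec <- model$muscles[[leg]][[m]]
      shape <- burst_shape(phase, spec$bursts, model$ramp)
      if (model$stride_gain_sd > 0) {
        uidx <- stride_idx - min(stride_idx) + 1L
        gains <- exp(rnorm(max(uidx), 0, model$stride_gain_sd))
        shape <- shape * gains[uidx]
      }
      sig <- spec$baseline + shape
      # heteroscedastic envelope noise: amplitude jitter of a rectified,
      # smoothed EMG scales with the signal level (roughly constant
      # coefficient of variation), floored so the baseline still jitters
      env[, m] <- pmax(sig + rnorm(n, 0, model$noise_sd * pmax(sig, 0.2)),
                       0)
      msk[, m] <- true_mask_at(phase, spec$bursts)
    }
    emg[[leg]] <- envelope_recording(env, rate_hz, musc_names, leg = leg,
                                     subject_id = sprintf("sim-seed%d",
                                                          model$seed))
    mask_truth[[leg]] <- msk
    if (raw_emg) {
      carrier <- matrix(rnorm(n * length(musc_names)), n)
      bp <- butter_or_fail(4, min(450, rate_hz / 2 * 0.9), rate_hz, "low")
      carrier <- apply(carrier, 2, function(x) filtfilt_reflect(bp, x))
      hp <- butter_or_fail(4, 20, rate_hz, "high")
      carrier <- apply(carrier, 2, function(x) filtfilt_reflect(hp, x))
      rawsig <- carrier * env
      colnames(rawsig) <- musc_names
      raw[[leg]] <- emg_recording(rawsig, rate_hz, musc_names, leg = leg,
                                  subject_id = sprintf("sim-seed%d",
                                                       model$seed))
    }
  }

  truth <- list(events = events,
                mask = mask_truth,
                components = lapply(stats::setNames(nm = intersect(both,
                                                                   legs)),
                                    function(l) true_components(model, l)),
                pp_percent = true_pp(model),
                impulse_per_stride = vapply(both, function(l)
                  model$prop_N[[l]] * model$stance_fraction[[l]] * T / pi,
                  numeric(1)))
  out <- list(emg = emg, grf = grf, truth = truth, model = model,
              duration_s = duration_s, rate_hz = rate_hz)
  if (raw_emg) out$raw <- raw
  out
}

# Closed-form paretic propulsion of the model: per-stride propulsive
# impulse is prop_N * stance_s / pi per leg.
true_pp <- function(model, paretic = model$paretic_leg) {
  other <- setdiff(c("left", "right"), paretic)
  p <- model$prop_N[[paretic]] * model$stance_fraction[[paretic]]
  np <- model$prop_N[[other]] * model$stance_fraction[[other]]
  100 * p / (p + np)
}

# Analytic six-region boundaries of one stride of `leg`, as fractions of
# the stride. Requires double-support overlap (enforced by gait_model).
true_boundaries <- function(model, leg) {
  contra <- setdiff(c("left", "right"), leg)
  lag <- (leg_offset(model, contra) - leg_offset(model, leg)) /
    model$stride_s
  chs <- lag %% 1
  s_i <- model$stance_fraction[[leg]]
  s_c <- model$stance_fraction[[contra]]
  cto <- chs + s_c - 1          # contralateral toe off inside this stride
  if (cto <= 0 || cto >= chs || chs >= s_i)
    stop_config("model events do not form a valid six-region stride")
  c(0, cto, (cto + chs) / 2, chs, s_i, (s_i + 1) / 2, 1)
}

# Ground-truth components by quadrature of the noiseless envelope and the
# analytic mask over a dense in-stride grid (independent of the pipeline).
true_components <- function(model, leg, n_grid = 20000L) {
  b <- true_boundaries(model, leg)
  u <- (seq_len(n_grid) - 0.5) / n_grid   # stride fraction, midpoints
  phase <- 100 * u
  reg <- findInterval(u, b, rightmost.closed = FALSE)
  reg[reg > 6] <- 6
  musc <- names(model$muscles[[leg]])
  timing <- amp <- matrix(0, length(musc), 6,
                          dimnames = list(musc, REGIONS))
  reg_counts <- tabulate(reg, nbins = 6)
  for (m in musc) {
    spec <- model$muscles[[leg]][[m]]
    on <- true_mask_at(phase, spec$bursts)
    env <- spec$baseline + burst_shape(phase, spec$bursts, model$ramp)
    on_counts <- tabulate(reg[on], nbins = 6)
    timing[m, ] <- 100 * on_counts / reg_counts
    a <- vapply(1:6, function(r) sum(env[on & reg == r]), numeric(1))
    if (sum(a) > 0) amp[m, ] <- 100 * a / sum(a)
  }
  list(timing = timing, amplitude = amp,
       boundaries_frac = b)
}

#' Simulate a cohort of walkers
#'
#' Draws `n_subjects` per-subject models around a base model (burst centers
#' jittered in % of cycle, burst amplitudes and baselines by lognormal
#' factors, stance fraction and stride duration perturbed), then simulates
#' one trial per subject. Reproducible: the same seed yields an identical
#' cohort.
#'
#' @param model base `gait_model`.
#' @param n_subjects number of subjects (>= 2).
#' @param between_subject_sd list of per-parameter SDs: `center` (% of
#'   cycle), `amp_log`, `baseline_log`, `stance`, `stride_log`.
#' @param seed cohort RNG seed.
#' @param duration_s,rate_hz,legs passed to [simulate_trial()].
#' @return A list of subjects, each `list(subject_id, model, sim)`.
#' @export
simulate_cohort <- function(model, n_subjects,
                            between_subject_sd = list(center = 1.5,
                                                      amp_log = 0.1,
                                                      baseline_log = 0.15,
                                                      stance = 0.015,
                                                      stride_log = 0.03),
                            seed = 1L, duration_s = 30, rate_hz = 500,
                            legs = c("left", "right")) {
  stopifnot(inherits(model, "gait_model"))
  if (n_subjects < 2)
    stop_config("a cohort needs at least 2 subjects")
  sd <- between_subject_sd
  set.seed(seed)
  # one shared within-trial noise seed: between-subject differences come
  # from the parameter jitter alone, so a zero-SD cohort is bit-identical
  trial_seed <- sample.int(.Machine$integer.max - 1L, 1)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    mi <- model
    mi$seed <- trial_seed
    set.seed(subject_seeds[i])
    mi$stride_s <- model$stride_s * exp(rnorm(1, 0, sd$stride_log))
    repeat {
      sf <- model$stance_fraction + rnorm(2, 0, sd$stance)
      ok <- all(sf > 0.5) && all(sf < 0.75) &&
        model$phase_lag + sf[["right"]] > 1 + 0.02 &&
        (1 - model$phase_lag) + sf[["left"]] > 1 + 0.02
      if (ok) break
    }
    mi$stance_fraction <- sf
    for (leg in names(mi$muscles))
      for (m in names(mi$muscles[[leg]])) {
        spec <- mi$muscles[[leg]][[m]]
        spec$baseline <- spec$baseline * exp(rnorm(1, 0, sd$baseline_log))
        spec$bursts <- lapply(spec$bursts, function(b) {
          b[["center"]] <- (b[["center"]] + rnorm(1, 0, sd$center)) %% 100
          b[["amp"]] <- max(b[["amp"]] * exp(rnorm(1, 0, sd$amp_log)),
                            spec$baseline)
          b
        })
        mi$muscles[[leg]][[m]] <- spec
      }
    sim <- simulate_trial(mi, duration_s = duration_s, rate_hz = rate_hz,
                          legs = legs)
    sid <- sprintf("sim%02d", i)
    for (l in names(sim$emg)) sim$emg[[l]]$subject_id <- sid
    subjects[[i]] <- list(subject_id = sid, model = mi, sim = sim)
  }
  subjects
}

#' Simulate a healthy cohort at the component level
#'
#' Draws timing and amplitude components cell-wise from Gaussian normative
#' cells (one mean and SD per muscle x region x component), bypassing the
#' signal level entirely. Each subject contributes one observation per
#' leg, as healthy normative cohorts do. Used to study the self-consistency
#' of normative scoring: scoring such a cohort against its own leave-in
#' profile yields standard-normal z-scores up to the leave-in shrinkage.
#'
#' @param n_subjects number of subjects.
#' @param legs_per_subject observations per subject (default 2, both legs).
#' @param muscles muscle labels.
#' @param seed RNG seed.
#' @return A list: `cohort` (list of `component_matrix`), `mu`, `sigma`
#'   (the generating cell parameters, lists of timing/amplitude matrices).
#' @export
simulate_component_cohort <- function(n_subjects = 20,
                                      legs_per_subject = 2,
                                      muscles = c("TA", "SO", "MG", "VM",
                                                  "RF", "LH", "MH", "GM"),
                                      seed = 1L) {
  set.seed(seed)
  dn <- list(muscles, REGIONS)
  nm <- length(muscles)
  cell <- function(lo, hi) matrix(stats::runif(nm * 6, lo, hi), nm, 6,
                                  dimnames = dn)
  mu <- list(timing = cell(20, 80), amplitude = cell(5, 30))
  sigma <- list(timing = cell(3, 10), amplitude = cell(1, 6))
  cohort <- list()
  for (i in seq_len(n_subjects))
    for (l in seq_len(legs_per_subject)) {
      draw <- function(comp)
        mu[[comp]] + matrix(stats::rnorm(nm * 6), nm, 6) * sigma[[comp]]
      cohort[[length(cohort) + 1L]] <-
        structure(list(timing = draw("timing"),
                       amplitude = draw("amplitude"),
                       n_strides = NA_integer_,
                       subject_id = sprintf("h%02d_leg%d", i, l),
                       speed_mps = NA_real_),
                  class = "component_matrix")
    }
  list(cohort = cohort, mu = mu, sigma = sigma)
}

#' @export
print.gait_model <- function(x, ...) {
  cat(sprintf(
    "<gait_model> %s: stride %.2f s, stance L %.2f / R %.2f, lag %.2f\n",
    x$preset, x$stride_s, x$stance_fraction[["left"]],
    x$stance_fraction[["right"]], x$phase_lag))
  invisible(x)
}
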