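# Synthetic multimodal grasp simulator.
#
# Generates labelled tactile recordings of a parallel-jaw grasp on citrus
# fruit: a 6x6 pressure-matrix stream (~20 Hz) and a piezoelectric vibration
# stream (~200 Hz), both as 10-bit ADC counts. Frost damage softens and damps
# the tissue, which the generator encodes as class offsets on the mechanical
# parameters of an explicit generative model: exponential force ramp to the
# gripper's 20 N set-point, Gaussian contact footprint on the sensor grid,
# damped-sinusoid contact transient, and Poisson-timed micro-transients
# during loading. Class-discriminative structure is deliberately confined to
# contact onset and early loading (ramp shape, footprint spread before creep
# redistribution, transient envelope, micro-event rate); during the hold the
# footprint of both classes relaxes towards a common creep spread, so the
# hold phase is only weakly informative.

# Normal-class mechanical baselines (frost offsets are added on top of these).
.sim_baselines <- list(
  stiffness_tau_s     = 0.15,  # force-ramp time constant
  footprint_spread    = 1.0,   # Gaussian footprint SD at contact, grid units
  vib_freq_hz         = 60,    # contact-transient natural frequency
  damping_ratio       = 0.05,
  micro_event_rate_hz = 2,     # Poisson rate of micro-transients during loading
  creep_spread        = 1.15,  # common footprint SD both classes creep towards
  creep_tau_s         = 0.8,
  transient_amp_counts = 140,
  bio_jitter_sd       = 0.10,  # lognormal per-fruit biological variability
  diameter_mean_mm    = 73.54,
  diameter_sd_mm      = 3.41,
  diameter_range_mm   = c(66.31, 81.34)
)

#' Simulation configuration for the grasp generator
#'
#' Defaults reproduce the acquisition conditions of the emulated study: 120
#' fruit per class, fingers closing at 50 mm/s until a 20 N force set-point,
#' a 5 s hold, ~20 Hz pressure and ~200 Hz vibration sampling, 10-bit ADC.
#'
#' @param n_per_class Trials per class (>= 1).
#' @param effect_size Scale in `[0, 1]` applied to all frost-vs-normal
#'   parameter offsets; 0 makes the classes distributionally identical.
#' @param pressure_rate_hz,vibration_rate_hz Nominal sampling rates (Hz).
#' @param close_speed_mm_s Finger closing speed (mm/s); together with fruit
#'   diameter it sets the small per-trial variation in contact onset.
#' @param force_max_N Gripper force set-point (N).
#' @param hold_s Hold duration at the force set-point (s).
#' @param pre_contact_s Nominal free-closing time before contact (s).
#' @param load_s Duration of the exponential loading ramp before the force is
#'   clamped at the set-point (s).
#' @param release_s,post_release_s Linear release ramp and trailing baseline
#'   durations (s).
#' @param adc_max Full-scale ADC count (1023 for 10 bit).
#' @param pressure_sd_counts,vibration_sd_counts White-noise SD (counts).
#' @param delta_tau,delta_sigma,delta_freq,delta_damping,delta_event_rate
#'   Frost-class offsets (at `effect_size = 1`): longer ramp time constant
#'   (s), larger footprint spread (grid units), lower transient frequency
#'   (Hz), higher damping ratio, higher micro-event rate (Hz).
#' @param gain_counts_per_N Pressure-cell gain (counts per newton of total
#'   grip force routed through the cell's footprint weight).
#' @param pressure_baseline_counts,vibration_midpoint_counts ADC operating
#'   points of the unloaded sensors (8 and 512 counts).
#' @param timestamp_jitter_frac Uniform timestamp jitter as a fraction of the
#'   sampling interval (+/- 2% by default).
#' @param seed Integer seed; the full dataset is deterministic given the
#'   configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_class = 120,
                       effect_size = 1,
                       pressure_rate_hz = 20,
                       vibration_rate_hz = 200,
                       close_speed_mm_s = 50,
                       force_max_N = 20,
                       hold_s = 5,
                       pre_contact_s = 0.5,
                       load_s = 1,
                       release_s = 0.3,
                       post_release_s = 0.5,
                       adc_max = 1023L,
                       pressure_sd_counts = 2,
                       vibration_sd_counts = 4,
                       delta_tau = 0.10,
                       delta_sigma = 0.35,
                       delta_freq = 15,
                       delta_damping = 0.04,
                       delta_event_rate = 6,
                       gain_counts_per_N = 120,
                       pressure_baseline_counts = 8,
                       vibration_midpoint_counts = 512,
                       timestamp_jitter_frac = 0.02,
                       seed = 1L) {
  stopifnot_scalar_num(n_per_class, "n_per_class", lower = 1)
  stopifnot_scalar_num(effect_size, "effect_size", lower = 0, upper = 1)
  stopifnot_scalar_num(pressure_rate_hz, "pressure_rate_hz", lower = 1e-6)
  stopifnot_scalar_num(vibration_rate_hz, "vibration_rate_hz", lower = 1e-6)
  stopifnot_scalar_num(force_max_N, "force_max_N", lower = 1e-6)
  for (nm in c("delta_tau", "delta_sigma", "delta_freq", "delta_damping",
               "delta_event_rate"))
    stopifnot_scalar_num(get(nm), nm, lower = 0)
  cfg <- list(
    n_per_class = as.integer(n_per_class), effect_size = effect_size,
    pressure_rate_hz = pressure_rate_hz, vibration_rate_hz = vibration_rate_hz,
    close_speed_mm_s = close_speed_mm_s, force_max_N = force_max_N,
    hold_s = hold_s, pre_contact_s = pre_contact_s, load_s = load_s,
    release_s = release_s, post_release_s = post_release_s,
    adc_max = as.integer(adc_max),
    pressure_sd_counts = pressure_sd_counts,
    vibration_sd_counts = vibration_sd_counts,
    delta_tau = delta_tau, delta_sigma = delta_sigma, delta_freq = delta_freq,
    delta_damping = delta_damping, delta_event_rate = delta_event_rate,
    gain_counts_per_N = gain_counts_per_N,
    pressure_baseline_counts = pressure_baseline_counts,
    vibration_midpoint_counts = vibration_midpoint_counts,
    timestamp_jitter_frac = timestamp_jitter_frac,
    seed = as.integer(seed))
  structure(cfg, class = "sim_config")
}

#' Draw a fruit profile for one class
#'
#' Diameter is drawn from Normal(73.54, 3.41) mm truncated to
#' `[66.31, 81.34]` mm. Mechanical parameters start at the normal-class
#' baselines, are shifted by `effect_size` times the class offsets for the
#' frost-damaged class, and carry independent per-fruit lognormal jitter
#' (10% SD) for biological variability. Uses the current RNG stream.
#'
#' @param config A [sim_config()].
#' @param label `"normal"` or `"frost_damaged"`.
#' @param fruit_id Optional identifier.
#' @return An object of class `fruit_profile`.
#' @export
sample_fruit_profile <- function(config, label, fruit_id = "fruit") {
  if (!is.character(label) || length(label) != 1L ||
      !(label %in% class_levels()))
    stop("`label` must be one of ", paste(class_levels(), collapse = ", "),
         call. = FALSE)
  b <- .sim_baselines
  repeat {
    d <- stats::rnorm(1L, b$diameter_mean_mm, b$diameter_sd_mm)
    if (d >= b$diameter_range_mm[1] && d <= b$diameter_range_mm[2]) break
  }
  e <- if (label == "frost_damaged") config$effect_size else 0
  sdl <- sqrt(log(1 + b$bio_jitter_sd^2))
  jit <- function() stats::rlnorm(1L, meanlog = -sdl^2 / 2, sdlog = sdl)
  damping <- min(0.95, max(1e-3, (b$damping_ratio + e * config$delta_damping) * jit()))
  structure(list(
    fruit_id = fruit_id,
    label = label,
    diameter_mm = d,
    stiffness_tau_s = (b$stiffness_tau_s + e * config$delta_tau) * jit(),
    footprint_center = stats::runif(2L, 1.5, 3.5),
    footprint_spread = (b$footprint_spread + e * config$delta_sigma) * jit(),
    vib_freq_hz = max(5, (b$vib_freq_hz - e * config$delta_freq) * jit()),
    damping_ratio = damping,
    micro_event_rate_hz = (b$micro_event_rate_hz + e * config$delta_event_rate) * jit()
  ), class = "fruit_profile")
}

# Grip force trajectory (N) at times t for one trial.
.force_at <- function(t, t0, tau, cfg) {
  t_hold <- t0 + cfg$load_s
  t_rel  <- t_hold + cfg$hold_s
  t_off  <- t_rel + cfg$release_s
  f <- numeric(length(t))
  load <- t >= t0 & t < t_hold
  f[load] <- cfg$force_max_N * (1 - exp(-(t[load] - t0) / tau))
  f[t >= t_hold & t < t_rel] <- cfg$force_max_N
  rel <- t >= t_rel & t < t_off
  f[rel] <- cfg$force_max_N * (1 - (t[rel] - t_rel) / cfg$release_s)
  f
}

# Footprint SD (grid units) at times t: constant until the hold starts, then
# exponential creep towards the common redistribution spread.
.spread_at <- function(t, t_hold, spread0) {
  b <- .sim_baselines
  s <- rep(spread0, length(t))
  h <- t >= t_hold
  s[h] <- b$creep_spread + (spread0 - b$creep_spread) *
    exp(-(t[h] - t_hold) / b$creep_tau_s)
  s
}

.jittered_timestamps <- function(total_s, rate_hz, jitter_frac) {
  n <- floor(total_s * rate_hz)
  dt <- 1 / rate_hz
  ts <- (seq_len(n) - 1L) * dt + stats::runif(n, -jitter_frac, jitter_frac) * dt
  ts[1] <- max(ts[1], 0)
  ts
}

#' Simulate one grasp trial from a fruit profile
#'
#' Produces the raw timestamped pressure-matrix and vibration streams for a
#' single grasp (pre-contact, exponential loading to the force set-point,
#' hold, linear release, trailing baseline), quantised to integer ADC counts
#' in `[0, adc_max]`. Uses the current RNG stream.
#'
#' @param profile A [sample_fruit_profile()] result.
#' @param config A [sim_config()].
#' @param trial_id Identifier for the trial.
#' @return An object of class `grasp_trial` with elements `pressure`
#'   (`timestamp_s`, `counts` n x 36 integer matrix, row-major channel order
#'   `p00..p55`), `vibration` (`timestamp_s`, `counts`), `fruit`,
#'   `contact_onset_s` and ground-truth `metadata`.
#' @export
simulate_trial <- function(profile, config, trial_id = "trial") {
  pars <- unlist(profile[c("diameter_mm", "stiffness_tau_s", "footprint_spread",
                           "vib_freq_hz", "damping_ratio",
                           "micro_event_rate_hz")])
  if (any(!is.finite(c(pars, profile$footprint_center))))
    stop("non-finite fruit parameters", call. = FALSE)
  b <- .sim_baselines
  # Larger fruit meet the closing fingers earlier (gap closes at 2x finger speed).
  t0 <- config$pre_contact_s +
    (b$diameter_mean_mm - profile$diameter_mm) / (2 * config$close_speed_mm_s)
  t_hold <- t0 + config$load_s
  total <- t0 + config$load_s + config$hold_s + config$release_s +
    config$post_release_s

  ## ---- pressure stream ----
  tp <- .jittered_timestamps(total, config$pressure_rate_hz,
                             config$timestamp_jitter_frac)
  f <- .force_at(tp, t0, profile$stiffness_tau_s, config)
  # squared grid distances from the footprint centre, row-major p00..p55
  gi <- rep(0:5, each = 6); gj <- rep(0:5, times = 6)
  d2 <- (gi - profile$footprint_center[1])^2 + (gj - profile$footprint_center[2])^2
  sig <- .spread_at(tp, t_hold, profile$footprint_spread)
  w <- exp(-outer(1 / (2 * sig^2), d2))      # n x 36
  w <- w / rowSums(w)
  pcounts <- config$pressure_baseline_counts + config$gain_counts_per_N * w * f +
    matrix(stats::rnorm(length(w), 0, config$pressure_sd_counts), nrow(w))
  pcounts <- matrix(as.integer(pmin(pmax(round(pcounts), 0), config$adc_max)),
                    nrow(w),
                    dimnames = list(NULL, sprintf("p%d%d", gi, gj)))

  ## ---- vibration stream ----
  tv <- .jittered_timestamps(total, config$vibration_rate_hz,
                             config$timestamp_jitter_frac)
  drift_amp <- stats::runif(1L, 5, 15)
  drift_freq <- stats::runif(1L, 0.5, 3)     # < 5 Hz quasi-static drift
  drift_phase <- stats::runif(1L, 0, 2 * pi)
  v <- config$vibration_midpoint_counts +
    drift_amp * sin(2 * pi * drift_freq * tv + drift_phase)
  sdl <- sqrt(log(1 + b$bio_jitter_sd^2))
  amp <- b$transient_amp_counts * stats::rlnorm(1L, -sdl^2 / 2, sdl)
  wn <- 2 * pi * profile$vib_freq_hz
  wd <- wn * sqrt(1 - profile$damping_ratio^2)
  tt <- tv - t0
  on <- tt >= 0
  v[on] <- v[on] + amp * exp(-profile$damping_ratio * wn * tt[on]) * sin(wd * tt[on])
  n_ev <- stats::rpois(1L, profile$micro_event_rate_hz * config$load_s)
  ev_times <- if (n_ev > 0) sort(stats::runif(n_ev, t0, t_hold)) else numeric(0)
  ev_amps <- stats::runif(n_ev, 20, 60)
  ev_freqs <- stats::runif(n_ev, 40, 90)
  for (k in seq_len(n_ev)) {
    te <- tv - ev_times[k]
    onk <- te >= 0
    wk <- 2 * pi * ev_freqs[k]
    v[onk] <- v[onk] + ev_amps[k] * exp(-0.1 * wk * te[onk]) *
      sin(wk * sqrt(1 - 0.01) * te[onk])
  }
  v <- v + stats::rnorm(length(v), 0, config$vibration_sd_counts)
  vcounts <- as.integer(pmin(pmax(round(v), 0), config$adc_max))

  structure(list(
    trial_id = trial_id,
    fruit = profile,
    pressure = list(timestamp_s = tp, counts = pcounts),
    vibration = list(timestamp_s = tv, counts = vcounts),
    contact_onset_s = t0,
    metadata = list(
      t_hold_start_s = t_hold,
      t_release_start_s = t_hold + config$hold_s,
      total_s = total,
      drift_amp = drift_amp, drift_freq_hz = drift_freq,
      drift_phase = drift_phase, transient_amp = amp,
      event_times_s = ev_times, event_amps = ev_amps, event_freqs_hz = ev_freqs)
  ), class = "grasp_trial")
}

#' Generate a labelled synthetic grasp dataset
#'
#' Draws `n_per_class` fruit profiles and trials per class, deterministically
#' for a given configuration (including its seed). The manifest records the
#' label and ground-truth mechanical parameters of every trial.
#'
#' @param config A [sim_config()].
#' @return An object of class `grasp_dataset`: list of `trials`, a `manifest`
#'   data frame and the echoed `config`.
#' @export
simulate_grasp_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) stop("`config` must be a sim_config")
  if (config$n_per_class < 1L) stop("n_per_class must be >= 1", call. = FALSE)
  local_seed(config$seed, {
    n <- config$n_per_class
    labels <- rep(class_levels(), each = n)
    trials <- vector("list", 2L * n)
    for (i in seq_along(labels)) {
      id <- sprintf("t%04d", i)
      prof <- sample_fruit_profile(config, labels[i], fruit_id = id)
      trials[[i]] <- simulate_trial(prof, config, trial_id = id)
    }
    manifest <- data.frame(
      trial_id = vapply(trials, `[[`, "", "trial_id"),
      label = labels,
      diameter_mm = vapply(trials, function(t) t$fruit$diameter_mm, 0),
      stiffness_tau_s = vapply(trials, function(t) t$fruit$stiffness_tau_s, 0),
      footprint_spread = vapply(trials, function(t) t$fruit$footprint_spread, 0),
      vib_freq_hz = vapply(trials, function(t) t$fruit$vib_freq_hz, 0),
      damping_ratio = vapply(trials, function(t) t$fruit$damping_ratio, 0),
      micro_event_rate_hz =
        vapply(trials, function(t) t$fruit$micro_event_rate_hz, 0),
      contact_onset_s = vapply(trials, `[[`, 0, "contact_onset_s"),
      stringsAsFactors = FALSE)
    structure(list(trials = trials, manifest = manifest, config = config),
              class = "grasp_dataset")
  })
}

#' @export
print.grasp_dataset <- function(x, ...) {
  tab <- table(x$manifest$label)
  cat("Synthetic grasp dataset:", length(x$trials), "trials (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")\n")
  cat("  effect size:", x$config$effect_size,
      " seed:", x$config$seed, "\n")
  invisible(x)
}

#' @export
print.grasp_trial <- function(x, ...) {
  cat(sprintf("Grasp trial %s [%s]: %d pressure frames, %d vibration samples, onset %.3f s\n",
              x$trial_id, x$fruit$label, nrow(x$pressure$counts),
              length(x$vibration$counts), x$contact_onset_s))
  invisible(x)
}
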