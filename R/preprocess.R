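# Raw grasp trials -> fixed-length model inputs.
#
# Pipeline per trial: detect the grasp segment from the summed pressure
# frames, crop both streams to it, moving-average denoise the pressure
# channels, linearly resample to the fixed model-input length (50 steps),
# min-max normalise the pressure block jointly over all channels; high-pass
# the vibration stream (2nd-order Butterworth, 30 Hz cutoff at the nominal
# 200 Hz rate, causal single pass), resample to 50 steps and z-score per
# trial. Throughout, sequences are stored time-by-channel (rows = time).

#' Preprocessing configuration
#'
#' @param target_length Fixed model-input length (time steps).
#' @param hp_order,hp_cutoff_hz Butterworth high-pass order and cutoff (Hz)
#'   for the vibration stream.
#' @param nominal_vib_rate_hz Nominal vibration sampling rate used for the
#'   digital filter design.
#' @param denoise_window Odd moving-average window (frames) for pressure
#'   denoising; 1 disables it.
#' @param onset_threshold_k Contact threshold in baseline SDs above the
#'   baseline mean of the summed pressure frame.
#' @param onset_baseline_frac Fraction of leading (and trailing) frames used
#'   as the contact/release baseline window. The default 0.06 keeps the
#'   baseline inside the free-closing phase that precedes contact under the
#'   emulated grasp timing (~0.5 s approach in a ~7 s trial at 20 Hz).
#' @param norm_epsilon Guard added to min-max and z-score denominators.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_length = 50L,
                              hp_order = 2L,
                              hp_cutoff_hz = 30,
                              nominal_vib_rate_hz = 200,
                              denoise_window = 3L,
                              onset_threshold_k = 5,
                              onset_baseline_frac = 0.06,
                              norm_epsilon = 1e-8) {
  if (target_length < 2L) stop("target_length must be >= 2", call. = FALSE)
  if (hp_cutoff_hz >= nominal_vib_rate_hz / 2)
    stop("hp_cutoff_hz must be below the Nyquist frequency", call. = FALSE)
  if (denoise_window < 1L || denoise_window %% 2L == 0L)
    stop("denoise_window must be an odd count >= 1", call. = FALSE)
  structure(list(
    target_length = as.integer(target_length), hp_order = as.integer(hp_order),
    hp_cutoff_hz = hp_cutoff_hz, nominal_vib_rate_hz = nominal_vib_rate_hz,
    denoise_window = as.integer(denoise_window),
    onset_threshold_k = onset_threshold_k,
    onset_baseline_frac = onset_baseline_frac,
    norm_epsilon = norm_epsilon), class = "preprocess_config")
}

#' Detect the grasp segment of a trial
#'
#' Contact onset is the first pressure frame whose summed counts exceed the
#' leading-baseline mean by `onset_threshold_k` baseline SDs; release is
#' found symmetrically from the trailing baseline window. Both stream crops
#' use the returned `[t_start, t_end]` interval.
#'
#' @param trial A `grasp_trial`.
#' @param cfg A [preprocess_config()].
#' @return List with `t_start` and `t_end` (seconds).
#' @export
detect_grasp_segment <- function(trial, cfg = preprocess_config()) {
  tp <- trial$pressure$timestamp_s
  sums <- rowSums(trial$pressure$counts)
  n <- length(sums)
  if (n == 0L || length(trial$vibration$counts) == 0L)
    stop("trial streams must be non-empty", call. = FALSE)
  nb <- max(3L, floor(cfg$onset_baseline_frac * n))
  lead <- sums[seq_len(nb)]
  thr_on <- mean(lead) + cfg$onset_threshold_k * stats::sd(lead)
  i_on <- which(sums > thr_on)[1]
  if (is.na(i_on)) stop("no contact detected", call. = FALSE)
  trail <- sums[(n - nb + 1L):n]
  thr_off <- mean(trail) + cfg$onset_threshold_k * stats::sd(trail)
  above <- which(sums > thr_off)
  i_off <- if (length(above)) max(above) else n
  if (i_off <= i_on) stop("no contact detected", call. = FALSE)
  list(t_start = tp[i_on], t_end = tp[i_off])
}

#' Moving-average denoising of a pressure stream
#'
#' Centred moving average of odd window `denoise_window`, applied
#' independently per channel; edge positions use symmetrically shrunken
#' windows so the output length equals the input length.
#'
#' @param frames Numeric matrix, time x channels.
#' @param cfg A [preprocess_config()] (or an odd integer window).
#' @return Numeric matrix of the same shape.
#' @export
denoise_pressure <- function(frames, cfg = preprocess_config()) {
  w <- if (inherits(cfg, "preprocess_config")) cfg$denoise_window else as.integer(cfg)
  if (w < 1L || w %% 2L == 0L)
    stop("denoise window must be an odd count >= 1", call. = FALSE)
  frames <- as.matrix(frames)
  n <- nrow(frames)
  if (n < w) stop("need at least `denoise_window` frames", call. = FALSE)
  if (w == 1L) return(frames)
  h <- (w - 1L) %/% 2L
  t <- seq_len(n)
  lo <- pmax(t - h, 1L)
  hi <- pmin(t + h, n)
  out <- apply(frames, 2L, function(x) {
    cs <- c(0, cumsum(x))
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  })
  matrix(out, nrow = n, dimnames = dimnames(frames))
}

#' Linear resampling to a fixed length
#'
#' Interpolates each channel linearly onto `target_length` points uniformly
#' spaced over the observed time span; the first and last output values
#' equal the first and last input values.
#'
#' @param values Numeric matrix (time x channels) or vector.
#' @param timestamps Strictly increasing numeric vector of sample times.
#' @param target_length Number of output time steps.
#' @return `target_length` x channels numeric matrix.
#' @export
resample_to_length <- function(values, timestamps, target_length = 50L) {
  values <- as.matrix(values)
  if (nrow(values) < 2L) stop("need at least 2 time points", call. = FALSE)
  if (length(timestamps) != nrow(values))
    stop("timestamps must match the number of rows", call. = FALSE)
  grid <- seq(timestamps[1], timestamps[length(timestamps)],
              length.out = target_length)
  out <- apply(values, 2L, function(x)
    stats::approx(timestamps, x, xout = grid, method = "linear")$y)
  matrix(out, nrow = target_length, dimnames = list(NULL, colnames(values)))
}

#' Joint min-max normalisation of a pressure sequence
#'
#' One min-max over all entries of the trial's pressure block, preserving
#' the relative spatial load pattern across channels.
#'
#' @param seq Numeric matrix.
#' @param epsilon Guard added to the denominator; a constant input maps to 0.
#' @return Matrix with entries in `[0, 1]`.
#' @export
normalize_pressure <- function(seq, epsilon = 1e-8) {
  if (any(!is.finite(seq))) stop("non-finite pressure input", call. = FALSE)
  rng <- range(seq)
  (seq - rng[1]) / (rng[2] - rng[1] + epsilon)
}

#' Butterworth high-pass filtering of a vibration stream
#'
#' Causal single-pass second-order Butterworth high-pass designed by
#' bilinear transform (cutoff prewarped) at the nominal sampling rate,
#' applied after removing the series mean. The steady-state gain at the
#' cutoff is 1/sqrt(2) and the DC gain is zero.
#'
#' @param samples Numeric vector.
#' @param cfg A [preprocess_config()].
#' @return Filtered numeric vector of the same length.
#' @export
highpass_vibration <- function(samples, cfg = preprocess_config()) {
  if (cfg$hp_cutoff_hz >= cfg$nominal_vib_rate_hz / 2)
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  if (length(samples) <= 3L * cfg$hp_order)
    stop("series too short for the filter order", call. = FALSE)
  bf <- signal::butter(cfg$hp_order,
                       cfg$hp_cutoff_hz / (cfg$nominal_vib_rate_hz / 2),
                       type = "high")
  as.numeric(signal::filter(bf, samples - mean(samples)))
}

#' Build one fixed-length model input from a grasp trial
#'
#' Runs the full preprocessing pipeline: segment, denoise and resample the
#' pressure stream (channels kept in row-major `p00..p55` order, renamed
#' `f00..f35`), min-max normalise; high-pass, resample and z-score the
#' vibration stream; attach the one-hot label (`normal` = `[1,0]`,
#' `frost_damaged` = `[0,1]`).
#'
#' @param trial A `grasp_trial`.
#' @param cfg A [preprocess_config()].
#' @param label Optional label override (defaults to the trial's own label).
#' @return An object of class `model_input` with `pressure_seq` (50 x 36 in
#'   `[0,1]`), `vibration_seq` (50 x 1, zero mean unit SD), `label`,
#'   `label_onehot` and `trial_id`.
#' @export
build_model_input <- function(trial, cfg = preprocess_config(), label = NULL) {
  label <- label %||% trial$fruit$label
  if (!label %in% class_levels())
    stop("unknown label: ", label, call. = FALSE)
  seg <- detect_grasp_segment(trial, cfg)

  pidx <- trial$pressure$timestamp_s >= seg$t_start &
    trial$pressure$timestamp_s <= seg$t_end
  pden <- denoise_pressure(trial$pressure$counts[pidx, , drop = FALSE], cfg)
  pres <- resample_to_length(pden, trial$pressure$timestamp_s[pidx],
                             cfg$target_length)
  pres <- normalize_pressure(pres, cfg$norm_epsilon)
  colnames(pres) <- sprintf("f%02d", 0:(ncol(pres) - 1L))

  vidx <- trial$vibration$timestamp_s >= seg$t_start &
    trial$vibration$timestamp_s <= seg$t_end
  vhp <- highpass_vibration(trial$vibration$counts[vidx], cfg)
  vib <- resample_to_length(vhp, trial$vibration$timestamp_s[vidx],
                            cfg$target_length)
  vib <- (vib - mean(vib)) / (stats::sd(vib) + cfg$norm_epsilon)
  colnames(vib) <- "v"

  onehot <- as.integer(class_levels() == label)
  structure(list(pressure_seq = pres, vibration_seq = vib,
                 label = label, label_onehot = onehot,
                 trial_id = trial$trial_id),
            class = "model_input")
}

#' Preprocess every trial of a dataset
#'
#' @param dataset A `grasp_dataset` (or plain list of `grasp_trial`s).
#' @param cfg A [preprocess_config()].
#' @return An object of class `model_input_set`: a list of `model_input`s
#'   with the preprocessing config attached as an attribute.
#' @export
preprocess_dataset <- function(dataset, cfg = preprocess_config()) {
  trials <- if (inherits(dataset, "grasp_dataset")) dataset$trials else dataset
  inputs <- lapply(trials, build_model_input, cfg = cfg)
  structure(inputs, class = "model_input_set", config = cfg)
}

#' Labels of a model-input set
#' @param inputs A `model_input_set` or list of `model_input`s.
#' @return Character vector of class labels.
#' @export
input_labels <- function(inputs) {
  vapply(inputs, `[[`, "", "label")
}

#' @export
print.model_input_set <- function(x, ...) {
  tab <- table(input_labels(x))
  cat("Model-input set:", length(x), "samples (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")\n")
  cat("  shapes:", paste(dim(x[[1]]$pressure_seq), collapse = "x"), "pressure,",
      paste(dim(x[[1]]$vibration_seq), collapse = "x"), "vibration\n")
  invisible(x)
}
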