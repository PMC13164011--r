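# Residual-aware attention rollout and temporal attribution.
#
# For each sample and branch: average the per-head post-softmax attention
# maps, add the identity for the residual path and row-normalise
# (equivalently (A_bar + I)/2 for a row-stochastic A_bar), roll out across
# layers by matrix product (the single-block architecture reduces this to
# the residual-adjusted map itself), score each time step by its mean
# incoming attention over all query positions, min-max normalise to [0, 1],
# fuse the two branch profiles by equal-weight averaging, and record the
# peak time step. Peak times over a dataset are summarised as a fixed-width
# interval histogram.

#' Attribution configuration
#'
#' @param epsilon Guard added to the min-max denominator.
#' @param interval_width Histogram bin width in time steps.
#' @param peak_tie_rule Tie rule for the peak time step (earliest index).
#' @return An object of class `attribution_config`.
#' @export
attribution_config <- function(epsilon = 1e-8, interval_width = 5L,
                               peak_tie_rule = "earliest") {
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (interval_width < 1L) stop("interval_width must be >= 1", call. = FALSE)
  structure(list(epsilon = epsilon, interval_width = as.integer(interval_width),
                 peak_tie_rule = peak_tie_rule), class = "attribution_config")
}

#' Average attention maps across heads
#' @param maps List of `H` row-stochastic `T` x `T` matrices.
#' @return Elementwise mean matrix (row-stochastic).
#' @export
average_heads <- function(maps) {
  if (length(maps) == 0L) stop("empty map list", call. = FALSE)
  Reduce(`+`, maps) / length(maps)
}

#' Residual-adjusted attention map
#'
#' Adds the identity for the residual connection and row-normalises; for a
#' row-stochastic input each row of `A_bar + I` sums to 2, so the result is
#' `(A_bar + I) / 2`.
#'
#' @param A_bar Row-stochastic `T` x `T` matrix.
#' @return Row-stochastic `T` x `T` matrix.
#' @export
residual_adjust <- function(A_bar) {
  A <- A_bar + diag(nrow(A_bar))
  A / rowSums(A)
}

#' Attention rollout across layers
#'
#' Ordered matrix product of residual-adjusted maps; with a single
#' self-attention block the rollout is the residual-adjusted map itself.
#'
#' @param A_tilde_layers A single matrix or list of `T` x `T` matrices,
#'   first layer first.
#' @return `T` x `T` rollout matrix.
#' @export
attention_rollout <- function(A_tilde_layers) {
  if (is.matrix(A_tilde_layers)) return(A_tilde_layers)
  if (length(A_tilde_layers) == 0L) stop("need at least one layer map")
  dims <- vapply(A_tilde_layers, function(m) dim(m), integer(2))
  if (length(unique(as.vector(dims))) != 1L)
    stop("layer maps must share dimensions", call. = FALSE)
  Reduce(`%*%`, A_tilde_layers)
}

#' Temporal attribution score
#'
#' `s(t)` is the mean incoming attention to time step `t` over all query
#' positions (the column means of the rollout matrix); for a row-stochastic
#' rollout the scores sum to 1.
#'
#' @param R Row-stochastic rollout matrix.
#' @return Numeric vector of length `T`.
#' @export
temporal_score <- function(R) {
  colMeans(R)
}

#' Min-max normalisation of an attribution profile
#' @param s Numeric vector.
#' @param epsilon Guard added to the denominator; a constant profile maps
#'   to all zeros.
#' @return Vector in `[0, 1]`.
#' @export
minmax_normalize <- function(s, epsilon = 1e-8) {
  (s - min(s)) / (max(s) - min(s) + epsilon)
}

#' Equal-weight fusion of two normalised profiles
#' @param s_hat_p,s_hat_v Normalised profiles of equal length.
#' @return Elementwise mean profile.
#' @export
fuse_profiles <- function(s_hat_p, s_hat_v) {
  if (length(s_hat_p) != length(s_hat_v))
    stop("profiles must have equal length", call. = FALSE)
  (s_hat_p + s_hat_v) / 2
}

#' Peak-attribution time step
#' @param s_hat_fused Fused normalised profile.
#' @return 0-based index of the maximum; ties broken by earliest index.
#' @export
peak_time <- function(s_hat_fused) {
  if (length(s_hat_fused) == 0L) stop("empty profile", call. = FALSE)
  which.max(s_hat_fused) - 1L
}

#' Histogram of peak-attribution intervals
#'
#' Groups 0-based peak time steps into fixed-width bins `[0, w)`, `[w, 2w)`,
#' ..., covering `[0, T-1]`; the final bin may be partial.
#'
#' @param t_stars Integer vector of 0-based peak time steps.
#' @param cfg An [attribution_config()].
#' @param T Sequence length.
#' @param labels Optional class labels for a per-class breakdown.
#' @return Object of class `peak_histogram` with `edges` (bin starts),
#'   `counts`, and optional `per_class` counts.
#' @export
peak_interval_histogram <- function(t_stars, cfg = attribution_config(),
                                    T = 50L, labels = NULL) {
  if (length(t_stars) == 0L) stop("empty peak-time input", call. = FALSE)
  if (any(t_stars < 0 | t_stars > T - 1L))
    stop("peak times must lie in [0, T-1]", call. = FALSE)
  w <- cfg$interval_width
  n_bins <- ceiling(T / w)
  bin <- pmin(t_stars %/% w, n_bins - 1L) + 1L
  counts <- tabulate(bin, nbins = n_bins)
  per_class <- NULL
  if (!is.null(labels)) {
    per_class <- t(vapply(unique(labels),
                          function(l) tabulate(bin[labels == l], nbins = n_bins),
                          integer(n_bins)))
    rownames(per_class) <- unique(labels)
  }
  structure(list(edges = (seq_len(n_bins) - 1L) * w, width = w,
                 counts = counts, per_class = per_class, T = as.integer(T)),
            class = "peak_histogram")
}

#' Attribution profile of a single sample
#'
#' Runs the full rollout pipeline on one sample's extracted attention maps.
#'
#' @param model A fitted Transformer-kind [graspnet()].
#' @param input A single `model_input`.
#' @param cfg An [attribution_config()].
#' @return Object of class `attribution_profile` with per-branch raw scores
#'   (`s_p`, `s_v`; each sums to 1), normalised profiles (`s_hat_p`,
#'   `s_hat_v`), the fused profile, the 0-based peak step `t_star`, the
#'   rollout intermediates, and the sample id/label.
#' @export
attribution_profile <- function(model, input, cfg = attribution_config()) {
  maps <- extract_attention_maps(model, input)
  branch <- function(head_maps) {
    A_bar <- average_heads(head_maps)
    A_tilde <- residual_adjust(A_bar)
    R <- attention_rollout(A_tilde)
    s <- temporal_score(R)
    list(A_bar = A_bar, A_tilde = A_tilde, R = R, s = s,
         s_hat = minmax_normalize(s, cfg$epsilon))
  }
  br <- lapply(maps, branch)
  s_hats <- lapply(br, `[[`, "s_hat")
  fused <- if (length(s_hats) == 2L) fuse_profiles(s_hats[[1]], s_hats[[2]])
           else s_hats[[1]]
  structure(list(
    sample_id = input$trial_id, label = input$label,
    s_p = if (!is.null(br$pressure)) br$pressure$s,
    s_v = if (!is.null(br$vibration)) br$vibration$s,
    s_hat_p = if (!is.null(br$pressure)) br$pressure$s_hat,
    s_hat_v = if (!is.null(br$vibration)) br$vibration$s_hat,
    s_hat_fused = fused, t_star = peak_time(fused),
    rollout = lapply(br, `[`, c("A_bar", "A_tilde", "R"))),
    class = "attribution_profile")
}

#' Attribution profiles and peak histogram over a dataset
#'
#' Extracts inference-mode attention maps for every sample, computes the
#' rollout attribution profile per branch, fuses them, and summarises the
#' peak times as an interval histogram (with per-class counts).
#'
#' @param model A fitted Transformer-kind [graspnet()].
#' @param inputs A `model_input_set` or list of `model_input`s.
#' @param cfg An [attribution_config()].
#' @return Object of class `attribution_result`: `profiles` (list of
#'   [attribution_profile()]s), `fused` (n x T matrix of fused profiles),
#'   `t_star`, `labels` and `histogram`.
#' @export
attribute_dataset <- function(model, inputs, cfg = attribution_config()) {
  if (inherits(inputs, "model_input")) inputs <- list(inputs)
  profiles <- lapply(inputs, function(x) attribution_profile(model, x, cfg))
  fused <- do.call(rbind, lapply(profiles, `[[`, "s_hat_fused"))
  rownames(fused) <- vapply(profiles, `[[`, "", "sample_id")
  t_star <- vapply(profiles, `[[`, 0L, "t_star")
  labels <- vapply(profiles, `[[`, "", "label")
  hist <- peak_interval_histogram(t_star, cfg, T = model$net$T, labels = labels)
  structure(list(profiles = profiles, fused = fused, t_star = t_star,
                 labels = labels, histogram = hist),
            class = "attribution_result")
}

#' @export
print.peak_histogram <- function(x, ...) {
  cat("Peak-attribution interval histogram (bin width", x$width, "steps):\n")
  for (i in seq_along(x$counts))
    cat(sprintf("  [%2d,%2d): %d\n", x$edges[i],
                min(x$edges[i] + x$width, x$T), x$counts[i]))
  invisible(x)
}

#' @export
print.attribution_result <- function(x, ...) {
  cat("Attribution over", length(x$profiles), "samples; median peak step",
      stats::median(x$t_star), "of", ncol(x$fused), "\n")
  invisible(x)
}
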