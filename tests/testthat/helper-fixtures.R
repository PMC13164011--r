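# Shared fixtures, all built in code at test time.

tiny_dataset <- function(n_per_class = 4, effect_size = 1, seed = 7, ...) {
  simulate_grasp_dataset(sim_config(n_per_class = n_per_class,
                                    effect_size = effect_size,
                                    seed = seed, ...))
}

tiny_inputs <- function(...) preprocess_dataset(tiny_dataset(...))

# Trivially separable time-constant inputs: the two classes differ by a
# large fixed pattern across pressure channels and an opposite-phase
# vibration waveform (patterns, not constant offsets, so they survive the
# layer-norm invariances of the architecture).
toy_inputs <- function(n_per_class = 12, T = 50) {
  pat <- rep(c(0.9, 0.1), each = 18)
  mk <- function(label, id) {
    sgn <- if (label == "normal") 1 else -1
    structure(list(
      pressure_seq = outer(rep(1, T), if (sgn > 0) pat else rev(pat),
                           `*`) + 0,
      vibration_seq = matrix(sgn * sin(2 * pi * seq_len(T) / T), T, 1,
                             dimnames = list(NULL, "v")),
      label = label,
      label_onehot = as.integer(c("normal", "frost_damaged") == label),
      trial_id = id), class = "model_input")
  }
  inputs <- c(
    lapply(seq_len(n_per_class), function(i)
      mk("normal", sprintf("toyN%02d", i))),
    lapply(seq_len(n_per_class), function(i)
      mk("frost_damaged", sprintf("toyF%02d", i))))
  structure(inputs, class = "model_input_set")
}

random_row_stochastic <- function(T) {
  m <- matrix(stats::runif(T * T), T, T)
  m / rowSums(m)
}

# Fast training settings for protocol smoke tests.
quick_training <- function(max_epochs = 4, patience = 3)
  training_config(max_epochs = max_epochs, patience = patience)

# A small network config for gradient checks.
tiny_net <- function() network_config(T = 6L, d_p = 4L, d_v = 1L, H = 2L,
                                      d_k = 3L, dropout_rate = 0,
                                      head_units = c(5L, 4L))

# Stacked random batch matching a config.
random_batch <- function(cfg, B = 3L) {
  list(Xp = matrix(stats::rnorm(B * cfg$T * cfg$d_p), B * cfg$T, cfg$d_p),
       Xv = matrix(stats::rnorm(B * cfg$T * cfg$d_v), B * cfg$T, cfg$d_v),
       Y = t(vapply(seq_len(B), function(i) sample(c(1, 0)), numeric(2))),
       B = B)
}

# Wrap an untrained build_model() result so predict() methods apply.
as_untrained_fit <- function(model) {
  structure(c(model, list(net = model$cfg,
                          levels = c("normal", "frost_damaged"))),
            class = "graspnet")
}
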