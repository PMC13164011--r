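test_that("grasp segmentation recovers the true contact onset", {
  cfg <- sim_config(n_per_class = 2, pressure_sd_counts = 0,
                    vibration_sd_counts = 0, seed = 13)
  ds <- simulate_grasp_dataset(cfg)
  for (tr in ds$trials) {
    seg <- detect_grasp_segment(tr)
    expect_gte(seg$t_start, tr$contact_onset_s)
    expect_lt(seg$t_start - tr$contact_onset_s, 1.1 / 20)  # one frame interval
    expect_gte(seg$t_end - seg$t_start, sim_config()$hold_s)
  }
})

test_that("an all-baseline trial raises a no-contact error", {
  tr <- tiny_dataset(n_per_class = 1, seed = 17)$trials[[1]]
  tr$pressure$counts[] <- 8L
  expect_error(detect_grasp_segment(tr), "no contact detected")
})

test_that("moving-average denoising matches its closed form", {
  const <- matrix(5, 20, 3)
  expect_equal(denoise_pressure(const, 3L), const, ignore_attr = TRUE)
  expect_identical(denoise_pressure(const, 1L), const)

  imp <- matrix(0, 21, 1)
  imp[11, 1] <- 9
  sm <- denoise_pressure(imp, 3L)
  expect_equal(sm[10:12, 1], c(3, 3, 3))
  expect_equal(sum(sm), 9)           # linear-phase averaging conserves mass
  # shrunken edge windows
  edge <- matrix(c(6, 0, 0, 0), 4, 1)
  expect_equal(denoise_pressure(edge, 3L)[1, 1], 3)  # mean of first two

  expect_error(denoise_pressure(const, 4L), "odd")
  expect_error(denoise_pressure(const[1:2, , drop = FALSE], 3L), "frames")
})

test_that("linear resampling matches the analytic interpolant", {
  # identity on an already-uniform length-50 grid
  ts <- seq(0, 1, length.out = 50)
  x <- matrix(stats::rnorm(50 * 2), 50, 2)
  expect_equal(resample_to_length(x, ts, 50L), x,
               tolerance = 1e-9, ignore_attr = TRUE)

  # linear ramp 0 -> 1 over 200 points resampled to 50
  ramp <- seq(0, 1, length.out = 200)
  out <- resample_to_length(ramp, seq_along(ramp), 50L)
  expect_equal(as.vector(out), seq(0, 1, length.out = 50), tolerance = 1e-9)

  # constants stay constant; endpoints are preserved
  const <- rep(3.5, 37)
  expect_equal(as.vector(resample_to_length(const, cumsum(runif(37)), 50L)),
               rep(3.5, 50))
  y <- cumsum(abs(rnorm(80)))
  r <- resample_to_length(y, seq_len(80), 50L)
  expect_equal(r[1, 1], y[1])
  expect_equal(r[50, 1], y[80])
  expect_true(all(diff(r[, 1]) >= 0))  # monotone input stays monotone

  expect_error(resample_to_length(matrix(1, 1, 1), 1, 50L), "2 time points")
})

test_that("pressure normalisation is a joint epsilon-guarded min-max", {
  expect_equal(normalize_pressure(matrix(7, 5, 5)), matrix(0, 5, 5))
  x <- matrix(c(100, 400, 900, 250), 2, 2)
  nx <- normalize_pressure(x)
  expect_equal(min(nx), 0)
  expect_equal(max(nx), (900 - 100) / (800 + 1e-8))
  r <- matrix(stats::rnorm(100), 10)
  expect_true(all(normalize_pressure(r) >= 0 & normalize_pressure(r) <= 1))
})

test_that("the high-pass filter matches its frequency response", {
  cfg <- preprocess_config()
  fs <- 200
  t <- (0:2047) / fs
  measured_gain <- function(f) {
    y <- highpass_vibration(sin(2 * pi * f * t), cfg)
    idx <- 500:2048                       # steady state past the transient
    fit <- stats::lm(y[idx] ~ sin(2 * pi * f * t[idx]) +
                       cos(2 * pi * f * t[idx]))
    sqrt(sum(stats::coef(fit)[2:3]^2))
  }
  # DC: constant input decays below 1e-6 after the transient
  yc <- highpass_vibration(rep(512, 2048), cfg)
  expect_lt(max(abs(yc[51:2048])), 1e-6)
  # cutoff gain 1/sqrt(2); passband gain near 1
  expect_lt(abs(measured_gain(30) - 0.7071), 0.01)
  expect_gte(measured_gain(80), 0.97)
  # measured gains match the analytic digital response within 1%
  analytic <- function(f) {
    bf <- signal::butter(2, 30 / (fs / 2), type = "high")
    z <- exp(-1i * 2 * pi * f / fs)
    Mod(sum(bf$b * z^(0:2)) / sum(bf$a * z^(0:2)))
  }
  for (f in c(30, 80))
    expect_lt(abs(measured_gain(f) - analytic(f)) / analytic(f), 0.01)

  expect_error(highpass_vibration(rnorm(100),
                                  preprocess_config(hp_cutoff_hz = 99,
                                                    nominal_vib_rate_hz = 200)),
               NA)
  expect_error(preprocess_config(hp_cutoff_hz = 100), "Nyquist")
  expect_error(highpass_vibration(rnorm(5), cfg), "too short")
})

test_that("model inputs satisfy the shape and normalisation contracts", {
  inputs <- tiny_inputs(n_per_class = 3, seed = 19)
  expect_length(inputs, 6L)
  for (x in inputs) {
    expect_identical(dim(x$pressure_seq), c(50L, 36L))
    expect_identical(dim(x$vibration_seq), c(50L, 1L))
    expect_true(all(is.finite(x$pressure_seq)) && all(is.finite(x$vibration_seq)))
    expect_true(all(x$pressure_seq >= 0 & x$pressure_seq <= 1))
    expect_lt(abs(mean(x$vibration_seq)), 1e-6)
    expect_equal(sum(x$label_onehot), 1L)
    if (x$label == "frost_damaged")
      expect_identical(x$label_onehot, c(0L, 1L))
    else
      expect_identical(x$label_onehot, c(1L, 0L))
  }
})
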