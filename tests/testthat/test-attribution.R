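# The 3x3 worked example used throughout: a row-stochastic head-averaged map
# whose residual adjustment and scores have simple closed forms.
worked_A_bar <- matrix(c(0.5, 0.2, 0.1,
                         0.3, 0.6, 0.1,
                         0.2, 0.2, 0.8), 3, 3)
worked_A_tilde <- matrix(c(0.75, 0.10, 0.05,
                           0.15, 0.80, 0.05,
                           0.10, 0.10, 0.90), 3, 3)

test_that("head averaging preserves row-stochasticity", {
  m <- random_row_stochastic(5)
  expect_identical(average_heads(list(m)), m)

  T <- 4
  ab <- average_heads(list(diag(T), matrix(1 / T, T, T)))
  expect_equal(diag(ab), rep((1 + 1 / T) / 2, T))
  expect_equal(ab[1, 2], 1 / (2 * T))
  expect_equal(rowSums(ab), rep(1, T))

  expect_error(average_heads(list()), "empty")
})

test_that("residual adjustment matches (A + I) / 2 for stochastic inputs", {
  expect_equal(residual_adjust(diag(2)), diag(2))
  expect_equal(residual_adjust(worked_A_bar), worked_A_tilde, tolerance = 1e-12)
  u <- residual_adjust(matrix(1 / 50, 50, 50))
  expect_equal(diag(u), rep(0.51, 50))
  expect_equal(u[2, 1], 0.01)
})

test_that("rollout reduces to the residual-adjusted map for one block", {
  m <- random_row_stochastic(6)
  expect_identical(attention_rollout(m), m)
  expect_identical(attention_rollout(list(m)), m)
  expect_equal(attention_rollout(list(diag(3), diag(3))), diag(3))
  r <- attention_rollout(list(random_row_stochastic(7),
                              random_row_stochastic(7)))
  expect_lt(max(abs(rowSums(r) - 1)), 1e-9)
  expect_error(attention_rollout(list(diag(2), diag(3))), "dimensions")
})

test_that("temporal scores are column means summing to one", {
  for (T in c(3, 50)) {
    expect_equal(temporal_score(residual_adjust(matrix(1 / T, T, T))),
                 rep(1 / T, T))
    expect_equal(temporal_score(diag(T)), rep(1 / T, T))
  }
  s <- temporal_score(worked_A_tilde)
  expect_equal(s, c(0.3000, 0.3333, 0.3667), tolerance = 1e-4)
  expect_equal(sum(s), 1)
})

test_that("min-max normalisation and fusion follow their formulas", {
  expect_equal(minmax_normalize(rep(0.25, 8)), rep(0, 8))
  s_hat <- minmax_normalize(c(0.3000, 1 / 3, 11 / 30))
  expect_equal(s_hat, c(0, 0.5, 1), tolerance = 1e-4)
  expect_equal(min(minmax_normalize(rnorm(20))), 0)

  expect_equal(fuse_profiles(c(1, 0), c(0, 1)), c(0.5, 0.5))
  p <- minmax_normalize(runif(10))
  expect_equal(fuse_profiles(p, p), p)
  expect_equal(fuse_profiles(c(0, 0.5, 1), c(1, 0.5, 0)), rep(0.5, 3))
  expect_error(fuse_profiles(1:3, 1:4), "equal length")
})

test_that("peak times use the earliest-index tie rule", {
  expect_identical(peak_time(c(0.1, 0.9, 0.3)), 1L)
  expect_identical(peak_time(rep(0.5, 3)), 0L)
  expect_identical(peak_time(c(0, 0.5, 1)), 2L)
  expect_error(peak_time(numeric(0)), "empty")
})

test_that("peak-interval histograms partition the samples", {
  h <- peak_interval_histogram(0:4, T = 50)
  expect_equal(h$counts, c(5, rep(0, 9)))
  h2 <- peak_interval_histogram(c(0L, 49L), T = 50)
  expect_equal(h2$counts[c(1, 10)], c(1, 1))
  expect_equal(sum(h2$counts), 2)
  set.seed(8)
  ts <- sample(0:49, 37, replace = TRUE)
  lab <- sample(c("normal", "frost_damaged"), 37, replace = TRUE)
  h3 <- peak_interval_histogram(ts, T = 50, labels = lab)
  expect_equal(sum(h3$counts), 37)
  expect_equal(colSums(h3$per_class), h3$counts, ignore_attr = TRUE)
  expect_error(peak_interval_histogram(integer(0), T = 50), "empty")
  expect_error(peak_interval_histogram(c(1L, 50L), T = 50), "T-1")
})

test_that("the pipeline matches an independent brute-force oracle", {
  # naive re-implementation with explicit loops, kept deliberately separate
  # from the package's matrix formulation
  naive <- function(head_maps, L = 1) {
    H <- length(head_maps)
    T <- nrow(head_maps[[1]])
    ab <- matrix(0, T, T)
    for (i in 1:T) for (j in 1:T) {
      acc <- 0
      for (h in 1:H) acc <- acc + head_maps[[h]][i, j]
      ab[i, j] <- acc / H
    }
    at <- matrix(0, T, T)
    for (i in 1:T) {
      rs <- 0
      for (j in 1:T) rs <- rs + ab[i, j] + (i == j)
      for (j in 1:T) at[i, j] <- (ab[i, j] + (i == j)) / rs
    }
    R <- diag(T)
    for (l in seq_len(L)) {
      Rn <- matrix(0, T, T)
      for (i in 1:T) for (j in 1:T) {
        acc <- 0
        for (k in 1:T) acc <- acc + R[i, k] * at[k, j]
        Rn[i, j] <- acc
      }
      R <- Rn
    }
    s <- numeric(T)
    for (j in 1:T) {
      acc <- 0
      for (i in 1:T) acc <- acc + R[i, j]
      s[j] <- acc / T
    }
    list(A_bar = ab, A_tilde = at, R = R, s = s)
  }
  set.seed(12)
  for (T in 2:6) {
    maps <- list(random_row_stochastic(T), random_row_stochastic(T))
    ref <- naive(maps)
    A_bar <- average_heads(maps)
    A_tilde <- residual_adjust(A_bar)
    R <- attention_rollout(A_tilde)
    s <- temporal_score(R)
    expect_lt(max(abs(A_bar - ref$A_bar)), 1e-9)
    expect_lt(max(abs(A_tilde - ref$A_tilde)), 1e-9)
    expect_lt(max(abs(R - ref$R)), 1e-9)
    expect_lt(max(abs(s - ref$s)), 1e-9)
    expect_lt(abs(sum(s) - 1), 1e-9)
    # multi-layer rollout against the same oracle
    ref3 <- naive(maps, L = 3)
    expect_lt(max(abs(attention_rollout(list(A_tilde, A_tilde, A_tilde)) -
                        ref3$R)), 1e-9)
  }
})

test_that("dataset attribution conserves scores and honours the tie rule", {
  inputs <- tiny_inputs(n_per_class = 2, seed = 37)
  set.seed(14)
  model <- as_untrained_fit(build_model("fusion"))
  res <- attribute_dataset(model, inputs)
  expect_length(res$profiles, 4L)
  for (pr in res$profiles) {
    expect_lt(abs(sum(pr$s_p) - 1), 1e-6)
    expect_lt(abs(sum(pr$s_v) - 1), 1e-6)
    expect_true(all(pr$s_hat_fused >= 0 & pr$s_hat_fused <= 1))
    expect_true(pr$t_star >= 0 && pr$t_star <= 49)
  }
  expect_equal(sum(res$histogram$counts), 4)

  # zero projections -> uniform attention -> constant profiles -> t* = 0
  zero <- model
  for (nm in grep("_(Wq|Wk|bq|bk)$", names(zero$params), value = TRUE))
    zero$params[[nm]][] <- 0
  rz <- attribute_dataset(zero, inputs)
  expect_true(all(rz$t_star == 0L))
  expect_equal(rz$histogram$counts[1], 4)
  expect_true(all(abs(rz$fused) < 1e-6))
})
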