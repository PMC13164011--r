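test_that("the sinusoidal positional encoding follows its closed form", {
  pe <- positional_encoding(50L, 36L)
  expect_identical(dim(pe), c(50L, 36L))
  expect_true(all(pe >= -1 & pe <= 1))
  # t = 0: sine columns 0, cosine columns 1
  expect_equal(pe[1, seq(1, 35, by = 2)], rep(0, 18))
  expect_equal(pe[1, seq(2, 36, by = 2)], rep(1, 18))
  # width 1: a single sine column sin(t)
  expect_equal(as.vector(positional_encoding(50L, 1L)), sin(0:49))
  # interior value matches the formula directly
  expect_equal(pe[8, 5], sin(7 / 10000^(4 / 36)))
})

test_that("attention maps are row-stochastic and inference is deterministic", {
  set.seed(3)
  model <- build_model("fusion")
  inputs <- tiny_inputs(n_per_class = 1, seed = 23)
  maps <- extract_attention_maps(model, inputs[[1]])
  expect_named(maps, c("pressure", "vibration"))
  expect_length(maps$pressure, 2L)
  expect_length(maps$vibration, 2L)
  for (br in maps) for (A in br) {
    expect_identical(dim(A), c(50L, 50L))
    expect_true(all(A >= 0))
    expect_lt(max(abs(rowSums(A) - 1)), 1e-5)
  }
  expect_identical(maps, extract_attention_maps(model, inputs[[1]]))

  fit <- as_untrained_fit(model)
  p1 <- predict(fit, inputs)
  p2 <- predict(fit, inputs)
  expect_identical(p1, p2)  # dropout disabled at inference
})

test_that("zero projections give uniform attention over time steps", {
  set.seed(4)
  model <- build_model("fusion")
  for (nm in grep("_(Wq|Wk|bq|bk)$", names(model$params), value = TRUE))
    model$params[[nm]][] <- 0
  inp <- tiny_inputs(n_per_class = 1, seed = 29)[[1]]
  maps <- extract_attention_maps(model, inp)
  for (br in maps) for (A in br)
    expect_equal(A, matrix(1 / 50, 50, 50), tolerance = 1e-12)
})

test_that("classifier outputs are valid 2-class distributions", {
  set.seed(5)
  inputs <- tiny_inputs(n_per_class = 2, seed = 23)
  for (kind in c("fusion", "pressure_only", "vibration_only",
                 "rnn", "cnn", "lstm")) {
    model <- build_model(kind)
    fit <- as_untrained_fit(model)
    probs <- predict(fit, inputs)
    expect_identical(dim(probs), c(4L, 2L))
    expect_true(all(probs >= 0))
    expect_lt(max(abs(rowSums(probs) - 1)), 1e-6)
  }
})

test_that("model construction is seeded and validates its inputs", {
  mk <- function(seed) {
    set.seed(seed)
    build_model("fusion")$params
  }
  expect_identical(mk(9), mk(9))
  expect_false(identical(mk(9)$W1, mk(10)$W1))
  expect_error(build_model("perceptron"))

  set.seed(6)
  model <- build_model("vibration_only")
  fit <- as_untrained_fit(model)
  bad <- tiny_inputs(n_per_class = 1, seed = 23)[[1]]
  bad$vibration_seq <- cbind(bad$vibration_seq, bad$vibration_seq)
  expect_error(predict(fit, list(bad)), "50x1")
})

test_that("analytic gradients agree with finite differences", {
  cfg <- tiny_net()
  for (kind in c("fusion", "pressure_only", "vibration_only",
                 "rnn", "cnn", "lstm")) {
    set.seed(11)
    params <- build_model(kind, cfg)$params
    batch <- random_batch(cfg)
    lossfun <- function(p) {
      fw <- graspfusion:::.nn_forward(kind, p, cfg, batch$Xp, batch$Xv,
                                      batch$B, train = TRUE)
      -mean(log(rowSums(fw$probs * batch$Y) + 1e-12))
    }
    fw <- graspfusion:::.nn_forward(kind, params, cfg, batch$Xp, batch$Xv,
                                    batch$B, train = TRUE)
    dlogits <- (fw$probs - batch$Y) / batch$B
    grads <- graspfusion:::.nn_backward(dlogits, fw$cache, kind, params, cfg,
                                        batch$B)
    for (nm in names(params)) {
      idx <- seq_along(params[[nm]])
      if (length(idx) > 3) idx <- sort(sample(idx, 3))
      for (i in idx) {
        eps <- 1e-6
        p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
        fd <- (lossfun(p1) - lossfun(p2)) / (2 * eps)
        expect_lt(abs(fd - grads[[nm]][i]) /
                    max(1e-4, abs(fd), abs(grads[[nm]][i])), 1e-3)
      }
    }
  }
})

test_that("one optimizer step on a fixed batch decreases the loss", {
  cfg <- network_config(dropout_rate = 0)   # deterministic loss surface
  inputs <- toy_inputs(n_per_class = 4)
  S <- graspfusion:::.stack_inputs(inputs, cfg)
  B <- length(inputs)
  loss_of <- function(params) {
    fw <- graspfusion:::.nn_forward("fusion", params, cfg, S$P, S$V, B)
    -mean(log(rowSums(fw$probs * S$Y) + 1e-12))
  }
  for (seed in 1:3) {
    set.seed(seed)
    params <- build_model("fusion", cfg)$params
    l0 <- loss_of(params)
    fw <- graspfusion:::.nn_forward("fusion", params, cfg, S$P, S$V, B,
                                    train = TRUE)
    dlogits <- (fw$probs - S$Y) / B
    grads <- graspfusion:::.nn_backward(dlogits, fw$cache, "fusion", params,
                                        cfg, B)
    upd <- graspfusion:::.adam_step(params, grads,
                                    graspfusion:::.adam_init(params), 0.001)
    expect_lt(loss_of(upd$params), l0)
  }
})

test_that("the fusion model can memorise a 20-sample training set", {
  inputs <- tiny_inputs(n_per_class = 10, seed = 2)
  fit <- graspnet(inputs, kind = "fusion",
                  training = training_config(max_epochs = 300, patience = 25))
  acc <- mean(predict(fit, inputs, type = "class") == input_labels(inputs))
  expect_gte(acc, 0.99)
  expect_lte(nrow(fit$history), 300L)
})
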