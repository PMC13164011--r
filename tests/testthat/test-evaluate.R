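test_that("the 7:2:1 stratified split yields exact subset arithmetic", {
  labels <- rep(c("normal", "frost_damaged"), each = 120)
  plan <- stratified_split(labels, seed = 1)
  expect_length(plan$train, 168L)
  expect_length(plan$val, 48L)
  expect_length(plan$test, 24L)
  for (sub in list(plan$train, plan$val, plan$test)) {
    tab <- table(labels[sub])
    expect_equal(unname(tab)[1], unname(tab)[2])  # perfectly stratified
  }
  expect_equal(unname(table(labels[plan$train]))[1], 84L)
  expect_equal(unname(table(labels[plan$val]))[1], 24L)
  expect_equal(unname(table(labels[plan$test]))[1], 12L)

  all_idx <- sort(c(plan$train, plan$val, plan$test))
  expect_identical(all_idx, seq_along(labels))        # exhaustive + disjoint

  expect_identical(stratified_split(labels, seed = 5),
                   stratified_split(labels, seed = 5))
  tests <- lapply(1:10, function(s) stratified_split(labels, seed = s)$test)
  expect_gt(length(unique(tests)), 1L)

  expect_error(stratified_split(labels, ratios = c(0.6, 0.2, 0.1)), "sum")
  expect_error(stratified_split(rep(c("a", "b"), c(5, 50))), "at least 10")
})

test_that("uneven class sizes are allocated by largest remainder", {
  labels <- rep(c("normal", "frost_damaged"), c(23, 31))
  plan <- stratified_split(labels, seed = 3)
  for (cl in c("normal", "frost_damaged")) {
    n_c <- sum(labels == cl)
    got <- vapply(list(plan$train, plan$val, plan$test),
                  function(s) sum(labels[s] == cl), 0L)
    expect_equal(sum(got), n_c)
    expect_true(all(abs(got - n_c * c(0.7, 0.2, 0.1)) < 1))
  }
})

test_that("confusion-matrix metrics reproduce hand-computed values", {
  cm <- matrix(c(10, 2, 1, 11), 2, 2,
               dimnames = list(c("normal", "frost_damaged"),
                               c("normal", "frost_damaged")))
  m <- compute_metrics(cm)
  expect_equal(m$per_class$precision[1], 0.8333, tolerance = 1e-4)
  expect_equal(m$per_class$recall[1], 0.9091, tolerance = 1e-4)
  expect_equal(m$per_class$f1[1], 0.8696, tolerance = 1e-4)
  expect_equal(m$accuracy, 0.875)

  md <- compute_metrics(diag(c(7, 9)))
  expect_true(all(unlist(md$per_class[, -1]) == 1))
  expect_equal(md$accuracy, 1)

  ms <- compute_metrics(matrix(6, 2, 2))
  expect_equal(ms$accuracy, 0.5)
  expect_equal(ms$per_class$f1, c(0.5, 0.5))

  expect_error(compute_metrics(matrix(0, 2, 2)), "positive total")
  expect_warning(mz <- compute_metrics(matrix(c(5, 5, 0, 0), 2, 2)),
                 "zero denominator")
  expect_true(mz$zero_denominator)
  expect_equal(mz$per_class$precision[2], 0)
})

test_that("training runs early-stop, restore the best checkpoint and separate a toy problem", {
  inputs <- toy_inputs(n_per_class = 12)
  plan <- stratified_split(input_labels(inputs), seed = 2)
  tcfg <- training_config(max_epochs = 80, patience = 15)
  run <- train_run("fusion", inputs, plan, tcfg = tcfg)

  expect_lte(nrow(run$history), 80L)
  expect_lt(run$best_epoch, nrow(run$history) + 1L)
  # restored parameters reproduce the recorded best validation loss
  expect_lt(abs(evaluate_loss(run$model, inputs[plan$val]) -
                  run$best_val_loss), 1e-6)
  # constant-signal classes are perfectly separable
  expect_equal(run$metrics$test$accuracy, 1)
  # confusion marginals equal subset class counts
  for (nm in c("train", "val", "test"))
    expect_equal(unname(rowSums(run$confusion[[nm]])),
                 as.vector(table(factor(input_labels(inputs)[plan[[nm]]],
                                        c("normal", "frost_damaged")))))
  plan_empty <- plan
  plan_empty$test <- integer(0)
  expect_error(train_run("fusion", inputs, plan_empty, tcfg), "empty subset")
})

test_that("aggregation reproduces closed-form mean and sample SD", {
  mk_run <- function(cm, seed) {
    m <- compute_metrics(cm)
    structure(list(seed = seed, kind = "fusion",
                   metrics = list(test = m)), class = "run_result")
  }
  runs <- list(mk_run(matrix(c(4, 1, 1, 4), 2), 1),   # accuracy 0.8
               mk_run(diag(c(5, 5)), 2))              # accuracy 1.0
  agg <- aggregate_runs(runs)
  acc <- agg[agg$metric == "accuracy", ]
  expect_equal(acc$mean, 0.9)
  expect_equal(acc$sd, 0.1414214, tolerance = 1e-6)

  runs_const <- list(mk_run(matrix(c(9, 1, 1, 9), 2), 1),
                     mk_run(matrix(c(9, 1, 1, 9), 2), 2))
  agg_const <- aggregate_runs(runs_const)
  expect_equal(agg_const$sd[agg_const$metric == "accuracy"], 0)
  expect_equal(agg_const$mean[agg_const$metric == "accuracy"], 0.9)
})

test_that("the repeated protocol covers every kind and subset and is recomputable", {
  inputs <- toy_inputs(n_per_class = 12)
  report <- repeat_protocol(c("fusion", "cnn"), inputs, n_repeats = 2,
                            base_seed = 4, tcfg = quick_training())
  tab <- report$table
  expect_setequal(unique(tab$kind), c("fusion", "cnn"))
  expect_setequal(unique(tab$subset), c("train", "val", "test"))
  expect_setequal(unique(tab$metric), c("accuracy", "precision", "recall", "f1"))
  expect_true(all(tab$sd >= 0))
  # independent recomputation from the stored runs matches exactly
  expect_identical(aggregate_runs(report$runs), tab)
  # per-seed fairness: same split plan for every kind
  plans <- lapply(report$runs, function(r) r$plan)
  expect_identical(plans[[1]], plans[[2]])

  expect_error(repeat_protocol("fusion", inputs, n_repeats = 1), "n_repeats")
})
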