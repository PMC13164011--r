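# Repeated stratified-split training and evaluation protocol.
#
# Each repeat draws a fresh 7:2:1 stratified train/validation/test split,
# trains every requested model kind on identical subsets, and records
# per-subset confusion matrices and metrics; results over repeats are
# aggregated as mean and sample standard deviation.

#' Stratified train/validation/test split
#'
#' Per-class shuffled assignment at the given ratios using floor allocation
#' with largest-remainder top-up (ties resolved in subset order), so subset
#' class proportions match the global balance exactly when divisible and
#' within one sample otherwise. Deterministic for a given seed.
#'
#' @param labels Character vector of class labels (>= 10 per class).
#' @param ratios Train/validation/test proportions summing to 1.
#' @param seed Integer seed.
#' @return An object of class `split_plan` with disjoint, exhaustive
#'   `train`, `val` and `test` index vectors.
#' @export
stratified_split <- function(labels, ratios = c(0.7, 0.2, 0.1), seed = 1L) {
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-8)
    stop("ratios must be three proportions summing to 1", call. = FALSE)
  tab <- table(labels)
  if (any(tab < 10L))
    stop("need at least 10 samples per class", call. = FALSE)
  sets <- list(train = integer(0), val = integer(0), test = integer(0))
  local_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      n_c <- length(idx)
      q <- n_c * ratios
      counts <- floor(q)
      rem <- q - counts
      leftover <- n_c - sum(counts)
      if (leftover > 0) {
        top <- order(-rem, seq_along(rem))[seq_len(leftover)]
        counts[top] <- counts[top] + 1L
      }
      bounds <- cumsum(c(0L, counts))
      for (j in 1:3)
        sets[[j]] <- c(sets[[j]], idx[seq.int(bounds[j] + 1L,
                                              length.out = counts[j])])
    }
  })
  structure(list(seed = as.integer(seed), train = sort(sets$train),
                 val = sort(sets$val), test = sort(sets$test),
                 ratios = ratios), class = "split_plan")
}

#' Classification metrics from a 2x2 confusion matrix
#'
#' Rows are true classes, columns predicted classes. Precision, recall and
#' F1 are computed one-vs-rest per class; zero-denominator cases return 0
#' and raise the `zero_denominator` flag with a warning.
#'
#' @param confusion 2x2 non-negative count matrix.
#' @return List with `per_class` (data frame of precision/recall/F1),
#'   `accuracy` and `zero_denominator`.
#' @export
compute_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0) || sum(confusion) == 0)
    stop("confusion matrix must be non-negative with positive total",
         call. = FALSE)
  k <- nrow(confusion)
  classes <- rownames(confusion) %||% class_levels()[seq_len(k)]
  flag <- FALSE
  safe_div <- function(a, b) {
    if (b == 0) { flag <<- TRUE; 0 } else a / b
  }
  per <- do.call(rbind, lapply(seq_len(k), function(i) {
    tp <- confusion[i, i]
    fp <- sum(confusion[-i, i])
    fn <- sum(confusion[i, -i])
    prec <- safe_div(tp, tp + fp)
    rec <- safe_div(tp, tp + fn)
    f1 <- safe_div(2 * prec * rec, prec + rec)
    data.frame(class = classes[i], precision = prec, recall = rec, f1 = f1,
               stringsAsFactors = FALSE)
  }))
  if (flag) warning("zero denominator in metric computation; returning 0")
  list(per_class = per,
       accuracy = sum(diag(confusion)) / sum(confusion),
       zero_denominator = flag)
}

.confusion_matrix <- function(truth, pred) {
  lv <- class_levels()
  as.matrix(table(factor(truth, lv), factor(pred, lv)))
}

#' Train and evaluate one model under a split plan
#'
#' Fits the requested kind on the training subset with early stopping on the
#' validation subset, restores the best-validation checkpoint, and computes
#' confusion matrices and metrics on all three subsets.
#'
#' @param kind Model kind (see [graspnet()]).
#' @param inputs A `model_input_set` covering all indices of `plan`.
#' @param plan A [stratified_split()] plan.
#' @param tcfg A [training_config()].
#' @param net A [network_config()].
#' @param seed Run seed for initialisation/shuffling/dropout (defaults to
#'   the plan's seed).
#' @return An object of class `run_result` with the fitted `model`, loss
#'   `history`, per-subset `confusion` matrices and `metrics`.
#' @export
train_run <- function(kind, inputs, plan, tcfg = training_config(),
                      net = network_config(), seed = plan$seed) {
  subsets <- list(train = plan$train, val = plan$val, test = plan$test)
  if (any(vapply(subsets, length, 0L) == 0L))
    stop("empty subset in split plan", call. = FALSE)
  fit <- graspnet(inputs[plan$train], kind = kind, val = inputs[plan$val],
                  net = net, training = tcfg, seed = seed)
  labels <- input_labels(inputs)
  confusion <- list(); metrics <- list()
  for (nm in names(subsets)) {
    idx <- subsets[[nm]]
    pred <- predict(fit, inputs[idx], type = "class")
    confusion[[nm]] <- .confusion_matrix(labels[idx], pred)
    metrics[[nm]] <- compute_metrics(confusion[[nm]])
  }
  structure(list(seed = seed, kind = kind, model = fit, plan = plan,
                 history = fit$history, best_epoch = fit$best_epoch,
                 best_val_loss = fit$best_val_loss,
                 confusion = confusion, metrics = metrics),
            class = "run_result")
}

# Long-format metric rows of one run: kind, subset, class, metric, value.
.run_metric_rows <- function(run) {
  do.call(rbind, lapply(names(run$metrics), function(sub) {
    m <- run$metrics[[sub]]
    per <- m$per_class
    long <- rbind(
      data.frame(class = "overall", metric = "accuracy", value = m$accuracy,
                 stringsAsFactors = FALSE),
      do.call(rbind, lapply(seq_len(nrow(per)), function(i)
        data.frame(class = per$class[i],
                   metric = c("precision", "recall", "f1"),
                   value = unlist(per[i, c("precision", "recall", "f1")],
                                  use.names = FALSE),
                   stringsAsFactors = FALSE))))
    cbind(data.frame(kind = run$kind, seed = run$seed, subset = sub,
                     stringsAsFactors = FALSE), long)
  }))
}

#' Aggregate stored run results into a mean +/- SD report
#'
#' @param runs List of `run_result` objects.
#' @return Data frame with one row per kind/subset/class/metric holding the
#'   arithmetic mean and sample standard deviation over runs.
#' @export
aggregate_runs <- function(runs) {
  long <- do.call(rbind, lapply(runs, .run_metric_rows))
  agg <- stats::aggregate(value ~ kind + subset + class + metric, long,
                          function(v) c(mean = mean(v), sd = stats::sd(v)))
  out <- data.frame(agg[c("kind", "subset", "class", "metric")],
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"],
                    stringsAsFactors = FALSE)
  out[order(out$kind, out$subset, out$class, out$metric), ]
}

#' Repeated stratified-split evaluation protocol
#'
#' For each of `n_repeats` seeds, draws a fresh stratified split and trains
#' every requested model kind on byte-identical subsets with a fresh
#' initialisation; per-run metrics are aggregated as arithmetic mean and
#' sample standard deviation.
#'
#' @param kinds Character vector of model kinds.
#' @param inputs A `model_input_set`.
#' @param n_repeats Number of repeated splits (>= 2, default 10).
#' @param base_seed First seed; repeat `k` uses `base_seed + k - 1`.
#' @param tcfg A [training_config()].
#' @param net A [network_config()].
#' @return An object of class `aggregate_report`: `table` (mean/SD per
#'   kind, subset, class and metric), the constituent `runs` and the seeds.
#' @export
repeat_protocol <- function(kinds, inputs, n_repeats = 10L, base_seed = 1L,
                            tcfg = training_config(), net = network_config()) {
  if (n_repeats < 2L)
    stop("n_repeats must be >= 2 (sample SD undefined otherwise)",
         call. = FALSE)
  kinds <- vapply(kinds, match.arg, "", choices = .model_kinds)
  labels <- input_labels(inputs)
  seeds <- base_seed + seq_len(n_repeats) - 1L
  runs <- list()
  for (s in seeds) {
    plan <- stratified_split(labels, seed = s)
    for (kind in kinds) {
      runs[[length(runs) + 1L]] <-
        train_run(kind, inputs, plan, tcfg = tcfg, net = net, seed = s)
    }
  }
  structure(list(table = aggregate_runs(runs), runs = runs, seeds = seeds,
                 n_repeats = as.integer(n_repeats), kinds = kinds),
            class = "aggregate_report")
}

#' @export
print.aggregate_report <- function(x, ...) {
  cat(sprintf("Repeated stratified-split report: %d repeats x %d model kind(s)\n",
              x$n_repeats, length(x$kinds)))
  acc <- x$table[x$table$metric == "accuracy" & x$table$subset == "test", ]
  for (i in seq_len(nrow(acc)))
    cat(sprintf("  %-15s test accuracy %.3f +/- %.3f\n",
                acc$kind[i], acc$mean[i], acc$sd[i]))
  invisible(x)
}
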