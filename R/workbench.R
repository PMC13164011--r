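# End-to-end workbench: simulate -> preprocess -> repeated evaluation ->
# attribution -> report, with provenance stamping and stage timing.

#' Workbench configuration
#'
#' Bundles the stage configurations of the full pipeline.
#'
#' @param sim A [sim_config()].
#' @param preprocess A [preprocess_config()].
#' @param net A [network_config()].
#' @param training A [training_config()].
#' @param attribution An [attribution_config()].
#' @param repeats Number of repeated stratified splits (default 10).
#' @param kinds Model kinds to evaluate.
#' @param base_seed First protocol seed.
#' @return An object of class `workbench_config`.
#' @export
workbench_config <- function(sim = sim_config(),
                             preprocess = preprocess_config(),
                             net = network_config(),
                             training = training_config(),
                             attribution = attribution_config(),
                             repeats = 10L,
                             kinds = c("fusion", "pressure_only",
                                       "vibration_only"),
                             base_seed = 1L) {
  stopifnot(inherits(sim, "sim_config"),
            inherits(preprocess, "preprocess_config"),
            inherits(net, "network_config"),
            inherits(training, "training_config"),
            inherits(attribution, "attribution_config"))
  structure(list(sim = sim, preprocess = preprocess, net = net,
                 training = training, attribution = attribution,
                 repeats = as.integer(repeats), kinds = kinds,
                 base_seed = as.integer(base_seed)),
            class = "workbench_config")
}

.stage <- function(name, verbose, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  if (verbose)
    message(sprintf("[%s] done in %.1f s", name,
                    proc.time()[["elapsed"]] - t0))
  res
}

# Nested kind -> subset -> class -> metric -> {mean, sd} view of the report
# table, mirroring the layout of the published summary tables.
.report_nested <- function(tab) {
  out <- list()
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    out[[r$kind]][[r$subset]][[r$class]][[r$metric]] <-
      list(mean = r$mean, sd = r$sd)
  }
  out
}

#' Run the full analysis pipeline
#'
#' Simulates a dataset, preprocesses it, runs the repeated stratified-split
#' protocol over the requested model kinds, computes attention-rollout
#' attribution on every fusion run's test subset, and writes all artifacts
#' (per-run results, aggregate report, attribution profiles and histogram)
#' stamped with the configuration hash and seeds.
#'
#' @param config A [workbench_config()].
#' @param out_dir Output directory for artifacts.
#' @param write_raw Also write the raw simulated trial CSVs.
#' @param write_inputs Also write the preprocessed model-input CSVs.
#' @param verbose Log stage timings.
#' @return Invisibly, a list with the `report` (aggregate_report), the
#'   pooled `attribution` result (or `NULL` without a fusion run), the
#'   `dataset`, `inputs` and `out_dir`.
#' @export
run_pipeline <- function(config = workbench_config(), out_dir = "runs",
                         write_raw = FALSE, write_inputs = FALSE,
                         verbose = TRUE) {
  if (!inherits(config, "workbench_config"))
    stop("`config` must be a workbench_config", call. = FALSE)
  if (config$repeats < 2L)
    stop("repeats must be >= 2 (sample SD undefined otherwise)", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  chash <- config_hash(lapply(unclass(config), unclass))

  dataset <- .stage("simulate", verbose, simulate_grasp_dataset(config$sim))
  if (write_raw)
    .stage("write_raw", verbose,
           write_grasp_dataset(dataset, file.path(out_dir, "dataset")))

  inputs <- .stage("preprocess", verbose,
                   preprocess_dataset(dataset, config$preprocess))
  if (write_inputs)
    .stage("write_inputs", verbose,
           write_model_inputs(inputs, file.path(out_dir, "inputs")))

  report <- .stage("evaluate", verbose,
                   repeat_protocol(config$kinds, inputs,
                                   n_repeats = config$repeats,
                                   base_seed = config$base_seed,
                                   tcfg = config$training, net = config$net))

  for (run in report$runs) {
    rdir <- file.path(out_dir, "runs", run$kind, sprintf("seed%d", run$seed))
    dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(
      seed = run$seed, kind = run$kind, config_hash = chash,
      n_params = run$model$n_params,
      best_epoch = run$best_epoch, best_val_loss = run$best_val_loss,
      epochs_trained = nrow(run$history), history = run$history,
      confusion = lapply(run$confusion, function(m)
        list(counts = unclass(m), rows = "true", cols = "predicted")),
      metrics = lapply(run$metrics, function(m)
        list(per_class = m$per_class, accuracy = m$accuracy))),
      file.path(rdir, "result.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  attribution <- NULL
  if ("fusion" %in% config$kinds) {
    attribution <- .stage("attribute", verbose, {
      profiles <- list(); t_star <- integer(0); labels <- character(0)
      fused <- NULL
      for (run in report$runs) {
        if (run$kind != "fusion") next
        res <- attribute_dataset(run$model, inputs[run$plan$test],
                                 config$attribution)
        profiles <- c(profiles, res$profiles)
        t_star <- c(t_star, res$t_star)
        labels <- c(labels, res$labels)
        fused <- rbind(fused, res$fused)
      }
      hist <- peak_interval_histogram(t_star, config$attribution,
                                      T = config$net$T, labels = labels)
      list(profiles = profiles, fused = fused, t_star = t_star,
           labels = labels, histogram = hist)
    })
    adir <- file.path(out_dir, "attributions")
    dir.create(adir, recursive = TRUE, showWarnings = FALSE)
    prof_df <- data.frame(sample_id = rownames(attribution$fused),
                          label = attribution$labels,
                          t_star = attribution$t_star,
                          attribution$fused, check.names = FALSE,
                          row.names = NULL)
    colnames(prof_df)[-(1:3)] <- sprintf("s%02d", seq_len(config$net$T) - 1L)
    utils::write.csv(prof_df, file.path(adir, "profiles.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(
      config_hash = chash, edges = attribution$histogram$edges,
      width = attribution$histogram$width,
      counts = attribution$histogram$counts,
      per_class = apply(attribution$histogram$per_class %||% matrix(0, 0, 0),
                        1L, identity, simplify = FALSE)),
      file.path(adir, "histogram.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  jsonlite::write_json(list(
    config_hash = chash, seeds = report$seeds, kinds = config$kinds,
    repeats = config$repeats, report = .report_nested(report$table)),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(report = report, attribution = attribution,
                 dataset = dataset, inputs = inputs, out_dir = out_dir))
}
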