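# Plain-text dataset interchange: per-trial CSVs plus a JSON manifest.
#
# CSV dialect: comma-separated, UTF-8, '.' decimal, mandatory header row.
# Timestamps are written with fixed 9-decimal precision so that a
# write -> read -> write cycle reproduces byte-identical files.

.fmt_ts <- function(x) sprintf("%.9f", x)

#' Write a grasp dataset to disk
#'
#' Writes `<trial_id>_pressure.csv` (`timestamp_s,p00,...,p55`, row-major
#' 6x6 channels), `<trial_id>_vibration.csv` (`timestamp_s,v`) and a
#' `manifest.json` listing every trial's files, label, fruit profile and
#' contact onset together with the echoed configuration and its hash.
#'
#' @param dataset A `grasp_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_grasp_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trial_entries <- lapply(dataset$trials, function(tr) {
    pfile <- paste0(tr$trial_id, "_pressure.csv")
    vfile <- paste0(tr$trial_id, "_vibration.csv")
    pdf <- data.frame(timestamp_s = .fmt_ts(tr$pressure$timestamp_s),
                      tr$pressure$counts, check.names = FALSE)
    utils::write.csv(pdf, file.path(dir, pfile), row.names = FALSE,
                     quote = FALSE)
    vdf <- data.frame(timestamp_s = .fmt_ts(tr$vibration$timestamp_s),
                      v = tr$vibration$counts)
    utils::write.csv(vdf, file.path(dir, vfile), row.names = FALSE,
                     quote = FALSE)
    fruit <- unclass(tr$fruit)
    list(trial_id = tr$trial_id, label = tr$fruit$label,
         pressure_file = pfile, vibration_file = vfile,
         contact_onset_s = tr$contact_onset_s, fruit = fruit)
  })
  cfg <- unclass(dataset$config)
  manifest <- list(config = cfg, config_hash = config_hash(cfg),
                   n_trials = length(dataset$trials), trials = trial_entries)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a grasp dataset from disk
#'
#' @param dir Directory written by [write_grasp_dataset()] (or real
#'   recordings in the same layout).
#' @return A `grasp_dataset`.
#' @export
read_grasp_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("missing manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  config <- do.call(sim_config, manifest$config)
  trials <- lapply(manifest$trials, function(e) {
    pdf <- utils::read.csv(file.path(dir, e$pressure_file), check.names = FALSE)
    vdf <- utils::read.csv(file.path(dir, e$vibration_file))
    counts <- as.matrix(pdf[, -1, drop = FALSE])
    storage.mode(counts) <- "integer"
    fruit <- e$fruit
    fruit$footprint_center <- unlist(fruit$footprint_center)
    structure(list(
      trial_id = e$trial_id,
      fruit = structure(fruit, class = "fruit_profile"),
      pressure = list(timestamp_s = pdf$timestamp_s, counts = counts),
      vibration = list(timestamp_s = vdf$timestamp_s,
                       counts = as.integer(vdf$v)),
      contact_onset_s = e$contact_onset_s,
      metadata = list()), class = "grasp_trial")
  })
  manifest_df <- data.frame(
    trial_id = vapply(manifest$trials, `[[`, "", "trial_id"),
    label = vapply(manifest$trials, `[[`, "", "label"),
    stringsAsFactors = FALSE)
  structure(list(trials = trials, manifest = manifest_df, config = config),
            class = "grasp_dataset")
}

#' Validate an on-disk grasp dataset
#'
#' Checks, per trial: file presence, CSV schemas (`timestamp_s,p00..p55`
#' and `timestamp_s,v`), integer counts within `[0, adc_max]`, and strictly
#' increasing timestamps; plus manifest/file consistency.
#'
#' @param dir Dataset directory.
#' @return Data frame with one row per trial (`trial_id`, `pass`, `issues`).
#' @export
validate_grasp_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("missing manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  adc_max <- manifest$config$adc_max %||% 1023L
  gi <- rep(0:5, each = 6); gj <- rep(0:5, times = 6)
  p_header <- c("timestamp_s", sprintf("p%d%d", gi, gj))
  rows <- lapply(manifest$trials, function(e) {
    issues <- character(0)
    pfile <- file.path(dir, e$pressure_file)
    vfile <- file.path(dir, e$vibration_file)
    if (!file.exists(pfile) || !file.exists(vfile)) {
      issues <- c(issues, "missing file")
    } else {
      pdf <- utils::read.csv(pfile, check.names = FALSE)
      vdf <- utils::read.csv(vfile)
      if (!identical(colnames(pdf), p_header))
        issues <- c(issues, "pressure header mismatch")
      if (!identical(colnames(vdf), c("timestamp_s", "v")))
        issues <- c(issues, "vibration header mismatch")
      counts <- as.matrix(pdf[, -1, drop = FALSE])
      if (any(counts < 0 | counts > adc_max) || any(counts != round(counts)))
        issues <- c(issues, "pressure counts out of ADC range")
      if (any(vdf$v < 0 | vdf$v > adc_max) || any(vdf$v != round(vdf$v)))
        issues <- c(issues, "vibration counts out of ADC range")
      if (any(diff(pdf$timestamp_s) <= 0))
        issues <- c(issues, "pressure timestamps not strictly increasing")
      if (any(diff(vdf$timestamp_s) <= 0))
        issues <- c(issues, "vibration timestamps not strictly increasing")
    }
    data.frame(trial_id = e$trial_id, pass = length(issues) == 0L,
               issues = paste(issues, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write preprocessed model inputs to disk
#'
#' One `<trial_id>_input.csv` per sample (50 rows, columns `f00..f35` then
#' `v`) plus `inputs_manifest.json` with labels and the preprocessing
#' configuration echo.
#'
#' @param inputs A `model_input_set`.
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_model_inputs <- function(inputs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(inputs, function(x) {
    file <- paste0(x$trial_id, "_input.csv")
    df <- data.frame(x$pressure_seq, v = as.vector(x$vibration_seq),
                     check.names = FALSE)
    utils::write.csv(df, file.path(dir, file), row.names = FALSE, quote = FALSE)
    list(trial_id = x$trial_id, label = x$label, file = file)
  })
  cfg <- unclass(attr(inputs, "config") %||% preprocess_config())
  manifest <- list(preprocess_config = cfg, config_hash = config_hash(cfg),
                   n_inputs = length(inputs), inputs = entries)
  path <- file.path(dir, "inputs_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read preprocessed model inputs from disk
#' @param dir Directory written by [write_model_inputs()].
#' @return A `model_input_set`.
#' @export
read_model_inputs <- function(dir) {
  mpath <- file.path(dir, "inputs_manifest.json")
  if (!file.exists(mpath)) stop("missing inputs_manifest.json", call. = FALSE)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  inputs <- lapply(manifest$inputs, function(e) {
    df <- utils::read.csv(file.path(dir, e$file), check.names = FALSE)
    pres <- as.matrix(df[, colnames(df) != "v", drop = FALSE])
    vib <- matrix(df$v, ncol = 1L, dimnames = list(NULL, "v"))
    structure(list(pressure_seq = pres, vibration_seq = vib,
                   label = e$label,
                   label_onehot = as.integer(class_levels() == e$label),
                   trial_id = e$trial_id), class = "model_input")
  })
  cfg <- do.call(preprocess_config, manifest$preprocess_config)
  structure(inputs, class = "model_input_set", config = cfg)
}
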