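#' Pipeline configuration
#'
#' A single nested list collects every tunable parameter of the chain:
#' artifact-filter window and threshold, detrending strength, QC gates,
#' entropy and spectral settings, classifier hyper-parameters and the
#' run seed. [write_config()] / [read_config()] serialise it as YAML so
#' an unattended batch run is fully described by one file;
#' [validate_config()] checks every value against the preconditions of
#' the module that consumes it.
#'
#' @return `default_config()` returns the default configuration list
#'   with sections `preprocess`, `features`, `model` and a top-level
#'   `seed`.
#' @export
default_config <- function() {
  list(
    preprocess = list(
      window_beats = 11L,          # artifact filter: running-median window
      rel_threshold = 0.2,         # relative deviation flagged as artifact
      detrend_lambda = 300,        # smoothness-priors regularisation
      min_duration_s = 300L,       # QC: minimum record length
      max_artifact_fraction = 0.05 # QC: max corrected-beat fraction
    ),
    features = list(
      entropy_m = 2L,              # ApEn/SampEn template length
      entropy_r = 0.2,             # tolerance as fraction of SD
      binen_m = 2L,                # BinEn word length
      copula = "clayton",
      welch_seg_s = 256L           # Welch segment length, seconds
    ),
    model = list(
      kind = "rf",
      n_trees = 500L,
      criterion = "gini",
      hidden_units = 16L,
      epochs = 500L,
      train_fraction = 0.7,
      stratified = TRUE,
      threshold = 0.5,
      warn_band = c(0.3, 0.5)
    ),
    seed = 1L
  )
}

#' @rdname default_config
#' @param config a configuration list.
#' @param path file path for the YAML document.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  config <- yaml::read_yaml(path)
  validate_config(config)
  config
}

#' @rdname default_config
#' @export
validate_config <- function(config) {
  need <- function(cond, msg) if (!isTRUE(cond)) stop("invalid config: ",
                                                      msg, call. = FALSE)
  pp <- config$preprocess; fe <- config$features; md <- config$model
  need(is.list(pp) && is.list(fe) && is.list(md),
       "sections preprocess/features/model required")
  need(pp$window_beats >= 3, "preprocess$window_beats must be >= 3")
  need(pp$rel_threshold > 0, "preprocess$rel_threshold must be positive")
  need(pp$detrend_lambda >= 0, "preprocess$detrend_lambda must be >= 0")
  need(pp$min_duration_s > 0, "preprocess$min_duration_s must be positive")
  need(pp$max_artifact_fraction >= 0 && pp$max_artifact_fraction <= 1,
       "preprocess$max_artifact_fraction must lie in [0, 1]")
  need(fe$entropy_m >= 1, "features$entropy_m must be >= 1")
  need(fe$entropy_r > 0, "features$entropy_r must be positive")
  need(fe$binen_m >= 1, "features$binen_m must be >= 1")
  need(fe$welch_seg_s >= 4, "features$welch_seg_s must be >= 4")
  need(md$kind %in% c("rf", "mlp"), "model$kind must be 'rf' or 'mlp'")
  need(md$n_trees >= 1, "model$n_trees must be >= 1")
  need(md$criterion %in% c("gini", "entropy"),
       "model$criterion must be 'gini' or 'entropy'")
  need(md$hidden_units >= 1, "model$hidden_units must be >= 1")
  need(md$epochs >= 1, "model$epochs must be >= 1")
  need(md$train_fraction > 0 && md$train_fraction < 1,
       "model$train_fraction must lie in (0, 1)")
  need(md$threshold > 0 && md$threshold < 1,
       "model$threshold must lie in (0, 1)")
  need(is.numeric(config$seed), "top-level seed required")
  invisible(config)
}

#' Run the full processing pipeline on a directory of RR records
#'
#' Reads every record (via `manifest.csv` if present, else all `*.txt`
#' files), applies the artifact filter and quality control, extracts
#' features from the accepted records and, depending on the mode,
#' trains and evaluates a classifier (`train = TRUE`) or computes the
#' per-record hypertension probability feedback with a supplied model.
#' Every discarded or unreadable record is logged with its reason; the
#' run is deterministic under a fixed configuration.
#'
#' @param input_dir directory of plain-text RR records (format of
#'   [write_rr()]).
#' @param config pipeline configuration, see [default_config()].
#' @param model optional fitted `hrv_classifier` used for feedback.
#' @param train train and evaluate a classifier on the extracted
#'   features (requires labelled records).
#' @param quiet suppress per-record log lines.
#' @return List with `features` (data.frame), `log` (one row per input
#'   record: file, status `accepted`/`discarded`/`error`, reason),
#'   `counts`, and, depending on mode, `model`/`report` or `feedback`.
#' @export
run_pipeline <- function(input_dir, config = default_config(), model = NULL,
                         train = FALSE, quiet = FALSE) {
  validate_config(config)
  manifest_path <- file.path(input_dir, "manifest.csv")
  if (file.exists(manifest_path)) {
    manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
    files <- file.path(input_dir, manifest$path)
  } else {
    manifest <- NULL
    files <- list.files(input_dir, pattern = "\\.(txt|rr)$",
                        full.names = TRUE)
  }
  if (length(files) == 0) stop("no input records in ", input_dir,
                               call. = FALSE)
  pp <- config$preprocess
  say <- function(...) if (!quiet) message(...)

  rows <- list(); log <- list()
  for (i in seq_along(files)) {
    f <- files[i]
    status <- "accepted"; reason <- "none"
    res <- tryCatch({
      r <- read_rr(f)
      if (!is.null(manifest)) {
        r$meta$subject_id <- manifest$subject_id[i]
        r$meta$group <- manifest$label[i]
        r$meta$age <- manifest$age[i]
        r$meta$activity <- manifest$activity[i]
      }
      nn <- filter_artifacts(r, pp$window_beats, pp$rel_threshold)
      qc <- quality_control(nn, pp$min_duration_s, pp$max_artifact_fraction)
      if (!qc$accepted) {
        status <- "discarded"; reason <- qc$reject_reason
        NULL
      } else {
        fv <- extract_features(nn, config = config, check_qc = FALSE)
        cbind(data.frame(
          subject_id = r$meta$subject_id %||% basename(f),
          label = r$meta$group %||% NA_character_,
          activity = r$meta$activity %||% NA_character_,
          stringsAsFactors = FALSE), fv)
      }
    }, error = function(e) {
      status <<- "error"; reason <<- conditionMessage(e)
      NULL
    })
    log[[i]] <- data.frame(file = basename(f), status = status,
                           reason = reason, stringsAsFactors = FALSE)
    say(sprintf("[%s] %s%s", status, basename(f),
                if (reason == "none") "" else paste0(": ", reason)))
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  log <- do.call(rbind, log)
  counts <- c(input = nrow(log),
              accepted = sum(log$status == "accepted"),
              discarded = sum(log$status == "discarded"),
              errored = sum(log$status == "error"))
  if (counts["accepted"] == 0) {
    stop("no record passed quality control (",
         counts["discarded"], " discarded, ", counts["errored"],
         " unreadable)", call. = FALSE)
  }
  features <- do.call(rbind, rows)
  rownames(features) <- NULL
  out <- list(features = features, log = log, counts = counts)

  md <- config$model
  if (isTRUE(train)) {
    sp <- split_cohort(features, md$train_fraction, md$stratified,
                       seed = config$seed)
    fitted <- if (md$kind == "rf") {
      train_rf(sp$train, n_trees = md$n_trees, criterion = md$criterion,
               seed = config$seed)
    } else {
      train_mlp(sp$train, hidden_units = md$hidden_units,
                epochs = md$epochs, seed = config$seed)
    }
    out$model <- fitted
    out$report <- evaluate_model(fitted, sp$test, threshold = md$threshold)
  } else if (!is.null(model)) {
    pr <- predict_proba(model, features)
    out$feedback <- data.frame(
      subject_id = features$subject_id,
      probability = pr,
      status = classify_feedback(pr, md$threshold, md$warn_band),
      stringsAsFactors = FALSE)
  }
  out
}
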