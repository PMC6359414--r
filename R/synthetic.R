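#' Synthetic RR-record generator configuration
#'
#' Parameters of the seeded tachogram simulator. Clean beats follow
#' \deqn{RR(t) = \mu + A_{LF}\sin(2\pi f_{LF} t) + A_{HF}\sin(2\pi f_{HF} t)
#'   + A_{tr}\sin(2\pi t / T_{tr}) + \epsilon,\quad \epsilon \sim N(0,\sigma^2)}
#' so that the simulated series carries band-limited oscillatory content in
#' the standard LF (0.04--0.15 Hz) and HF (0.15--0.4 Hz) bands plus a slow
#' drift, the components the downstream spectral features measure. A
#' fraction of beats is then replaced by detection artifacts (a single
#' interval multiplied by a factor drawn from \{0.4\} or U(2, 3)) or by
#' ectopic short--long pairs (two consecutive intervals rescaled to 0.7x
#' and 1.3x of their common mean, preserving the local sum). Every altered
#' beat is annotated in the ground-truth flags.
#'
#' @param duration_s record length in seconds (beats are generated until
#'   the cumulative time reaches it); must be positive.
#' @param mean_rr_ms mean RR interval, milliseconds; must be positive.
#' @param sd_rr_ms standard deviation of the white Gaussian beat-to-beat
#'   jitter, milliseconds.
#' @param lf_amp_ms,lf_freq_hz amplitude (ms) and frequency (Hz) of the
#'   low-frequency sinusoidal modulation; default frequency 0.1 Hz.
#' @param hf_amp_ms,hf_freq_hz amplitude and frequency of the
#'   high-frequency (respiratory) modulation; default frequency 0.25 Hz.
#' @param trend_amp_ms,trend_period_s amplitude (ms) and period (s) of the
#'   slow sinusoidal drift.
#' @param artifact_rate fraction of beats replaced by spike/drop
#'   artifacts, in `[0, 1)`.
#' @param ectopic_rate fraction of beats starting an ectopic short--long
#'   pair, in `[0, 1)`.
#' @param seed integer seed; identical configurations produce identical
#'   records.
#' @return A validated list of class `rr_gen_config`.
#' @seealso [generate_rr_record()], [group_profile()]
#' @export
rr_gen_config <- function(duration_s = 600, mean_rr_ms = 800, sd_rr_ms = 0,
                          lf_amp_ms = 0, lf_freq_hz = 0.1,
                          hf_amp_ms = 0, hf_freq_hz = 0.25,
                          trend_amp_ms = 0, trend_period_s = 300,
                          artifact_rate = 0, ectopic_rate = 0, seed = 1L) {
  cfg <- list(
    duration_s = duration_s, mean_rr_ms = mean_rr_ms, sd_rr_ms = sd_rr_ms,
    lf_amp_ms = lf_amp_ms, lf_freq_hz = lf_freq_hz,
    hf_amp_ms = hf_amp_ms, hf_freq_hz = hf_freq_hz,
    trend_amp_ms = trend_amp_ms, trend_period_s = trend_period_s,
    artifact_rate = artifact_rate, ectopic_rate = ectopic_rate,
    seed = as.integer(seed)
  )
  check_pos <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop(sprintf("invalid config field '%s': must be a positive number",
                   field), call. = FALSE)
    }
  }
  check_nonneg <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      stop(sprintf("invalid config field '%s': must be non-negative", field),
           call. = FALSE)
    }
  }
  check_rate <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0 || v >= 1) {
      stop(sprintf("invalid config field '%s': must lie in [0, 1)", field),
           call. = FALSE)
    }
  }
  for (f in c("duration_s", "mean_rr_ms", "lf_freq_hz", "hf_freq_hz",
              "trend_period_s")) check_pos(f)
  for (f in c("sd_rr_ms", "lf_amp_ms", "hf_amp_ms", "trend_amp_ms"))
    check_nonneg(f)
  for (f in c("artifact_rate", "ectopic_rate")) check_rate(f)
  if (is.na(cfg$seed)) stop("invalid config field 'seed'", call. = FALSE)
  structure(cfg, class = "rr_gen_config")
}

# clean-beat model evaluated at time t (seconds); vectorised over t
.clean_rr <- function(cfg, t) {
  cfg$mean_rr_ms +
    cfg$lf_amp_ms * sin(2 * pi * cfg$lf_freq_hz * t) +
    cfg$hf_amp_ms * sin(2 * pi * cfg$hf_freq_hz * t) +
    cfg$trend_amp_ms * sin(2 * pi * t / cfg$trend_period_s)
}

#' Generate a synthetic RR record
#'
#' Simulates one tachogram under the model described in
#' [rr_gen_config()]. Beats are laid down sequentially (each interval is
#' evaluated at the current cumulative time) until the record covers
#' `duration_s`; artifacts and ectopic pairs are then injected at the
#' configured rates and the corrupted beats flagged, giving a ground
#' truth for the artifact filter. Intervals are floored at 250 ms so
#' extreme jitter cannot produce a non-physiological beat.
#'
#' @param config an [rr_gen_config()] object.
#' @param meta optional subject metadata list merged into the record.
#' @return An [rr_series()] whose `flags` mark every injected artifact
#'   (`"artifact"`) and ectopic beat (`"ectopic"`); total duration is at
#'   least `config$duration_s`.
#' @examples
#' rr <- generate_rr_record(rr_gen_config(duration_s = 300, sd_rr_ms = 25,
#'                                        artifact_rate = 0.02, seed = 7))
#' table(rr$flags)
#' @export
generate_rr_record <- function(config, meta = list()) {
  if (!inherits(config, "rr_gen_config")) {
    config <- do.call(rr_gen_config, as.list(config))
  }
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed)

  gen_until <- function(rr, t, target) {
    repeat {
      if (t >= target - 1e-9) break   # tolerance for accumulated fp error
      v <- .clean_rr(config, t) + rnorm(1, 0, config$sd_rr_ms)
      v <- max(v, 250)
      rr[length(rr) + 1L] <- v
      t <- t + v / 1000
    }
    list(rr = rr, t = t)
  }
  g <- gen_until(numeric(0), 0, config$duration_s)
  rr <- g$rr
  n <- length(rr)
  flags <- rep("normal", n)

  if (config$artifact_rate > 0) {
    hit <- which(runif(n) < config$artifact_rate)
    for (i in hit) {
      fac <- if (runif(1) < 0.5) 0.4 else runif(1, 2, 3)
      rr[i] <- rr[i] * fac
      flags[i] <- "artifact"
    }
  }
  if (config$ectopic_rate > 0) {
    cand <- which(runif(n) < config$ectopic_rate)
    for (i in cand) {
      if (i >= n) next
      if (flags[i] != "normal" || flags[i + 1] != "normal") next
      s <- rr[i] + rr[i + 1]
      rr[i] <- 0.35 * s        # premature (0.7x of the pair mean)
      rr[i + 1] <- 0.65 * s    # compensatory (1.3x), local sum preserved
      flags[c(i, i + 1)] <- "ectopic"
    }
  }

  # injection may shorten the record; top up with clean beats if needed
  if (sum(rr) / 1000 < config$duration_s) {
    g <- gen_until(rr, sum(rr) / 1000, config$duration_s)
    rr <- g$rr
    flags <- c(flags, rep("normal", length(rr) - length(flags)))
  }

  rr_series(rr, flags, meta)
}

#' Cohort group profile
#'
#' A template [rr_gen_config()] plus between-subject dispersion for each
#' generator parameter and an age distribution, defining one simulated
#' population. [default_group_profiles()] returns the bundled
#' control-like and hypertensive-like profiles: the hypertensive profile
#' has a higher mean heart rate, markedly lower short-term variability
#' (beat jitter and respiratory modulation) and an older age
#' distribution, the qualitative contrasts reported between hypertensive
#' and control HRV.
#'
#' @param label group label, e.g. `"control"` or `"hypertensive"`.
#' @param template an [rr_gen_config()] with the population-mean
#'   parameters.
#' @param dispersion named list of between-subject standard deviations
#'   for template fields (unlisted fields do not vary across subjects).
#' @param age_mean,age_sd,age_bounds truncated-normal age distribution in
#'   years.
#' @return An object of class `group_profile`.
#' @export
group_profile <- function(label, template, dispersion = list(),
                          age_mean = 50, age_sd = 12,
                          age_bounds = c(18, 90)) {
  stopifnot(inherits(template, "rr_gen_config"),
            is.character(label), length(label) == 1,
            age_sd >= 0, length(age_bounds) == 2,
            age_bounds[1] < age_bounds[2])
  unknown <- setdiff(names(dispersion), names(template))
  if (length(unknown) > 0) {
    stop("dispersion for unknown field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(list(label = label, template = template,
                 dispersion = dispersion, age_mean = age_mean,
                 age_sd = age_sd, age_bounds = age_bounds),
            class = "group_profile")
}

#' @rdname group_profile
#' @param duration_s record length used by both bundled profiles.
#' @export
default_group_profiles <- function(duration_s = 600) {
  ctrl <- group_profile(
    "control",
    rr_gen_config(duration_s = duration_s, mean_rr_ms = 834, sd_rr_ms = 26,
                  lf_amp_ms = 40, hf_amp_ms = 15,
                  trend_amp_ms = 50, trend_period_s = 300,
                  artifact_rate = 0.02, ectopic_rate = 0.01),
    dispersion = list(mean_rr_ms = 50, sd_rr_ms = 5, lf_amp_ms = 8,
                      hf_amp_ms = 3, trend_amp_ms = 10),
    age_mean = 45, age_sd = 12
  )
  hyp <- group_profile(
    "hypertensive",
    rr_gen_config(duration_s = duration_s, mean_rr_ms = 800, sd_rr_ms = 17,
                  lf_amp_ms = 30, hf_amp_ms = 8,
                  trend_amp_ms = 40, trend_period_s = 300,
                  artifact_rate = 0.02, ectopic_rate = 0.01),
    dispersion = list(mean_rr_ms = 50, sd_rr_ms = 3.5, lf_amp_ms = 6,
                      hf_amp_ms = 1.6, trend_amp_ms = 8),
    age_mean = 58, age_sd = 10
  )
  list(control = ctrl, hypertensive = hyp)
}

# truncated-normal draw by rejection (bounds are generous, so cheap)
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- rnorm(1, mean, sd)
      if (v >= lower && v <= upper) break
    }
    out[i] <- v
  }
  out
}

#' Generate a labelled synthetic cohort
#'
#' Draws `n_per_group` subjects from each [group_profile()]: per-subject
#' generator parameters are sampled from the profile's dispersions
#' (truncated so rates stay in `[0, 1)` and scales stay positive), an age
#' is drawn from the profile's truncated-normal age distribution, and one
#' record is generated per subject with a seed derived from `seed`.
#'
#' @param profiles list of [group_profile()] objects (typically the two
#'   from [default_group_profiles()]).
#' @param n_per_group number of subjects per profile; at least 1.
#' @param seed master seed; the whole cohort is reproducible from it.
#' @param activity activity tag recorded in the metadata of every record.
#' @return List of [rr_series()] records, `n_per_group` per label, each
#'   with `meta$subject_id`, `meta$age`, `meta$group`, `meta$activity`.
#' @examples
#' coh <- generate_rr_cohort(default_group_profiles(300), n_per_group = 2,
#'                           seed = 1)
#' vapply(coh, function(r) r$meta$group, "")
#' @export
generate_rr_cohort <- function(profiles, n_per_group, seed = 1L,
                               activity = "rest") {
  stopifnot(is.list(profiles), length(profiles) >= 1)
  if (!is.numeric(n_per_group) || n_per_group < 1) {
    stop("'n_per_group' must be at least 1", call. = FALSE)
  }
  n_per_group <- as.integer(n_per_group)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  records <- list()
  sid <- 0L
  for (prof in profiles) {
    stopifnot(inherits(prof, "group_profile"))
    tmpl <- prof$template
    for (j in seq_len(n_per_group)) {
      sid <- sid + 1L
      cfg <- unclass(tmpl)
      for (field in names(prof$dispersion)) {
        s <- prof$dispersion[[field]]
        base <- tmpl[[field]]
        lower <- if (grepl("rate", field)) 0 else max(base * 0.2, 1e-6)
        upper <- if (grepl("rate", field)) 0.999 else Inf
        cfg[[field]] <- .rtruncnorm(1, base, s, lower, upper)
      }
      cfg$seed <- sample.int(.Machine$integer.max - 1L, 1)
      age <- round(.rtruncnorm(1, prof$age_mean, prof$age_sd,
                               prof$age_bounds[1], prof$age_bounds[2]))
      meta <- list(subject_id = sprintf("S%04d", sid), age = age,
                   group = prof$label, activity = activity)
      records[[sid]] <- generate_rr_record(do.call(rr_gen_config, cfg), meta)
    }
  }
  records
}

#' Write a cohort to disk
#'
#' Writes each record in the plain-text format of [write_rr()] plus a
#' `manifest.csv` (columns `subject_id`, `label`, `age`, `activity`,
#' `path`).
#'
#' @param cohort list of records from [generate_rr_cohort()].
#' @param dir output directory (created if missing).
#' @return Path of the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(r) {
    p <- file.path(dir, paste0(r$meta$subject_id, ".txt"))
    write_rr(r, p)
    data.frame(subject_id = r$meta$subject_id,
               label = r$meta$group %||% NA_character_,
               age = r$meta$age %||% NA_real_,
               activity = r$meta$activity %||% NA_character_,
               path = basename(p), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# save/restore the global RNG state so seeded generators do not disturb
# the caller's random stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
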