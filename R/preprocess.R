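#' Artifact filter for RR series
#'
#' Detects and corrects detection artifacts and ectopic beats in a raw RR
#' series. A beat is flagged when it deviates from the running local
#' median (window of `window_beats` beats) by more than `rel_threshold`
#' of that median; flagged beats are replaced by natural cubic spline
#' interpolation over the surrounding reliable beats. Detection and
#' replacement are iterated until no new beat is flagged, so the filter
#' is idempotent: a corrected series passes through unchanged. The number
#' of beats is never changed, only their values and flags.
#'
#' Both beats of an ectopic short--long pair typically exceed the
#' threshold and are corrected together.
#'
#' @param raw an [rr_series()]; must contain at least `window_beats`
#'   beats.
#' @param window_beats width of the running-median window in beats; must
#'   be odd (an even value is increased by one). Default 11.
#' @param rel_threshold relative deviation from the local median above
#'   which a beat is treated as an artifact. Default 0.2 (20 %).
#' @return An `nn_series` with corrected intervals, `flags` set to
#'   `"corrected"` for every replaced beat, and `n_corrected` recording
#'   their count.
#' @examples
#' rr <- rr_series(c(rep(800, 20), 2000, rep(800, 20)))
#' nn <- filter_artifacts(rr)
#' nn$n_corrected            # 1
#' round(nn$intervals[21])   # back near 800
#' @export
filter_artifacts <- function(raw, window_beats = 11, rel_threshold = 0.2) {
  stopifnot(inherits(raw, "rr_series"))
  if (!is.numeric(rel_threshold) || rel_threshold <= 0) {
    stop("'rel_threshold' must be positive", call. = FALSE)
  }
  window_beats <- as.integer(window_beats)
  if (window_beats < 3) stop("'window_beats' must be at least 3", call. = FALSE)
  if (window_beats %% 2 == 0) window_beats <- window_beats + 1L
  x <- raw$intervals
  n <- length(x)
  if (n < window_beats) {
    stop(sprintf("series has %d beats; at least %d required", n, window_beats),
         call. = FALSE)
  }

  corrected <- rep(FALSE, n)
  for (iter in 1:20) {
    med <- runmed(x, k = window_beats, endrule = "median")
    bad <- abs(x - med) / med > rel_threshold & !corrected
    if (!any(bad)) break
    corrected <- corrected | bad
    good <- which(!corrected)
    if (length(good) < 4) {
      stop("too few reliable beats left to interpolate over", call. = FALSE)
    }
    x[corrected] <- spline(good, x[good], xout = which(corrected),
                           method = "natural")$y
  }
  x <- pmax(x, 1)  # interpolation safety: intervals must stay positive

  flags <- raw$flags
  flags[corrected] <- "corrected"
  new_nn_series(x, flags, raw$meta, n_corrected = sum(corrected))
}

#' Remove the slow-varying trend from an NN series
#'
#' Smoothness-priors detrending of the beat series: the trend is the
#' solution of \eqn{\min_z \|x - z\|^2 + \lambda^2 \|D_2 z\|^2} with
#' \eqn{D_2} the second-difference operator, i.e. a regularised
#' least-squares smoother acting as a time-varying high-pass filter. The
#' trend is removed around the series mean, so the mean RR (and hence
#' mean heart rate) is preserved exactly.
#'
#' With the default `lambda = 300` the half-power cutoff on a typical
#' ~1.25 beats/s record sits near 0.03 Hz: oscillations in the VLF edge
#' and below (periods of minutes) are removed while LF/HF content is
#' untouched, which is what the entropy, Hurst and spectral features
#' assume.
#'
#' @param nn an artifact-corrected `nn_series` (output of
#'   [filter_artifacts()]).
#' @param lambda regularisation strength; larger values remove only
#'   slower trends.
#' @return The detrended `nn_series` (`detrended` flag set).
#' @export
detrend_rr <- function(nn, lambda = 300) {
  stopifnot(inherits(nn, "rr_series"))
  if (!is.numeric(lambda) || lambda < 0) {
    stop("'lambda' must be non-negative", call. = FALSE)
  }
  x <- nn$intervals
  n <- length(x)
  out <- x
  if (lambda > 0 && n >= 3) {
    D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                            diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                             rep(1, n - 2)))
    A <- Matrix::Diagonal(n) + lambda^2 * Matrix::crossprod(D)
    trend <- as.numeric(Matrix::solve(A, x))
    out <- x - trend
    out <- out - mean(out) + mean(x)
  }
  out <- pmax(out, 1)
  res <- new_nn_series(out, nn$flags, nn$meta,
                       n_corrected = nn$n_corrected %||% 0L,
                       detrended = TRUE)
  res
}

#' Quality control for NN series
#'
#' A record is accepted only if it is long enough and not too corrupted:
#' duration at least `min_duration_s` (default 300 s, the standard
#' minimum for reliable short-term HRV analysis) and fraction of
#' corrected beats at most `max_artifact_fraction`.
#'
#' @param nn an `nn_series` (or raw `rr_series`; then the fraction of
#'   beats flagged artifact/ectopic is used).
#' @param min_duration_s minimum record duration, seconds.
#' @param max_artifact_fraction maximum tolerated fraction of corrected
#'   beats. Default 0.05.
#' @return A `qc_report`: list with `duration_s`, `artifact_fraction`,
#'   `accepted`, and `reject_reason` (one of `"none"`, `"too_short"`,
#'   `"too_many_artifacts"`).
#' @examples
#' nn <- filter_artifacts(rr_series(rep(800, 400)))
#' quality_control(nn)$accepted          # TRUE: 320 s, no corrections
#' @export
quality_control <- function(nn, min_duration_s = 300,
                            max_artifact_fraction = 0.05) {
  stopifnot(inherits(nn, "rr_series"))
  dur <- duration_s(nn)
  n <- length(nn$intervals)
  frac <- if (!is.null(nn$n_corrected)) {
    nn$n_corrected / n
  } else {
    mean(nn$flags %in% c("artifact", "ectopic", "corrected"))
  }
  reason <- "none"
  if (dur < min_duration_s) {
    reason <- "too_short"
  } else if (frac > max_artifact_fraction) {
    reason <- "too_many_artifacts"
  }
  structure(list(duration_s = dur, artifact_fraction = frac,
                 accepted = reason == "none", reject_reason = reason),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %.1f s, %.2f%% corrected -> %s%s\n",
              x$duration_s, 100 * x$artifact_fraction,
              if (x$accepted) "accepted" else "rejected",
              if (x$accepted) "" else paste0(" (", x$reject_reason, ")")))
  invisible(x)
}

#' Resample an NN series to an equidistant tachogram
#'
#' Evaluates the RR-versus-time function on a uniform grid by natural
#' cubic spline interpolation, producing the equidistant tachogram the
#' spectral features require. The grid starts at the first whole second
#' at or after the first beat and steps by `1/fs`.
#'
#' @param nn an `nn_series` with at least 4 beats.
#' @param fs sampling rate of the grid in Hz; default 1.
#' @return A `tachogram`: list with `values` (ms), `t0` (s), `fs`.
#' @examples
#' tach <- resample_tachogram(filter_artifacts(rr_series(rep(800, 400))))
#' length(tach$values)  # one sample per second
#' @export
resample_tachogram <- function(nn, fs = 1) {
  stopifnot(inherits(nn, "rr_series"))
  if (length(nn$intervals) < 4) {
    stop("at least 4 beats required for cubic resampling", call. = FALSE)
  }
  t <- nn$times
  grid <- seq(ceiling(t[1] * fs) / fs, floor(t[length(t)] * fs) / fs,
              by = 1 / fs)
  vals <- spline(t, nn$intervals, xout = grid, method = "natural")$y
  structure(list(values = vals, t0 = grid[1], fs = fs), class = "tachogram")
}
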