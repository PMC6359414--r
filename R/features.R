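#' Time-domain HRV features
#'
#' Heart-rate statistics and the classical short-term variability
#' measures computed from artifact-corrected NN intervals:
#' instantaneous heart rate is `60000 / NN` (bpm); `pnn50` is the
#' percentage of adjacent NN pairs differing by more than 50 ms;
#' `rmssd` is the root mean square of successive differences.
#'
#' pNN50 and RMSSD are difference-based and therefore insensitive to
#' slow trends; they are intended to be computed on corrected but
#' non-detrended NN intervals.
#'
#' @param nn an `nn_series` (or `rr_series`) with at least 2 beats.
#' @return Named list: `hr_mean`, `hr_sd` (bpm), `pnn50` (percent),
#'   `rmssd` (ms).
#' @examples
#' hrv_time_domain(rr_series(c(800, 850, 800)))$rmssd  # 50
#' @export
hrv_time_domain <- function(nn) {
  stopifnot(inherits(nn, "rr_series"))
  x <- nn$intervals
  if (length(x) < 2) stop("at least 2 beats required", call. = FALSE)
  hr <- 60000 / x
  d <- diff(x)
  list(hr_mean = mean(hr), hr_sd = sd(hr),
       pnn50 = 100 * mean(abs(d) > 50),
       rmssd = sqrt(mean(d^2)))
}

#' Poincare-plot features
#'
#' Dispersion of the lag-1 scatter plot of NN intervals. `sd1`, the
#' spread across the identity line, measures short-term variability;
#' `sd2`, the spread along it, long-term variability:
#' \deqn{SD1^2 = Var(x_{n+1} - x_n)/2, \qquad SD2^2 = 2 Var(x) - SD1^2,}
#' with population (1/n) variances so the identities are exact on
#' deterministic series. `theta` summarises the strength of the lag-1
#' dependence as the parameter of a one-parameter Archimedean copula
#' estimated by Kendall-tau inversion; for the default Clayton family
#' \eqn{\theta = 2\tau/(1-\tau)}, 0 at independence.
#'
#' @param nn an `nn_series` with at least 3 beats.
#' @param copula copula family for `theta`; currently `"clayton"`.
#' @return Named list: `sd1`, `sd2` (ms), `ratio` (SD1/SD2; `NA` when
#'   SD2 is 0), `theta`. A zero-variance series gives
#'   `sd1 = sd2 = 0` and `ratio = theta = NA`.
#' @examples
#' x <- rep(c(800, 850), 50)
#' hrv_poincare(rr_series(c(x, 800)))$sd1  # sqrt(1250)
#' @export
hrv_poincare <- function(nn, copula = c("clayton")) {
  stopifnot(inherits(nn, "rr_series"))
  copula <- match.arg(copula)
  x <- nn$intervals
  n <- length(x)
  if (n < 3) stop("at least 3 beats required", call. = FALSE)
  varp <- function(v) mean((v - mean(v))^2)
  d <- diff(x)
  sd1 <- sqrt(varp(d) / 2)
  sd2 <- sqrt(max(2 * varp(x) - sd1^2, 0))
  if (varp(x) == 0) {
    return(list(sd1 = 0, sd2 = 0, ratio = NA_real_, theta = NA_real_))
  }
  ratio <- if (sd2 > 0) sd1 / sd2 else NA_real_
  tau <- suppressWarnings(cor(x[-n], x[-1], method = "kendall"))
  theta <- if (is.na(tau) || tau >= 1) NA_real_ else 2 * tau / (1 - tau)
  list(sd1 = sd1, sd2 = sd2, ratio = ratio, theta = theta)
}

#' Fractal scaling features: DFA exponents and Hurst exponent
#'
#' Detrended fluctuation analysis integrates the mean-removed series,
#' splits the profile into non-overlapping boxes of size n, removes a
#' least-squares line per box, and measures the residual fluctuation
#' F(n); the scaling exponents are log-log slopes of F(n): `alpha1` over
#' short scales (4--16 beats), `alpha2` over long scales (16--64) and
#' `alpha` overall (4--64). White noise gives alpha ~ 0.5, Brownian
#' motion ~ 1.5.
#'
#' The Hurst exponent is estimated by rescaled-range (R/S) analysis on
#' log-spaced window sizes from 8 to N/2, slope by least squares; it
#' assumes a stationary (detrended) input. White noise gives H ~ 0.5.
#'
#' @param nn an `nn_series` with at least 100 beats (shorter series give
#'   unstable log-log fits).
#' @param scales_alpha1,scales_alpha2 box-size ranges (beats) for the
#'   short- and long-scale DFA exponents.
#' @return Named list: `alpha`, `alpha1`, `alpha2`, `hurst`.
#' @export
hrv_fractal <- function(nn, scales_alpha1 = c(4, 16),
                        scales_alpha2 = c(16, 64)) {
  stopifnot(inherits(nn, "rr_series"))
  x <- nn$intervals
  if (length(x) < 100) {
    stop("at least 100 beats required for fractal analysis", call. = FALSE)
  }
  lo <- scales_alpha1[1]; hi <- scales_alpha2[2]
  d <- dfa_fluctuation(x, lo, hi)
  fit_slope <- function(keep) {
    if (sum(keep) < 2) return(NA_real_)
    coef(lm.fit(cbind(1, log(d$scales[keep])), log(d$fn[keep])))[2]
  }
  ok <- d$fn > 0
  alpha  <- fit_slope(ok)
  alpha1 <- fit_slope(ok & d$scales >= scales_alpha1[1] &
                        d$scales <= scales_alpha1[2])
  alpha2 <- fit_slope(ok & d$scales >= scales_alpha2[1] &
                        d$scales <= scales_alpha2[2])
  list(alpha = unname(alpha), alpha1 = unname(alpha1),
       alpha2 = unname(alpha2), hurst = hurst_rs(x))
}

# DFA fluctuation function over log-spaced box sizes in [lo, hi]
dfa_fluctuation <- function(x, lo = 4, hi = 64, n_scales = 16) {
  n <- length(x)
  hi <- min(hi, floor(n / 4))
  scales <- unique(round(exp(seq(log(lo), log(hi), length.out = n_scales))))
  y <- cumsum(x - mean(x))
  fn <- vapply(scales, function(s) {
    nwin <- floor(n / s)
    Y <- matrix(y[seq_len(nwin * s)], nrow = s)
    X <- cbind(1, seq_len(s))
    # least-squares line per column, residual RMS over all boxes
    C <- solve(crossprod(X), crossprod(X, Y))
    R <- Y - X %*% C
    sqrt(mean(R^2))
  }, 0)
  list(scales = scales, fn = fn)
}

# Hurst exponent by rescaled-range analysis
hurst_rs <- function(x, min_win = 8) {
  n <- length(x)
  sizes <- unique(round(exp(seq(log(min_win), log(floor(n / 2)),
                                length.out = 10))))
  rs <- vapply(sizes, function(s) {
    nwin <- floor(n / s)
    vals <- vapply(seq_len(nwin), function(w) {
      seg <- x[((w - 1) * s + 1):(w * s)]
      z <- cumsum(seg - mean(seg))
      S <- sd(seg)
      if (S == 0) return(NA_real_)
      (max(z) - min(z)) / S
    }, 0)
    mean(vals, na.rm = TRUE)
  }, 0)
  keep <- is.finite(rs) & rs > 0
  if (sum(keep) < 2) return(NA_real_)
  unname(coef(lm.fit(cbind(1, log(sizes[keep])), log(rs[keep])))[2])
}

#' Entropy features: ApEn, SampEn, BinEn
#'
#' Approximate entropy and sample entropy are template-matching
#' irregularity measures (natural logarithms, Chebyshev distance,
#' tolerance `r` expressed as a fraction of the series standard
#' deviation). ApEn counts self-matches; SampEn excludes them and is
#' reported as missing (`NA`) when no template pair matches, rather than
#' infinity.
#'
#' Binarized entropy (BinEn) is a cheap, artifact-robust alternative
#' designed for crowd sensing: the series is differentially coded to the
#' binary sequence \eqn{b_i = 1} if \eqn{NN_{i+1} \ge NN_i} else 0, and
#' BinEn is the entropy rate estimate
#' \eqn{H(\text{(m_bin+1)-words}) - H(\text{m_bin-words})} in nats,
#' with the m_bin-word distribution taken as the marginal of the
#' (m_bin+1)-word distribution so that the estimate is a true
#' conditional entropy, bounded by \eqn{[0, \ln 2]}. A monotone series
#' gives 0; i.i.d. symmetric jitter approaches ln 2.
#'
#' @param nn an `nn_series`. Estimates are unreliable below ~100 beats;
#'   the hard minimum is what the template lengths require.
#' @param m template length for ApEn/SampEn; default 2.
#' @param r tolerance as a fraction of the series SD; default 0.2.
#' @param m_bin word length for BinEn; default 2.
#' @return Named list: `apen`, `sampen`, `binen` (nats).
#' @examples
#' hrv_entropy(rr_series(rep(800, 120)))           # all zero
#' @export
hrv_entropy <- function(nn, m = 2, r = 0.2, m_bin = 2) {
  stopifnot(inherits(nn, "rr_series"))
  x <- nn$intervals
  m <- as.integer(m); m_bin <- as.integer(m_bin)
  if (m < 1 || m_bin < 1) stop("'m' and 'm_bin' must be >= 1", call. = FALSE)
  if (length(x) < m + 3 || length(x) < m_bin + 3) {
    stop("series too short for the requested template lengths", call. = FALSE)
  }
  r_abs <- r * sd(x)
  list(apen = approx_entropy(x, m, r_abs),
       sampen = sample_entropy(x, m, r_abs),
       binen = binarized_entropy(x, m_bin))
}

# Chebyshev distance matrix between all m-length templates starting at
# positions 1..nt
.template_dist <- function(x, m, nt) {
  D <- matrix(0, nt, nt)
  for (k in 0:(m - 1)) {
    v <- x[(1 + k):(nt + k)]
    D <- pmax(D, abs(outer(v, v, "-")))
  }
  D
}

approx_entropy <- function(x, m, r_abs) {
  phi <- function(mm) {
    nt <- length(x) - mm + 1
    C <- rowMeans(.template_dist(x, mm, nt) <= r_abs)  # self-match included
    mean(log(C))
  }
  phi(m) - phi(m + 1)
}

sample_entropy <- function(x, m, r_abs) {
  nt <- length(x) - m  # templates with a defined (m+1)-extension
  Dm <- .template_dist(x, m, nt) <= r_abs
  Dm1 <- .template_dist(x, m + 1, nt) <= r_abs
  ut <- upper.tri(Dm)
  B <- sum(Dm[ut]); A <- sum(Dm1[ut])
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

binarized_entropy <- function(x, m_bin) {
  b <- as.integer(diff(x) >= 0)
  L <- length(b) - m_bin
  if (L < 1) stop("series too short for BinEn word length", call. = FALSE)
  # id of each (m_bin+1)-word
  id <- integer(L)
  for (k in 0:m_bin) id <- id * 2L + b[(1 + k):(L + k)]
  nbins <- 2^(m_bin + 1)
  p_joint <- tabulate(id + 1L, nbins) / L
  # marginal over the first m_bin symbols: drop the last bit
  p_marg <- tapply(p_joint, (seq_len(nbins) - 1L) %/% 2L, sum)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  max(H(p_joint) - H(p_marg), 0)
}

#' Frequency-domain HRV features
#'
#' Welch power spectral density of the mean-removed equidistant
#' tachogram (Hann-windowed segments, 50 % overlap, default segment
#' length 256 s) integrated over the standard HRV bands: ULF below
#' 0.0033 Hz, VLF 0.0033--0.04 Hz, LF 0.04--0.15 Hz, HF 0.15--0.4 Hz.
#' `total_power` is the summed power of the four bands (components above
#' the HF edge are outside the physiological bands and excluded), so the
#' four band percentages sum to 100 by construction. Normalised units
#' are `lf_nu = 100 LF/(LF+HF)` and its complement `hf_nu`.
#'
#' Note: at the default 256-s segment length the lowest resolvable
#' frequency is ~0.004 Hz, so the ULF band is only populated when longer
#' segments (and records) are supplied.
#'
#' @param tach a `tachogram` from [resample_tachogram()] with at least
#'   300 samples.
#' @param seg_len_s Welch segment length in seconds; default 256.
#' @return Named list: `total_power` (ms^2), `ulf_pct`, `vlf_pct`,
#'   `lf_pct`, `hf_pct` (percent of total), `lf_hf`, `lf_nu`, `hf_nu`.
#'   When LF + HF power is zero, `lf_hf`, `lf_nu`, `hf_nu` are `NA`.
#' @export
hrv_spectral <- function(tach, seg_len_s = 256) {
  stopifnot(inherits(tach, "tachogram"))
  v <- tach$values
  if (length(v) < 300) {
    stop("tachogram must have at least 300 samples", call. = FALSE)
  }
  ps <- welch_psd(v, fs = tach$fs, seg_len = min(seg_len_s * tach$fs,
                                                 length(v)))
  band_power <- function(f_lo, f_hi) {
    keep <- ps$freq > f_lo & ps$freq <= f_hi & ps$freq > 0
    sum(ps$psd[keep]) * ps$df
  }
  ulf <- band_power(0, 0.0033)
  vlf <- band_power(0.0033, 0.04)
  lf  <- band_power(0.04, 0.15)
  hf  <- band_power(0.15, 0.4)
  total <- ulf + vlf + lf + hf
  pct <- function(p) if (total > 0) 100 * p / total else NA_real_
  if (lf + hf > 0) {
    lf_hf <- if (hf > 0) lf / hf else NA_real_
    lf_nu <- 100 * lf / (lf + hf)
    hf_nu <- 100 - lf_nu
  } else {
    lf_hf <- lf_nu <- hf_nu <- NA_real_
  }
  list(total_power = total, ulf_pct = pct(ulf), vlf_pct = pct(vlf),
       lf_pct = pct(lf), hf_pct = pct(hf),
       lf_hf = lf_hf, lf_nu = lf_nu, hf_nu = hf_nu)
}

# Welch PSD: Hann window, 50% overlap, one-sided density (power/Hz)
welch_psd <- function(v, fs = 1, seg_len = 256, overlap = 0.5) {
  v <- v - mean(v)
  seg_len <- min(as.integer(seg_len), length(v))
  step <- max(1L, as.integer(seg_len * (1 - overlap)))
  starts <- seq(1L, length(v) - seg_len + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(seg_len - 1)) / (seg_len - 1)))
  U <- sum(w^2) * fs
  acc <- numeric(seg_len)
  for (s in starts) {
    seg <- v[s:(s + seg_len - 1)] * w
    acc <- acc + Mod(fft(seg))^2
  }
  psd <- acc / (length(starts) * U)
  half <- floor(seg_len / 2)
  one_sided <- psd[1:(half + 1)]
  # double the interior bins to fold the negative frequencies in
  if (half >= 2) one_sided[2:half] <- 2 * one_sided[2:half]
  if (seg_len %% 2 == 1) one_sided[half + 1] <- 2 * one_sided[half + 1]
  freq <- (0:half) * fs / seg_len
  list(freq = freq, psd = one_sided, df = fs / seg_len)
}

#' Names of the transmitted feature vector
#'
#' Column order of the feature vector produced by [extract_features()]:
#' age plus 23 cardiovascular features. This compact vector (a few dozen
#' numbers) is what a crowd-sensing client transmits in place of the raw
#' signal.
#'
#' @return Character vector of feature names.
#' @export
feature_names <- function() {
  c("age", "hr_mean", "hr_sd", "pp_sd1", "pp_sd2", "pp_ratio", "pp_theta",
    "dfa_alpha", "dfa_alpha1", "dfa_alpha2", "hurst",
    "apen", "sampen", "binen", "pnn50", "rmssd",
    "total_power", "ulf_pct", "vlf_pct", "lf_pct", "hf_pct",
    "lf_hf", "lf_nu", "hf_nu")
}

#' Extract the full HRV feature vector from a corrected NN series
#'
#' Runs the complete feature battery on a QC-accepted record. Heart
#' rate, pNN50, RMSSD and the Poincare features are computed on the
#' corrected (non-detrended) NN intervals; the entropy and fractal
#' features on the detrended series; the spectral features on the 1 Hz
#' tachogram of the detrended series.
#'
#' @param nn an `nn_series` from [filter_artifacts()].
#' @param age subject age in years; taken from `nn$meta$age` when
#'   missing.
#' @param config feature/preprocessing parameters, see
#'   [default_config()]; QC gates and all feature defaults come from it.
#' @param check_qc run [quality_control()] first and refuse rejected
#'   records (default TRUE).
#' @return A one-row `data.frame` with columns [feature_names()].
#' @examples
#' rr <- generate_rr_record(rr_gen_config(duration_s = 320, sd_rr_ms = 25,
#'                                        hf_amp_ms = 10, seed = 2))
#' fv <- extract_features(filter_artifacts(rr), age = 50)
#' fv$pnn50
#' @export
extract_features <- function(nn, age = NULL, config = default_config(),
                             check_qc = TRUE) {
  stopifnot(inherits(nn, "rr_series"))
  if (is.null(age)) age <- nn$meta$age
  if (is.null(age)) age <- NA_real_
  pp <- config$preprocess
  if (isTRUE(check_qc)) {
    qc <- quality_control(nn, pp$min_duration_s, pp$max_artifact_fraction)
    if (!qc$accepted) {
      stop("record rejected by quality control: ", qc$reject_reason,
           call. = FALSE)
    }
  }
  fe <- config$features
  td <- hrv_time_domain(nn)
  pc <- hrv_poincare(nn, copula = fe$copula)
  det <- if (isTRUE(nn$detrended)) nn else detrend_rr(nn, pp$detrend_lambda)
  fr <- hrv_fractal(det)
  en <- hrv_entropy(det, m = fe$entropy_m, r = fe$entropy_r,
                    m_bin = fe$binen_m)
  sp <- hrv_spectral(resample_tachogram(det), seg_len_s = fe$welch_seg_s)
  out <- data.frame(
    age = as.numeric(age),
    hr_mean = td$hr_mean, hr_sd = td$hr_sd,
    pp_sd1 = pc$sd1, pp_sd2 = pc$sd2, pp_ratio = pc$ratio,
    pp_theta = pc$theta,
    dfa_alpha = fr$alpha, dfa_alpha1 = fr$alpha1, dfa_alpha2 = fr$alpha2,
    hurst = fr$hurst,
    apen = en$apen, sampen = en$sampen, binen = en$binen,
    pnn50 = td$pnn50, rmssd = td$rmssd,
    total_power = sp$total_power, ulf_pct = sp$ulf_pct,
    vlf_pct = sp$vlf_pct, lf_pct = sp$lf_pct, hf_pct = sp$hf_pct,
    lf_hf = sp$lf_hf, lf_nu = sp$lf_nu, hf_nu = sp$hf_nu
  )
  out[, feature_names()]
}

#' Build a cohort feature table
#'
#' Preprocesses every record (artifact filter + QC) and extracts the
#' feature vector of the accepted ones, assembling the table used by the
#' modelling stage: columns `subject_id`, `label`, `activity`, then
#' [feature_names()].
#'
#' @param records list of [rr_series()] (e.g. from
#'   [generate_rr_cohort()]).
#' @param config pipeline configuration, see [default_config()].
#' @return A `data.frame`; records rejected by QC are dropped (an
#'   attribute `"qc_log"` records every decision).
#' @export
cohort_features <- function(records, config = default_config()) {
  pp <- config$preprocess
  rows <- list(); log <- list()
  for (i in seq_along(records)) {
    r <- records[[i]]
    nn <- filter_artifacts(r, pp$window_beats, pp$rel_threshold)
    qc <- quality_control(nn, pp$min_duration_s, pp$max_artifact_fraction)
    sid <- r$meta$subject_id %||% sprintf("R%04d", i)
    log[[i]] <- data.frame(subject_id = sid,
                           accepted = qc$accepted,
                           reason = qc$reject_reason,
                           stringsAsFactors = FALSE)
    if (!qc$accepted) next
    fv <- extract_features(nn, config = config, check_qc = FALSE)
    rows[[length(rows) + 1]] <- cbind(
      data.frame(subject_id = sid,
                 label = r$meta$group %||% NA_character_,
                 activity = r$meta$activity %||% NA_character_,
                 stringsAsFactors = FALSE),
      fv)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    stop("no record passed quality control", call. = FALSE)
  rownames(out) <- NULL
  attr(out, "qc_log") <- do.call(rbind, log)
  out
}
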