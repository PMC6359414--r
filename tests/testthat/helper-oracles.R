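# Brute-force oracles, written as plain loops independent of the package
# implementations they check.

oracle_sd1_sd2 <- function(x) {
  n <- length(x)
  d <- x[2:n] - x[1:(n - 1)]
  varp <- function(v) {
    m <- sum(v) / length(v)
    sum((v - m)^2) / length(v)
  }
  sd1 <- sqrt(varp(d) / 2)
  sd2 <- sqrt(max(2 * varp(x) - sd1^2, 0))
  c(sd1 = sd1, sd2 = sd2)
}

oracle_pnn50 <- function(x) {
  cnt <- 0
  for (i in 2:length(x)) if (abs(x[i] - x[i - 1]) > 50) cnt <- cnt + 1
  100 * cnt / (length(x) - 1)
}

oracle_rmssd <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + (x[i] - x[i - 1])^2
  sqrt(s / (length(x) - 1))
}

# exhaustive template counting, self-matches included
oracle_apen <- function(x, m, r_abs) {
  phi <- function(mm) {
    nt <- length(x) - mm + 1
    tot <- 0
    for (i in 1:nt) {
      cnt <- 0
      for (j in 1:nt) {
        dmax <- 0
        for (k in 0:(mm - 1)) dmax <- max(dmax, abs(x[i + k] - x[j + k]))
        if (dmax <= r_abs) cnt <- cnt + 1
      }
      tot <- tot + log(cnt / nt)
    }
    tot / nt
  }
  phi(m) - phi(m + 1)
}

# exhaustive pair counting over templates 1..N-m, self-matches excluded
oracle_sampen <- function(x, m, r_abs) {
  nt <- length(x) - m
  A <- 0; B <- 0
  for (i in 1:(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- 0
      for (k in 0:(m - 1)) dm <- max(dm, abs(x[i + k] - x[j + k]))
      if (dm <= r_abs) {
        B <- B + 1
        if (max(dm, abs(x[i + m] - x[j + m])) <= r_abs) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# raw full-length periodogram; returns power per frequency (excl. DC)
oracle_periodogram <- function(v, fs = 1) {
  v <- v - mean(v)
  n <- length(v)
  p <- Mod(fft(v))^2 / n
  half <- floor(n / 2)
  list(freq = (1:half) * fs / n, power = p[2:(half + 1)])
}

# fraction of total (non-DC) periodogram power inside [f_lo, f_hi]
oracle_band_fraction <- function(v, f_lo, f_hi, fs = 1) {
  pg <- oracle_periodogram(v, fs)
  sum(pg$power[pg$freq >= f_lo & pg$freq <= f_hi]) / sum(pg$power)
}

# small labelled cohort with one informative feature, for model tests
make_separable_cohort <- function(n_per_class = 40, shift = 4, seed = 1) {
  set.seed(seed)
  data.frame(
    label = rep(c("control", "hypertensive"), each = n_per_class),
    f_sig = c(rnorm(n_per_class, 0), rnorm(n_per_class, shift)),
    f_noise1 = rnorm(2 * n_per_class),
    f_noise2 = rnorm(2 * n_per_class)
  )
}
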