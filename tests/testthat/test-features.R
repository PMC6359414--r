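test_that("time-domain features match hand-computed cases", {
  cst <- hrv_time_domain(rr_series(rep(800, 10)))
  expect_equal(cst$hr_mean, 75)
  expect_equal(cst$hr_sd, 0)
  expect_equal(cst$pnn50, 0)
  expect_equal(cst$rmssd, 0)

  td <- hrv_time_domain(rr_series(c(800, 860, 865, 800)))
  expect_equal(td$pnn50, 100 * 2 / 3)

  expect_equal(hrv_time_domain(rr_series(c(800, 850, 800)))$rmssd, 50)
  expect_error(hrv_time_domain(rr_series(800)), "2 beats")
})

test_that("constant-offset invariance of difference-based features", {
  set.seed(14)
  x <- 800 + rnorm(200, 0, 30)
  a <- hrv_time_domain(rr_series(x))
  b <- hrv_time_domain(rr_series(x + 150))
  expect_equal(a$pnn50, b$pnn50)
  expect_equal(a$rmssd, b$rmssd)
})

test_that("Poincare geometry follows its closed forms", {
  # alternating series: all variance lies across the identity line
  alt <- rep(c(800, 850), length.out = 101)
  pc <- hrv_poincare(rr_series(alt))
  expect_equal(pc$sd1, sqrt(1250), tolerance = 1e-12)
  expect_equal(pc$sd2, 0, tolerance = 1e-6)
  expect_true(is.na(pc$ratio))

  # i.i.d. series: symmetric lag-1 cloud, SD1 ~ SD2, theta ~ independence
  set.seed(8)
  iid <- hrv_poincare(rr_series(800 + rnorm(3000, 0, 30)))
  expect_equal(iid$ratio, 1, tolerance = 0.1)
  expect_equal(iid$theta, 0, tolerance = 0.15)

  # zero variance: dispersions zero, ratio undefined
  z <- hrv_poincare(rr_series(rep(800, 10)))
  expect_equal(z$sd1, 0)
  expect_equal(z$sd2, 0)
  expect_true(is.na(z$ratio))

  # positively dependent adjacent beats give a positive Clayton theta
  set.seed(9)
  ar <- as.numeric(800 + arima.sim(list(ar = 0.8), 2000, sd = 10))
  expect_gt(hrv_poincare(rr_series(ar))$theta, 0.5)
})

test_that("SD1/SD2 match the brute-force oracle on random series", {
  set.seed(101)
  for (i in 1:25) {
    x <- abs(rnorm(sample(10:50, 1), 800, 60)) + 300
    pc <- hrv_poincare(rr_series(x))
    o <- oracle_sd1_sd2(x)
    expect_equal(pc$sd1, o["sd1"], tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(pc$sd2, o["sd2"], tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("DFA and Hurst hit their analytic limits", {
  # white noise: alpha and H near 0.5
  set.seed(5)
  a <- h <- numeric(4)
  for (i in 1:4) {
    x <- rr_series(800 + rnorm(1500, 0, 30))
    fr <- hrv_fractal(x)
    a[i] <- fr$alpha; h[i] <- fr$hurst
  }
  expect_lt(abs(mean(a) - 0.5), 0.1)
  expect_lt(abs(mean(h) - 0.5), 0.1)

  # integrated white noise: alpha near 1.5
  set.seed(6)
  ab <- mean(vapply(1:3, function(i)
    hrv_fractal(rr_series(5000 + cumsum(rnorm(800, 0, 5))))$alpha, 0))
  expect_equal(ab, 1.5, tolerance = 0.15)

  expect_error(hrv_fractal(rr_series(rep(800, 50))), "100 beats")
})

test_that("Hurst estimate agrees with an independent R/S implementation", {
  set.seed(12)
  x <- 800 + rnorm(1200, 0, 25)
  mine <- hrv_fractal(rr_series(x))$hurst
  ref <- pracma::hurstexp(x, display = FALSE)$Hs
  expect_equal(mine, ref, tolerance = 0.15)
})

test_that("entropies of degenerate and toy series are exact", {
  z <- hrv_entropy(rr_series(rep(800, 120)))
  expect_equal(z$apen, 0)
  expect_equal(z$sampen, 0)
  expect_equal(z$binen, 0)

  # monotone series: deterministic difference coding
  mono <- hrv_entropy(rr_series(seq(700, 900, length.out = 150)))
  expect_equal(mono$binen, 0)

  # tolerance far below the spacing of distinct values: no template pair
  # matches, SampEn reported missing rather than infinite
  set.seed(41)
  far <- rr_series(800 + sample(1:20) * 10)
  expect_true(is.na(hrv_entropy(far, r = 1e-4)$sampen))
})

test_that("ApEn/SampEn equal exhaustive template counting on toy series", {
  set.seed(77)
  for (i in 1:10) {
    n <- sample(20:40, 1)
    x <- 800 + rnorm(n, 0, 40)
    r_abs <- 0.2 * sd(x)
    en <- hrv_entropy(rr_series(x))
    expect_equal(en$apen, oracle_apen(x, 2, r_abs), tolerance = 1e-12)
    expect_equal(en$sampen, oracle_sampen(x, 2, r_abs), tolerance = 1e-12)
  }
})

test_that("BinEn is bounded by ln 2 and reaches it for fair-coin coding", {
  # differences i.i.d. symmetric: sign sequence is a fair coin
  set.seed(33)
  walk <- rr_series(10000 + cumsum(rnorm(3000, 0, 3)))
  expect_lt(abs(hrv_entropy(walk)$binen - log(2)), 0.05)

  # bound holds across arbitrary random series
  for (i in 1:20) {
    x <- 800 + cumsum(rnorm(150, sample(c(-2, 0, 2), 1), 10))
    b <- hrv_entropy(rr_series(abs(x) + 300))$binen
    expect_gte(b, 0)
    expect_lte(b, log(2) + 1e-12)
  }
})

test_that("spectral band percentages behave as designed", {
  one_tone <- generate_rr_record(rr_gen_config(duration_s = 600,
                                               lf_amp_ms = 30, seed = 1))
  sp <- hrv_spectral(resample_tachogram(filter_artifacts(one_tone)))
  expect_gt(sp$lf_pct, 95)
  expect_gt(sp$lf_nu, 95)
  expect_equal(sp$lf_nu + sp$hf_nu, 100)

  # equal-amplitude tones in LF and HF: LF/HF ratio near 1
  two_tone <- generate_rr_record(rr_gen_config(duration_s = 600,
                                               lf_amp_ms = 30, hf_amp_ms = 30,
                                               seed = 1))
  sp2 <- hrv_spectral(resample_tachogram(filter_artifacts(two_tone)))
  expect_equal(sp2$lf_hf, 1, tolerance = 0.1)

  # offset invariance and percentage closure
  tach <- resample_tachogram(filter_artifacts(generate_rr_record(
    rr_gen_config(duration_s = 600, sd_rr_ms = 20, lf_amp_ms = 20,
                  hf_amp_ms = 10, seed = 6))))
  spa <- hrv_spectral(tach)
  tach_off <- tach; tach_off$values <- tach$values + 500
  spb <- hrv_spectral(tach_off)
  for (f in c("ulf_pct", "vlf_pct", "lf_pct", "hf_pct", "lf_hf")) {
    expect_equal(spa[[f]], spb[[f]], tolerance = 1e-9)
  }
  expect_equal(spa$ulf_pct + spa$vlf_pct + spa$lf_pct + spa$hf_pct, 100,
               tolerance = 1e-9)
  expect_error(hrv_spectral(structure(list(values = rnorm(100), t0 = 0,
                                           fs = 1), class = "tachogram")),
               "300 samples")
})

test_that("extract_features fills every field and respects QC", {
  rr <- generate_rr_record(rr_gen_config(duration_s = 400, sd_rr_ms = 26,
                                         lf_amp_ms = 40, hf_amp_ms = 15,
                                         trend_amp_ms = 50, seed = 10),
                           meta = list(age = 45))
  nn <- filter_artifacts(rr)
  fv <- extract_features(nn)
  expect_identical(names(fv), feature_names())
  expect_true(fv$pnn50 >= 0 && fv$pnn50 <= 100)
  expect_true(fv$rmssd >= 0 && fv$pp_sd1 >= 0 && fv$pp_sd2 >= 0)
  expect_true(fv$binen >= 0 && fv$binen <= log(2))
  expect_true(fv$apen >= 0 && fv$sampen >= 0)
  expect_equal(fv$ulf_pct + fv$vlf_pct + fv$lf_pct + fv$hf_pct, 100,
               tolerance = 1e-9)
  expect_equal(fv$lf_nu + fv$hf_nu, 100, tolerance = 1e-9)

  # determinism: same record, same vector
  expect_identical(fv, extract_features(nn))

  # QC refusal: short record
  short <- filter_artifacts(generate_rr_record(
    rr_gen_config(duration_s = 250, sd_rr_ms = 20, seed = 1)))
  expect_error(extract_features(short, age = 50), "too_short")
})

test_that("correction brings pNN50 and RMSSD back toward clean values", {
  for (seed in c(4, 16)) {
    base <- list(duration_s = 320, sd_rr_ms = 22, lf_amp_ms = 30, seed = seed)
    clean <- generate_rr_record(do.call(rr_gen_config, base))
    raw <- generate_rr_record(do.call(rr_gen_config,
      c(base, list(artifact_rate = 0.04, ectopic_rate = 0.02))))
    corr <- filter_artifacts(raw)
    for (f in c("pnn50", "rmssd")) {
      v_clean <- hrv_time_domain(clean)[[f]]
      expect_lt(abs(hrv_time_domain(corr)[[f]] - v_clean),
                abs(hrv_time_domain(raw)[[f]] - v_clean))
    }
  }
})

test_that("group comparison reports exact moments and calibrated tests", {
  set.seed(55)
  df <- data.frame(g = rep(c("a", "b"), c(30, 20)),
                   f = c(rnorm(30, 10, 2), rnorm(20, 10, 2)))
  cmp <- compare_groups(df, group = "g")
  expect_equal(cmp$mean_a, mean(df$f[df$g == "a"]))
  expect_equal(cmp$se_b, sd(df$f[df$g == "b"]) / sqrt(20))

  # overwhelming separation flips the bit
  df$f[df$g == "b"] <- df$f[df$g == "b"] + 6
  expect_identical(compare_groups(df, group = "g")$sig_a_vs_b, 1L)

  # type-I error near alpha for identically distributed groups
  set.seed(56)
  bits <- vapply(1:200, function(i) {
    d <- data.frame(g = rep(c("a", "b"), each = 25), f = rnorm(50))
    compare_groups(d, group = "g")$sig_a_vs_b
  }, 1L)
  expect_lt(mean(bits), 0.12)
  expect_gt(mean(bits), 0.005)

  # degenerate features: exact-equality convention
  d0 <- data.frame(g = rep(c("a", "b"), each = 3), f = c(1, 1, 1, 2, 2, 2))
  expect_identical(compare_groups(d0, group = "g")$sig_a_vs_b, 1L)
  d1 <- data.frame(g = rep(c("a", "b"), each = 3), f = rep(1, 6))
  expect_identical(compare_groups(d1, group = "g")$sig_a_vs_b, 0L)
})
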