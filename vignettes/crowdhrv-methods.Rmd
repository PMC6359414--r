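---
title: "Methods: HRV analysis and hypertension screening for crowd sensing"
author: "crowdhrv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HRV analysis and hypertension screening for crowd sensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdhrv)
```

## The problem

Hypertension is usually diagnosed from cuff blood-pressure readings, but a
cuff is incompatible with unattended, everyday monitoring by volunteers
wearing consumer devices. What such devices *can* deliver cheaply is the
beat-to-beat (RR) interval series of the heart. `crowdhrv` implements the
full chain needed to exploit it: clean the RR series automatically (no
human inspects a crowd-sensed record), reduce it to a compact vector of
heart-rate-variability (HRV) features, and classify the hypertensive
versus control state from that vector alone, returning a probability the
wearer can act on. The feature vector — two dozen numbers instead of
megabits of raw signal — is also what makes transmission affordable on a
battery- and bandwidth-constrained device: 600 s of ECG at 1 kHz and
12 bits is `transmission_bits(600, 1000, 12)` = 7,200,000 bits, while the
transmitted vector is `feature_payload_bits(24, 32)` = 768 bits.

## Pre-processing

**Artifact filter.** Crowd-sensed RR series contain spikes and drops from
loose sensors and detection software, and ectopic beats producing a
characteristic short–long interval pair. `filter_artifacts()` flags any
beat deviating from the running 11-beat median by more than 20 % of it
and replaces flagged beats by natural cubic-spline interpolation over
reliable neighbours, iterating until no new beat is flagged. Iteration
makes the filter idempotent and lets it catch both beats of an ectopic
pair. Window and threshold are configuration parameters: 11 beats is
short enough to track heart-rate changes and long enough that a majority
of window beats is reliable at the artifact rates we target (a few
percent); 20 % is well above normal beat-to-beat variability (a few
percent of the mean RR) but below the ~30–60 % excursions of ectopy and
detection failures.

**Detrending.** Several features (Hurst, the entropies, the spectral
bands) assume stationarity, which moving subjects violate.
`detrend_rr()` removes the slow trend with a smoothness-priors smoother:
the trend is the minimiser of $\|x-z\|^2 + \lambda^2\|D_2 z\|^2$ with
$D_2$ the second-difference operator. With the default $\lambda = 300$
the empirical half-power cutoff on a ~1.25 beat/s series sits near
0.01–0.03 Hz: a 1/300 Hz drift is attenuated to below 1 % while the
0.04–0.4 Hz LF/HF bands pass essentially untouched (gain > 0.98 at
0.04 Hz, 1.00 at 0.25 Hz, measured by projecting detrended sinusoidal
records on the input tone). The mean RR is preserved exactly, so mean
heart rate is unaffected. Difference-based features (pNN50, RMSSD) and
the Poincaré geometry are computed on the *corrected but non-detrended*
series — successive differences are inherently insensitive to slow
trends, and detrending would only add smoother artefacts to them.

**Quality control.** A record is accepted when it lasts at least 300 s
(the accepted minimum for short-term HRV statistics) and at most 5 % of
its beats needed correction. The 5 % default is a package choice — above
it, interpolated beats start to dominate the short-term statistics the
classifier relies on. Both gates are configurable, and tightening the
artifact gate provably only shrinks the accepted set.

**Resampling.** Spectral analysis needs equidistant samples;
`resample_tachogram()` evaluates the natural cubic spline of RR versus
time on a 1 s grid. Only the spectral features consume the resampled
tachogram; all beat-domain features use the beat series directly.

## The feature vector

`extract_features()` produces the 24-component vector (`feature_names()`):

* **Time domain** — mean and SD of instantaneous heart rate
  ($60000/RR$, bpm), pNN50 (% of adjacent pairs differing by > 50 ms),
  RMSSD (ms).
* **Poincaré geometry** — SD1/SD2, the dispersions across and along the
  identity line of the lag-1 scatter plot:
  $SD1^2 = \mathrm{Var}(\Delta x)/2$, $SD2^2 = 2\,\mathrm{Var}(x) - SD1^2$,
  with population variances so the identities are exact on deterministic
  series; their ratio; and a copula parameter $\theta$ summarising lag-1
  dependence. The copula family is configurable with Clayton as default,
  estimated by Kendall-$\tau$ inversion $\theta = 2\tau/(1-\tau)$; since
  the family choice is a package decision, $\theta$ is comparable within
  analyses run with the same family, not across families.
* **Fractal scaling** — DFA exponents fitted log-log over box sizes 4–16
  ($\alpha_1$), 16–64 ($\alpha_2$) and 4–64 ($\alpha$), the standard HRV
  convention; Hurst exponent by rescaled-range analysis over log-spaced
  windows from 8 to $N/2$. Both estimators carry the well-known
  small-sample upward bias for uncorrelated noise (measured here:
  $\alpha \approx 0.53$, $H \approx 0.55$ on 2000-beat white noise,
  against the asymptotic 0.5); no bias correction is applied because the
  classifier consumes the features relative to each other, not
  absolutely.
* **Entropies** — ApEn and SampEn with $m = 2$, $r = 0.2\,SD$, natural
  logarithms, the customary defaults; SampEn with no matching template
  pair is reported missing rather than infinite. BinEn, the
  crowd-sensing entropy, differentially codes the series to
  $b_i = \mathbf{1}[NN_{i+1} \ge NN_i]$ and estimates the conditional
  entropy of the next bit given the previous `m_bin = 2` bits; computing
  the word marginal from the joint word distribution makes the estimate
  a true conditional entropy, bounded by $[0, \ln 2]$. Because a single
  corrupted beat flips at most a few sign bits but can move many
  template distances across $r$, BinEn is far less artifact-sensitive
  than SampEn — the property the acceptance run quantifies. A subtlety:
  the sign process of an i.i.d. series is *not* a fair coin (successive
  differences share a sample and are negatively correlated), and its
  BinEn is ~0.62 nats; only i.i.d. *increments* (a random walk) give the
  fair-coin limit $\ln 2$.
* **Spectral bands** — Welch PSD of the mean-removed 1 Hz tachogram
  (256 s Hann segments, 50 % overlap) integrated over ULF (< 0.0033 Hz),
  VLF (0.0033–0.04), LF (0.04–0.15) and HF (0.15–0.4 Hz). `total_power`
  is the summed power of the four bands, so the four percentages close
  to 100 exactly; LF/HF and the normalised units
  $100\,LF/(LF+HF)$, $100\,HF/(LF+HF)$ complete the set. With 256 s
  segments the lowest resolvable frequency is ~0.004 Hz, so ULF is only
  populated for longer segments/records; on detrended 10-minute records
  it is essentially zero by construction, and the band is retained for
  completeness of the layout.

`compare_groups()` reports per-group mean ± SE for every feature and
pairwise 0/1 significance bits (pooled t-test for equal group sizes,
Welch otherwise), the layout used to contrast raw versus corrected and
patient versus control cohorts.

## Classification

`split_cohort()` makes the seeded, stratified 70/30 split. Two
classifiers are provided:

* **Random forest** (`train_rf()`): fully grown binary trees on
  bootstrap samples, a fresh random subset of $\lfloor\sqrt{p}\rfloor$
  features searched at *every node*, split scored by Gini (CART) or
  information gain (ID3) — both criteria under one interface, which no
  installed forest implementation offers; the trees are therefore grown
  by the package itself, and tests cross-check its accuracy against
  `randomForest`. Prediction is by majority vote; the probability
  returned to the patient is the fraction of trees voting hypertensive.
  Importance is mean decrease impurity: each split's impurity decrease,
  weighted by the fraction of samples reaching the node, accumulated per
  feature and normalised to sum to 1.
* **MLP** (`train_mlp()`): one hidden layer of 16 sigmoid units on
  min–max-normalised features (normalisation fitted on training data
  only, stored with the model, clipped at prediction). The network is
  fitted with `nnet` — quasi-Newton minimisation of the sigmoid-output
  cross-entropy — rather than a hand-stepped gradient loop; the
  optimiser reaches the same stationary points with far fewer
  iterations and without a learning-rate parameter to tune, and seeded
  initialisation keeps training reproducible.

`evaluate_model()` reports the confusion matrix at the 0.5 threshold,
the five screening metrics (accuracy, sensitivity, specificity,
positive/negative prediction) in percent, the ROC by threshold sweep and
AUC by the trapezoid rule (equal to the Wilcoxon two-sample statistic,
which the tests verify). `classify_feedback()` maps probabilities just
below threshold (default band [0.3, 0.5)) to a "negative (high risk)"
warning, the actionable feedback of the screening service.

## The synthetic generator

No public RR database accompanies this problem setting, so the package
ships a seeded simulator used by every test. Clean beats follow
$$RR(t) = \mu + A_{LF}\sin(2\pi\,0.1\,t) + A_{HF}\sin(2\pi\,0.25\,t)
 + A_{tr}\sin(2\pi t/T_{tr}) + \varepsilon,\qquad
 \varepsilon\sim N(0,\sigma^2),$$
band-limited LF/HF oscillations plus a slow drift and white jitter —
exactly the structure the spectral features measure. Artifacts replace a
beat by 0.4× or 2–3× its value; ectopic pairs rescale two consecutive
intervals to 0.7×/1.3× of their common mean, preserving the local sum.
Every altered beat is flagged, giving downstream stages a ground truth.

The two bundled cohort profiles encode the qualitative contrasts
expected between groups: hypertensive subjects beat faster (mean RR
800 ms vs 834 ms, i.e. 75 vs ~72 bpm) with markedly lower short-term
variability (jitter 17 vs 26 ms, HF amplitude 8 vs 15 ms) and are older
(58 ± 10 vs 45 ± 12 years, truncated to [18, 90]). Between-subject
dispersions and the 2 % artifact / 1 % ectopic rates are package
choices typical of ambulatory recordings; at these rates roughly 10–15 %
of simulated records exceed the 5 % QC gate, which deliberately
exercises the discard path. What the generator does **not** attempt is
physiological realism — no baroreflex dynamics, no respiratory
sinus-arrhythmia coupling to a breathing signal, no circadian structure.
Passing tests therefore demonstrate that the chain recovers *known
planted structure* under controlled corruption, not clinical validity;
published clinical performance figures for this task come from cohorts
of hundreds of real patients that are not publicly available, and this
package makes no claim to reproduce them.

## Numerical choices and degenerate inputs

* Intervals are floored at 250 ms in the generator and at 1 ms after
  interpolation, so downstream logs and divisions are safe.
* Zero-variance series: SD1 = SD2 = 0 with ratio and $\theta$ missing;
  all three entropies are exactly 0; the spectral stage sees a zero
  tachogram and reports missing normalised units (LF + HF = 0).
* The artifact filter refuses series shorter than its window; fractal
  analysis refuses < 100 beats (log-log fits become meaningless); the
  resampler needs ≥ 4 beats for a cubic spline; the Welch stage needs
  ≥ 300 tachogram samples. Entropy estimates are defined down to the
  template length but documented as unreliable below ~100 beats.
* Missing feature values at prediction are an error listing the fields,
  or median-imputed from the training set when explicitly requested.
* Problem sizes used by the automated runs (package choices): 200
  records per group of 600 s for the classification study, 50 seeded
  replicates for the artifact-recovery study, 2000-beat realisations
  (averaged over 5) for the fractal limits, and a 5-permutation mean for
  the label-permuted chance control — a single permutation's null AUC
  has sd ≈ 0.08 at this test-set size, so averaging is what makes the
  chance band tight.

## Known limitations

* The copula parameter is family-dependent; only its ordering carries
  information across subjects analysed with the same family.
* DFA/Hurst small-sample biases are uncorrected (see above).
* ULF power is structurally near zero on detrended 10-minute records.
* The forest and MLP are deliberately small, interpretable baselines;
  no hyper-parameter search is performed beyond the configuration
  defaults.
* The 300 s QC minimum means the toolkit targets short-term HRV; 24 h
  indices (SDNN over long horizons, circadian measures) are out of
  scope.
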