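#' Transmission-cost accounting
#'
#' In a crowd-sensing deployment the transmitter dominates the battery
#' budget, so what is sent matters: a raw 10-minute ECG at 1 kHz and
#' 12 bits per sample is 7,200,000 bits, while the extracted feature
#' vector is a few hundred bits. These helpers do that arithmetic.
#'
#' `transmission_bits()` is the cost of shipping a raw signal:
#' `duration_s * sample_rate * bits_per_sample`. `sensor_bandwidth()` is
#' the steady-state rate of a sensor stream: `sample_rate *
#' bits_per_sample` bits/s. `feature_payload_bits()` is the cost of
#' shipping the feature vector instead: `n_features * bits_per_feature`
#' with a 16- or 32-bit encoding.
#'
#' @param duration_s record duration, seconds.
#' @param sample_rate samples per second.
#' @param bits_per_sample bits per sample.
#' @return Bits (or bits per second) as a numeric scalar.
#' @examples
#' transmission_bits(600, 1000, 12)   # 7,200,000 bits for raw ECG
#' sensor_bandwidth(500, 16)          # 8000 bps: ECG upper bound
#' feature_payload_bits(23, 32)       # 736 bits for the feature vector
#' @export
transmission_bits <- function(duration_s, sample_rate, bits_per_sample) {
  .check_positive(duration_s = duration_s, sample_rate = sample_rate,
                  bits_per_sample = bits_per_sample)
  duration_s * sample_rate * bits_per_sample
}

#' @rdname transmission_bits
#' @export
sensor_bandwidth <- function(sample_rate, bits_per_sample) {
  .check_positive(sample_rate = sample_rate,
                  bits_per_sample = bits_per_sample)
  sample_rate * bits_per_sample
}

#' @rdname transmission_bits
#' @param x a feature vector (one-row `data.frame` or numeric vector) or
#'   a feature count.
#' @param bits_per_feature fixed-width encoding of one feature: 16 or 32
#'   bits.
#' @export
feature_payload_bits <- function(x, bits_per_feature = 32) {
  if (!bits_per_feature %in% c(16, 32)) {
    stop("'bits_per_feature' must be 16 or 32", call. = FALSE)
  }
  n <- if (is.data.frame(x)) ncol(x) else if (length(x) > 1) length(x)
       else as.integer(x)
  .check_positive(n_features = n)
  n * bits_per_feature
}

.check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      stop("'", nm, "' must be a positive number", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Reference table of health sensors and their bandwidth
#'
#' Typical wearable health-sensor streams with their sample rates and
#' per-sample widths, and the resulting bandwidth in bits/s computed by
#' [sensor_bandwidth()]. The ECG row is listed at its upper sampling
#' bound (500 samples/s, 2 bytes per sample: 8 kbps). The cuff
#' blood-pressure sensor does not stream at a fixed per-second rate (one
#' reading every 2 minutes); its row carries the note only and no
#' computed bandwidth.
#'
#' @return `data.frame` with columns `sensor`, `sample_rate_hz`,
#'   `bits_per_sample`, `bandwidth_bps`, `note`.
#' @export
health_sensors <- function() {
  df <- data.frame(
    sensor = c("ECG", "Blood pressure", "Pulse", "Respiration", "SpO2"),
    sample_rate_hz = c(500, NA, 2, 50, 2),
    bits_per_sample = c(16, NA, 16, 16, 16),
    note = c("125-500 samples/s, 2 bytes per sample",
             "1 sample per 2 min; 16 bits per reading",
             "", "", ""),
    stringsAsFactors = FALSE
  )
  df$bandwidth_bps <- NA_real_
  streaming <- !is.na(df$sample_rate_hz)
  df$bandwidth_bps[streaming] <- mapply(sensor_bandwidth,
                                        df$sample_rate_hz[streaming],
                                        df$bits_per_sample[streaming])
  df[, c("sensor", "sample_rate_hz", "bits_per_sample", "bandwidth_bps",
         "note")]
}
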