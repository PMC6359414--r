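#' RR-interval series
#'
#' Container for a beat-to-beat interval record: interval durations in
#' milliseconds, cumulative beat times in seconds, a per-beat annotation
#' flag and subject metadata. This is the raw input of the processing
#' chain; [filter_artifacts()] converts it into an artifact-corrected NN
#' series (class `nn_series`, which inherits from `rr_series`).
#'
#' @param intervals numeric vector of RR intervals in milliseconds; all
#'   values must be positive.
#' @param flags per-beat annotation, one of `"normal"`, `"artifact"`,
#'   `"ectopic"`, `"corrected"`. Recycled if length 1.
#' @param meta list of subject metadata: `subject_id`, `age` (years),
#'   `group` (e.g. `"control"` or `"hypertensive"`), `activity`.
#'
#' @return An object of class `rr_series`: a list with elements
#'   `intervals` (ms), `times` (cumulative seconds), `flags`, `meta`.
#' @examples
#' rr <- rr_series(rep(800, 10), meta = list(subject_id = "s1"))
#' rr$times[10]   # 8 seconds
#' @export
rr_series <- function(intervals, flags = "normal", meta = list()) {
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0) {
    stop("'intervals' must contain at least one beat", call. = FALSE)
  }
  if (any(!is.finite(intervals)) || any(intervals <= 0)) {
    stop("'intervals' must be positive and finite (milliseconds)",
         call. = FALSE)
  }
  flags <- rep_len(as.character(flags), length(intervals))
  bad <- setdiff(unique(flags), c("normal", "artifact", "ectopic", "corrected"))
  if (length(bad) > 0) {
    stop("unknown beat flag(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      intervals = intervals,
      times     = cumsum(intervals) / 1000,
      flags     = flags,
      meta      = meta
    ),
    class = "rr_series"
  )
}

#' @rdname rr_series
#' @param x an `rr_series` object.
#' @param ... ignored.
#' @export
print.rr_series <- function(x, ...) {
  kind <- if (inherits(x, "nn_series")) "NN series" else "RR series"
  cat(sprintf(
    "%s: %d beats, %.1f s, mean RR %.1f ms\n",
    kind, length(x$intervals), duration_s(x), mean(x$intervals)
  ))
  tab <- table(x$flags)
  cat("  flags:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  if (!is.null(x$n_corrected)) {
    cat(sprintf("  corrected beats: %d; detrended: %s\n",
                x$n_corrected, isTRUE(x$detrended)))
  }
  if (length(x$meta) > 0) {
    cat("  meta:", paste(sprintf("%s=%s", names(x$meta),
                                 vapply(x$meta, format, "")), collapse = " "), "\n")
  }
  invisible(x)
}

# Total record duration in seconds (sum of intervals).
#' Record duration
#'
#' @param x an `rr_series` (or `nn_series`) object.
#' @return duration of the record in seconds.
#' @export
duration_s <- function(x) {
  stopifnot(inherits(x, "rr_series"))
  sum(x$intervals) / 1000
}

# Build an nn_series from corrected intervals, preserving metadata.
new_nn_series <- function(intervals, flags, meta, n_corrected,
                          detrended = FALSE) {
  out <- rr_series(intervals, flags, meta)
  out$n_corrected <- as.integer(n_corrected)
  out$detrended <- isTRUE(detrended)
  class(out) <- c("nn_series", class(out))
  out
}

# single-letter disk codes for beat flags
.flag_codes <- c(normal = "N", artifact = "A", ectopic = "E", corrected = "C")

#' Read and write RR records as plain text
#'
#' The on-disk format is one line per beat, `<rr_ms> <flag>`, where the
#' flag is a single letter: `N` normal, `A` artifact, `E` ectopic,
#' `C` corrected. Metadata is stored in `# key: value` header lines.
#' `read_rr()` also accepts a bare one-column list of intervals in
#' milliseconds (all beats are then flagged normal).
#'
#' @param x an `rr_series` object.
#' @param path file path.
#' @return `read_rr()` returns an `rr_series`; `write_rr()` returns `path`
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' write_rr(rr_series(rep(800, 5)), f)
#' read_rr(f)
#' @export
write_rr <- function(x, path) {
  stopifnot(inherits(x, "rr_series"))
  hdr <- character(0)
  for (k in names(x$meta)) {
    v <- x$meta[[k]]
    if (!is.null(v) && !is.na(v)[1]) {
      hdr <- c(hdr, sprintf("# %s: %s", k, format(v)))
    }
  }
  body <- sprintf("%.6g %s", x$intervals, .flag_codes[x$flags])
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_rr
#' @export
read_rr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  body <- trimws(grep("^#", lines, value = TRUE, invert = TRUE))
  body <- body[nzchar(body)]
  if (length(body) == 0) stop("no beats found in ", path, call. = FALSE)

  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) {
      key <- trimws(m[2]); val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num) && key %in% c("age")) num else val
    }
  }

  parts <- strsplit(body, "\\s+")
  rr <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
  if (any(is.na(rr))) stop("unparseable interval line in ", path, call. = FALSE)
  codes <- vapply(parts, function(p) if (length(p) >= 2) p[2] else "N", "")
  names_by_code <- setNames(names(.flag_codes), .flag_codes)
  if (any(!codes %in% names(names_by_code))) {
    stop("unknown beat flag code in ", path, call. = FALSE)
  }
  rr_series(rr, names_by_code[codes], meta)
}
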