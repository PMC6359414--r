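#' Group-wise feature comparison
#'
#' Per-feature mean and standard error for each group, plus pairwise
#' significance bits from two-sample t-tests: the pooled-variance test
#' when the two groups have equal size, Welch's test for unequal sizes.
#' A comparison is emitted as 1 when the difference is significant at
#' `alpha`, else 0, matching the 0/1 columns of a raw-versus-corrected,
#' patient-versus-control feature table.
#'
#' Degenerate features (zero variance in both groups) fall back to the
#' exact-equality convention: bit 1 if the means differ, else 0.
#'
#' @param features a `data.frame` with one row per record, feature
#'   columns, and a grouping column.
#' @param group name of the grouping column (default `"group"`), or a
#'   vector of group labels of length `nrow(features)`.
#' @param comparisons list of length-2 character vectors naming the
#'   group pairs to test; defaults to all pairs of observed groups.
#' @param alpha significance level; default 0.05.
#' @param feature_cols which columns to compare; defaults to all numeric
#'   columns except the grouping column.
#' @return A `data.frame` with one row per feature: `mean_<g>` and
#'   `se_<g>` for each group and `sig_<a>_vs_<b>` bits per comparison.
#' @examples
#' df <- data.frame(g = rep(c("a", "b"), each = 20),
#'                  f = c(rnorm(20), rnorm(20, 5)))
#' compare_groups(df, group = "g")$sig_a_vs_b  # 1
#' @export
compare_groups <- function(features, group = "group", comparisons = NULL,
                           alpha = 0.05, feature_cols = NULL) {
  stopifnot(is.data.frame(features))
  if (length(group) == 1 && group %in% names(features)) {
    g <- as.character(features[[group]])
    drop_col <- group
  } else {
    stopifnot(length(group) == nrow(features))
    g <- as.character(group)
    drop_col <- character(0)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  }
  levels <- unique(g)
  if (any(table(g) < 2)) stop("each group needs at least 2 rows", call. = FALSE)
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(features)[vapply(features, is.numeric,
                                                   TRUE)], drop_col)
  }
  if (is.null(comparisons)) {
    comparisons <- utils::combn(levels, 2, simplify = FALSE)
  }

  rows <- lapply(feature_cols, function(f) {
    v <- features[[f]]
    row <- list(feature = f)
    for (lv in levels) {
      vi <- v[g == lv & !is.na(v)]
      row[[paste0("mean_", lv)]] <- mean(vi)
      row[[paste0("se_", lv)]] <- sd(vi) / sqrt(length(vi))
    }
    for (cmp in comparisons) {
      a <- v[g == cmp[1] & !is.na(v)]
      b <- v[g == cmp[2] & !is.na(v)]
      bit <- if (sd(a) == 0 && sd(b) == 0) {
        as.integer(mean(a) != mean(b))
      } else {
        tt <- tryCatch(
          t.test(a, b, var.equal = length(a) == length(b)),
          error = function(e) NULL)
        if (is.null(tt)) NA_integer_ else as.integer(tt$p.value < alpha)
      }
      row[[sprintf("sig_%s_vs_%s", cmp[1], cmp[2])]] <- bit
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
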