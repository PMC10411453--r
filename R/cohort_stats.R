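# Validate a per-group summary table (columns group, n, mean, sd).
as_group_summaries <- function(summaries) {
  need <- c("group", "n", "mean", "sd")
  if (!is.data.frame(summaries) || !all(need %in% names(summaries)))
    octamv_stop(paste("group summaries must have columns:",
                      paste(need, collapse = ", ")), "octamv_schema_error")
  if (any(summaries$n < 2))
    octamv_stop("every group needs n >= 2", "octamv_degenerate_group")
  if (any(summaries$sd < 0))
    octamv_stop("SDs must be non-negative", "octamv_invalid_parameter")
  summaries
}

#' Filter a cohort by signal strength
#'
#' Scan-quality filter: retains eyes whose signal strength index is at least
#' `threshold` (the conventional cutoff is 55; scans with SSI below it are
#' excluded from analysis). The number of removed rows is reported via
#' `message()`.
#'
#' @param cohort Cohort data frame with an `ssi` column.
#' @param threshold Minimum acceptable SSI (default 55).
#' @return The retained rows, attribute `n_removed` recording the exclusions.
#' @export
filter_by_ssi <- function(cohort, threshold = 55) {
  if (!is.data.frame(cohort) || !"ssi" %in% names(cohort))
    octamv_stop("cohort has no `ssi` column", "octamv_schema_error")
  keep <- cohort$ssi >= threshold
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("filter_by_ssi: removed %d of %d rows (SSI < %s)",
                  sum(!keep), length(keep), format(threshold)))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Per-group summaries of a cohort metric
#'
#' @param cohort Cohort data frame with `group` and the metric column.
#' @param metric Name of the metric column.
#' @return Data frame `group`, `n`, `mean`, `sd` (sample SD, denominator
#'   n - 1), ordered by severity.
#' @export
summarize_groups <- function(cohort, metric) {
  if (!is.data.frame(cohort) || !all(c("group", metric) %in% names(cohort)))
    octamv_stop(sprintf("cohort must have columns `group` and `%s`", metric),
                "octamv_schema_error")
  groups <- if (is.factor(cohort$group)) {
    intersect(levels(cohort$group), unique(as.character(cohort$group)))
  } else intersect(severity_levels(), unique(cohort$group))
  if (!length(groups)) groups <- unique(as.character(cohort$group))
  out <- do.call(rbind, lapply(groups, function(g) {
    x <- cohort[[metric]][cohort$group == g]
    if (length(x) < 2L)
      octamv_stop(sprintf("group `%s` has fewer than 2 rows", g),
                  "octamv_degenerate_group")
    data.frame(group = g, n = length(x), mean = mean(x), sd = sd(x),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Pooled within-group variance (MS_within) and error df from summaries.
pooled_ms_within <- function(summaries) {
  df2 <- sum(summaries$n) - nrow(summaries)
  list(ms = sum((summaries$n - 1) * summaries$sd^2) / df2, df = df2)
}

#' One-way ANOVA from group summaries
#'
#' Omnibus F test computed directly from per-group (n, mean, SD):
#' between-group sums of squares from the means about the weighted grand
#' mean, within-group sums of squares pooled as
#' \eqn{\sum_i (n_i - 1)\sigma_i^2}. Identical to ANOVA on raw data whenever
#' the raw data realize the summaries exactly.
#'
#' @param summaries Data frame `group`, `n`, `mean`, `sd` (one row per
#'   group).
#' @return List with `F`, `df1` (k - 1), `df2` (N - k), `p`, `ms_within`.
#' @export
oneway_anova <- function(summaries) {
  summaries <- as_group_summaries(summaries)
  k <- nrow(summaries)
  if (k < 2L)
    octamv_stop("need at least 2 groups", "octamv_invalid_parameter")
  N <- sum(summaries$n)
  grand <- sum(summaries$n * summaries$mean) / N
  ss_b <- sum(summaries$n * (summaries$mean - grand)^2)
  w <- pooled_ms_within(summaries)
  if (w$ms == 0)
    octamv_stop("all groups are identical constants (zero within-group variance)",
                "octamv_zero_variance")
  f <- (ss_b / (k - 1)) / w$ms
  list(F = f, df1 = k - 1L, df2 = w$df,
       p = pf(f, k - 1, w$df, lower.tail = FALSE), ms_within = w$ms)
}

#' Linear trend-contrast F across ordered groups ("p for trend")
#'
#' Tests whether the group means follow a linear trend across the ordered
#' severity groups, as a single-df contrast within the one-way ANOVA. For
#' contrast coefficients \eqn{c_i} (summing to zero) the contrast estimate
#' is \eqn{L = \sum_i c_i \bar{x}_i} and
#' \deqn{F = L^2 / (MS_w \sum_i c_i^2 / n_i), \quad df = (1, N - k),}
#' with \eqn{MS_w} pooled from the group SDs. The default coefficients
#' (-3, -1, 1, 3) are the equally spaced linear contrast for four groups;
#' the F statistic is invariant to rescaling the coefficients.
#'
#' @param summaries Data frame `group`, `n`, `mean`, `sd`, one row per group
#'   in severity order.
#' @param coefficients Contrast coefficients, same length as groups, summing
#'   to zero.
#' @return List with `F`, `df1` (= 1), `df2`, `p` (two-sided, from
#'   F(1, N - k)), `estimate` (L) and `coefficients`.
#' @export
trend_contrast_F <- function(summaries, coefficients = c(-3, -1, 1, 3)) {
  summaries <- as_group_summaries(summaries)
  k <- nrow(summaries)
  if (length(coefficients) != k)
    octamv_stop("one coefficient per group is required", "octamv_invalid_contrast")
  if (abs(sum(coefficients)) > 1e-8 * max(1, sum(abs(coefficients))))
    octamv_stop("contrast coefficients must sum to zero", "octamv_invalid_contrast")
  w <- pooled_ms_within(summaries)
  if (w$ms == 0)
    octamv_stop("zero within-group variance", "octamv_zero_variance")
  L <- sum(coefficients * summaries$mean)
  f <- L^2 / (w$ms * sum(coefficients^2 / summaries$n))
  list(F = f, df1 = 1L, df2 = w$df,
       p = pf(f, 1, w$df, lower.tail = FALSE),
       estimate = L, coefficients = coefficients)
}

#' Bonferroni-adjusted pairwise comparisons from group summaries
#'
#' All pairwise two-sided t tests using the pooled within-group variance
#' (error df N - k), with p values multiplied by the number of comparisons
#' C(k, 2) and capped at 1.
#'
#' @param summaries Data frame `group`, `n`, `mean`, `sd`.
#' @return Data frame with one row per pair: `group1`, `group2`, `diff`,
#'   `t`, `p`, `p_adj`.
#' @export
bonferroni_pairwise <- function(summaries) {
  summaries <- as_group_summaries(summaries)
  k <- nrow(summaries)
  if (k < 2L)
    octamv_stop("need at least 2 groups", "octamv_invalid_parameter")
  w <- pooled_ms_within(summaries)
  if (w$ms == 0)
    octamv_stop("zero within-group variance", "octamv_zero_variance")
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  m <- nrow(pairs)
  out <- do.call(rbind, lapply(seq_len(m), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    d <- summaries$mean[j] - summaries$mean[i]
    se <- sqrt(w$ms * (1 / summaries$n[i] + 1 / summaries$n[j]))
    tt <- d / se
    p <- 2 * pt(-abs(tt), w$df)
    data.frame(group1 = summaries$group[i], group2 = summaries$group[j],
               diff = d, t = tt, p = p, p_adj = min(1, p * m),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
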