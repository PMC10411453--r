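# Midrank Mann-Whitney AUC: P(pos > neg) + 0.5 P(tie).
mann_whitney_auc <- function(scores, positive) {
  r <- rank(scores)
  n1 <- as.numeric(sum(positive)); n0 <- as.numeric(sum(!positive))
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' Sweeps a decision threshold over the distinct score values (ties
#' grouped): at threshold t an eye is called diseased when its oriented
#' score is >= t. Metrics that decrease with disease use
#' `orientation = "lower"`, which negates the scores before thresholding so
#' that higher oriented scores always indicate disease.
#'
#' @param scores Numeric scores, one per eye.
#' @param labels Binary disease labels (logical, 0/1, or a two-level
#'   factor whose second level is taken as positive).
#' @param orientation `"higher"` if larger scores indicate disease,
#'   `"lower"` if smaller scores do.
#' @return A `roc_curve`: points data frame (`threshold`, `sensitivity`,
#'   `specificity`, thresholds on the oriented scale) plus class counts.
#' @export
empirical_roc <- function(scores, labels, orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels))
    octamv_stop("scores and labels must not contain NA", "octamv_invalid_labels")
  if (length(scores) != length(labels))
    octamv_stop("scores and labels differ in length", "octamv_invalid_labels")
  if (!any(labels) || all(labels))
    octamv_stop("both classes must be present", "octamv_invalid_labels")
  s <- if (orientation == "lower") -scores else scores
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  n1 <- sum(labels); n0 <- sum(!labels)
  sens <- vapply(thr, function(t) sum(s >= t & labels) / n1, numeric(1))
  spec <- vapply(thr, function(t) sum(s < t & !labels) / n0, numeric(1))
  structure(list(points = data.frame(threshold = thr, sensitivity = sens,
                                     specificity = spec),
                 orientation = orientation, scores = s, labels = labels,
                 n_positive = n1, n_negative = n0),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, %d positive / %d negative (%s-score disease)\n",
              nrow(x$points), x$n_positive, x$n_negative, x$orientation))
  invisible(x)
}

#' Area under an ROC curve
#'
#' Trapezoidal area under the empirical curve, equal to the midrank
#' Mann-Whitney statistic P(score_pos > score_neg) + 0.5 P(tie) on the
#' oriented scores.
#'
#' @param curve A `roc_curve`.
#' @return An `auc_result`: list with `auc`, `n_positive`, `n_negative`,
#'   `method = "empirical"`.
#' @export
roc_auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  auc_result(mann_whitney_auc(curve$scores, curve$labels),
             curve$n_positive, curve$n_negative, "empirical")
}

auc_result <- function(auc, n_positive, n_negative, method) {
  structure(list(auc = auc, n_positive = n_positive, n_negative = n_negative,
                 method = method), class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("<auc_result> AUC = %.3f (%s; %s positive / %s negative)\n",
              x$auc, x$method, x$n_positive, x$n_negative))
  invisible(x)
}

#' Optimal (Youden) cutoff of an ROC curve
#'
#' The operating threshold maximizing sensitivity + specificity; ties are
#' broken toward higher specificity.
#'
#' @param curve A `roc_curve`.
#' @return List with `threshold` on the original metric scale, `direction`
#'   (`">="` or `"<="`: the comparison that calls an eye diseased),
#'   `sensitivity`, `specificity` and `youden` (= sens + spec - 1).
#' @export
youden_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  p <- curve$points
  j <- p$sensitivity + p$specificity
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[which.max(p$specificity[best])]
  lower <- curve$orientation == "lower"
  list(threshold = if (lower) -p$threshold[best] else p$threshold[best],
       direction = if (lower) "<=" else ">=",
       sensitivity = p$sensitivity[best],
       specificity = p$specificity[best], youden = j[best] - 1)
}

#' Closed-form binormal-mixture AUC
#'
#' Normal-theory AUC for discriminating a Gaussian negative class from a
#' mixture of Gaussian positive components (e.g. DR = NPDR + PDR pooled
#' against healthy eyes), from group summaries alone:
#' \deqn{AUC = \sum_j w_j\,\Phi\!\big(|\mu_{neg} - \mu_j| /
#'   \sqrt{\sigma_{neg}^2 + \sigma_j^2}\big),}
#' exact under the Gaussian model when every diseased component shifts the
#' mean in the same direction.
#'
#' @param negative List or one-row data frame with `mean` and `sd` of the
#'   negative (healthy) class.
#' @param positives Data frame with columns `weight`, `mean`, `sd`, one row
#'   per diseased component; weights must be positive and sum to 1.
#' @return An `auc_result` with `method = "binormal_mixture"`
#'   (`n_positive`/`n_negative` are `NA`: the reconstruction uses summaries,
#'   not eyes).
#' @export
binormal_mixture_auc <- function(negative, positives) {
  if (!all(c("weight", "mean", "sd") %in% names(positives)))
    octamv_stop("`positives` needs columns weight, mean, sd", "octamv_schema_error")
  w <- positives$weight
  if (any(w <= 0) || abs(sum(w) - 1) > 1e-8)
    octamv_stop("weights must be positive and sum to 1", "octamv_invalid_parameter")
  if (negative$sd <= 0 || any(positives$sd <= 0))
    octamv_stop("SDs must be positive", "octamv_invalid_parameter")
  auc <- sum(w * pnorm(abs(negative$mean - positives$mean) /
                         sqrt(negative$sd^2 + positives$sd^2)))
  auc_result(auc, NA_integer_, NA_integer_, "binormal_mixture")
}

#' Monte Carlo AUC for a binormal mixture
#'
#' Stochastic cross-check of [binormal_mixture_auc()]: samples `n_per_class`
#' Gaussian scores for each class (positive scores from the mixture), orients
#' them so that disease increases the score, and computes the empirical
#' midrank AUC. Converges to the closed form as `n_per_class` grows.
#'
#' @inheritParams binormal_mixture_auc
#' @param n_per_class Samples per class (>= 100).
#' @param seed RNG seed.
#' @return An `auc_result` with `method = "monte_carlo"`.
#' @export
monte_carlo_auc <- function(negative, positives, n_per_class = 1e5, seed = 1L) {
  if (n_per_class < 100)
    octamv_stop("`n_per_class` must be at least 100", "octamv_invalid_parameter")
  w <- positives$weight
  if (any(w <= 0) || abs(sum(w) - 1) > 1e-8)
    octamv_stop("weights must be positive and sum to 1", "octamv_invalid_parameter")
  with_seed(seed, {
    neg <- rnorm(n_per_class, negative$mean, negative$sd)
    comp <- sample.int(nrow(positives), n_per_class, replace = TRUE, prob = w)
    pos <- rnorm(n_per_class, positives$mean[comp], positives$sd[comp])
    # orient so disease raises the score (mirrors the |.| in the closed form)
    if (sum(w * positives$mean) < negative$mean) { neg <- -neg; pos <- -pos }
    auc_result(mann_whitney_auc(c(neg, pos),
                                c(rep(FALSE, n_per_class), rep(TRUE, n_per_class))),
               n_per_class, n_per_class, "monte_carlo")
  })
}
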