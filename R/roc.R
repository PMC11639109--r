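#' ROC curve points for an integer-valued score
#'
#' Sweeps every candidate cut-off c from `min(scores)` to `max(scores) + 1`,
#' classifying `score >= c` as positive, so the curve is anchored at
#' (FPR 1, sens 1) and (FPR 0, sens 0).
#'
#' @param scores Numeric score per observation (higher = more test-positive).
#' @param labels Logical (or 0/1) reference diagnosis per observation.
#' @return A tibble of class `cam_roc` with columns `cutoff`, `sensitivity`,
#'   `specificity`, `fpr`, ordered by increasing cut-off.
#' @examples
#' roc_points(c(0, 1, 2, 5), c(FALSE, FALSE, TRUE, TRUE))
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) abort("Lengths differ.")
  if (anyNA(scores) || anyNA(labels)) abort("Missing values are not allowed.")
  if (!any(labels) || all(labels)) {
    abort("Need at least one positive and one negative label.")
  }
  cutoffs <- seq(floor(min(scores)), floor(max(scores)) + 1)
  pos <- scores[labels]
  neg <- scores[!labels]
  out <- tibble(
    cutoff = cutoffs,
    sensitivity = vapply(cutoffs, function(c) mean(pos >= c), numeric(1)),
    specificity = vapply(cutoffs, function(c) mean(neg < c), numeric(1))
  ) %>%
    mutate(fpr = 1 - .data$specificity)
  class(out) <- c("cam_roc", class(out))
  out
}

#' Area under the ROC curve
#'
#' Computes the AUROC two ways and asserts that they agree: the trapezoidal
#' area under the threshold-sweep curve from [roc_points()], and the
#' Mann-Whitney midrank statistic P(score_pos > score_neg) + 0.5 P(tie).
#' For a test dichotomized at a single cut-off this equals
#' (sensitivity + specificity) / 2 exactly.
#'
#' @inheritParams roc_points
#' @return A single numeric AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0, 1, 2, 5), c(FALSE, FALSE, TRUE, TRUE))
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  curve <- roc_points(scores, labels)
  # trapezoid over (fpr, sens), swept from (1,1) down to (0,0)
  o <- order(curve$fpr, curve$sensitivity)
  x <- curve$fpr[o]; y <- curve$sensitivity[o]
  auc_trap <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  # Mann-Whitney with midranks
  m <- sum(labels); n <- sum(!labels)
  r <- rank(scores, ties.method = "average")
  auc_mw <- (sum(r[labels]) - m * (m + 1) / 2) / (m * n)
  if (abs(auc_trap - auc_mw) > 1e-10) {
    abort("Internal inconsistency: trapezoid and Mann-Whitney AUROC disagree.")
  }
  auc_mw
}

# placement values: for each positive, the fraction of negatives it beats
# (ties count half), and vice versa; their means equal the AUROC
delong_placements <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), numeric(1))
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), numeric(1))
  list(v10 = v10, v01 = v01)
}

#' AUROC with DeLong confidence interval
#'
#' Nonparametric variance for the Mann-Whitney AUROC from the sample
#' variances of the positive- and negative-placement values:
#' var = S10/m + S01/n with m positives and n negatives. The normal
#' interval is truncated to `[0, 1]`.
#'
#' @inheritParams roc_points
#' @param alpha Two-sided error level (default 0.05).
#' @return A one-row tibble: `auc`, `se`, `conf.low`, `conf.high`, `n_pos`,
#'   `n_neg`, `method`.
#' @examples
#' delong_ci(c(0, 1, 1, 2, 3, 5), c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE))
#' @export
delong_ci <- function(scores, labels, alpha = 0.05) {
  labels <- as.logical(labels)
  if (sum(labels) < 2 || sum(!labels) < 2) {
    abort("DeLong variance needs at least two positives and two negatives.")
  }
  auc <- auroc(scores, labels)
  pl <- delong_placements(scores, labels)
  v <- var(pl$v10) / length(pl$v10) + var(pl$v01) / length(pl$v01)
  se <- sqrt(v)
  z <- z_alpha(alpha)
  tibble(
    auc = auc, se = se,
    conf.low = max(0, auc - z * se), conf.high = min(1, auc + z * se),
    n_pos = sum(labels), n_neg = sum(!labels), method = "delong"
  )
}

#' Youden-optimal cut-off
#'
#' Selects the cut-off maximizing the Youden index
#' J = sensitivity + specificity - 1. Ties are broken toward the lowest
#' cut-off, favouring sensitivity.
#'
#' @param points A data frame with columns `cutoff`, `sensitivity`,
#'   `specificity` (e.g. a [roc_points()] result).
#' @return The selected cut-off (same type as `points$cutoff`).
#' @examples
#' youden_optimal(tibble::tibble(
#'   cutoff = 3:5,
#'   sensitivity = c(0.96, 0.89, 0.83),
#'   specificity = c(0.94, 0.98, 0.99)
#' ))
#' @export
youden_optimal <- function(points) {
  stopifnot(all(c("cutoff", "sensitivity", "specificity") %in% names(points)))
  if (nrow(points) == 0) abort("`points` is empty.")
  j <- points$sensitivity + points$specificity - 1
  o <- order(points$cutoff)
  j <- j[o]
  points$cutoff[o][which.max(j)]
}
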