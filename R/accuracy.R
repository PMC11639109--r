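#' Confusion counts for an index test against a reference standard
#'
#' @param tp,fp,fn,tn Non-negative integer counts of true positives, false
#'   positives, false negatives and true negatives.
#' @return An object of class `confusion_counts`.
#' @examples
#' confusion_counts(tp = 52, fp = 32, fn = 2, tn = 538)
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    abort("Counts must be non-negative whole numbers.")
  }
  if (sum(counts) == 0) abort("At least one observation is required.")
  structure(
    as.list(setNames(as.integer(counts), names(counts))),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf(
    "2x2 confusion counts (n = %d)\n  tp = %d  fp = %d\n  fn = %d  tn = %d\n",
    x$tp + x$fp + x$fn + x$tn, x$tp, x$fp, x$fn, x$tn
  ))
  invisible(x)
}

#' @export
as_tibble.confusion_counts <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn)
}

#' Cross-tabulate index and reference calls
#'
#' @param index_positive,reference_positive Logical vectors of equal length
#'   with no missing values: the index-test call and the reference-standard
#'   diagnosis for each observation.
#' @return A [confusion_counts] object.
#' @examples
#' build_confusion(c(TRUE, FALSE, TRUE, FALSE), c(TRUE, TRUE, FALSE, FALSE))
#' @export
build_confusion <- function(index_positive, reference_positive) {
  if (length(index_positive) != length(reference_positive)) {
    abort("Index and reference vectors must have equal length.")
  }
  if (length(index_positive) == 0) abort("Empty input.")
  if (anyNA(index_positive) || anyNA(reference_positive)) {
    abort("Missing values are not allowed; exclude unassessable records first.")
  }
  i <- as.logical(index_positive)
  r <- as.logical(reference_positive)
  confusion_counts(
    tp = sum(i & r), fp = sum(i & !r), fn = sum(!i & r), tn = sum(!i & !r)
  )
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Computes the exact two-sided interval for a binomial proportion by the
#' beta-quantile formulation: the lower bound is the `alpha/2` quantile of
#' Beta(x, n - x + 1) (0 when x = 0) and the upper bound the `1 - alpha/2`
#' quantile of Beta(x + 1, n - x) (1 when x = n). Coverage is conservative
#' (at least nominal).
#'
#' @param x Number of successes (vectorized).
#' @param n Number of trials.
#' @param alpha Two-sided error level (default 0.05 for a 95% CI).
#' @return A tibble with columns `x`, `n`, `estimate`, `conf.low`,
#'   `conf.high`, `alpha`, `method`.
#' @examples
#' clopper_pearson(52, 54)
#' @export
clopper_pearson <- function(x, n, alpha = 0.05) {
  if (length(alpha) != 1 || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single value in (0, 1).")
  }
  m <- max(length(x), length(n))
  x <- rep_len(x, m)
  n <- rep_len(n, m)
  if (any(is.na(x)) || any(is.na(n)) || any(n < 1) || any(x < 0) ||
      any(x > n) || any(x != floor(x)) || any(n != floor(n))) {
    abort("Need whole numbers with 0 <= x <= n and n >= 1.")
  }
  lo <- ifelse(x == 0, 0, qbeta(alpha / 2, x, n - x + 1))
  hi <- ifelse(x == n, 1, qbeta(1 - alpha / 2, x + 1, n - x))
  tibble(
    x = as.integer(x), n = as.integer(n), estimate = x / n,
    conf.low = lo, conf.high = hi, alpha = alpha, method = "clopper_pearson"
  )
}

#' Sensitivity, specificity and predictive values with exact intervals
#'
#' Computes the four 2x2 proportions -- sensitivity tp/(tp+fn), specificity
#' tn/(tn+fp), positive predictive value tp/(tp+fp) and negative predictive
#' value tn/(tn+fn) -- each with a Clopper-Pearson interval. A zero
#' denominator leaves the corresponding row `NA` and flagged undefined.
#'
#' @param counts A [confusion_counts] object.
#' @param alpha Two-sided error level (default 0.05).
#' @return A tibble with columns `metric`, `x`, `n`, `estimate`, `conf.low`,
#'   `conf.high`, `defined`.
#' @examples
#' accuracy_estimates(confusion_counts(52, 32, 2, 538))
#' @export
accuracy_estimates <- function(counts, alpha = 0.05) {
  stopifnot(inherits(counts, "confusion_counts"))
  spec_tbl <- tibble(
    metric = c("sensitivity", "specificity", "ppv", "npv"),
    x = c(counts$tp, counts$tn, counts$tp, counts$tn),
    n = c(
      counts$tp + counts$fn, counts$tn + counts$fp,
      counts$tp + counts$fp, counts$tn + counts$fn
    )
  )
  out <- spec_tbl %>%
    mutate(defined = .data$n > 0)
  est <- purrr::map2(out$x, out$n, function(x, n) {
    if (n == 0) {
      tibble(estimate = NA_real_, conf.low = NA_real_, conf.high = NA_real_)
    } else {
      clopper_pearson(x, n, alpha)[, c("estimate", "conf.low", "conf.high")]
    }
  })
  dplyr::bind_cols(out, dplyr::bind_rows(est))[
    , c("metric", "x", "n", "estimate", "conf.low", "conf.high", "defined")
  ]
}

#' Positive and negative likelihood ratios with log-method intervals
#'
#' LR+ = sensitivity / (1 - specificity), LR- = (1 - sensitivity) /
#' specificity. Confidence intervals use the log-normal (Simel) method:
#' se(ln LR+) = sqrt(1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn)) and analogously
#' with fn and tn for LR-. Degenerate cells are flagged rather than silently
#' numeric: fp = 0 gives an infinite LR+ with undefined lower bound; fn = 0
#' gives LR- = 0 with undefined upper bound.
#'
#' @inheritParams accuracy_estimates
#' @return A tibble with columns `metric` (`lr_positive`, `lr_negative`),
#'   `estimate`, `conf.low`, `conf.high`, `method`, `degenerate`.
#' @examples
#' likelihood_ratios(confusion_counts(52, 32, 2, 538))
#' @export
likelihood_ratios <- function(counts, alpha = 0.05) {
  stopifnot(inherits(counts, "confusion_counts"))
  z <- z_alpha(alpha)
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  if (tp + fn == 0 || tn + fp == 0) {
    abort("Likelihood ratios need at least one positive and one negative reference observation.")
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)

  if (fp == 0) {
    pos <- tibble(
      metric = "lr_positive", estimate = Inf, conf.low = NaN, conf.high = Inf,
      method = "log_normal", degenerate = TRUE
    )
  } else {
    lr <- sens / (1 - spec)
    if (tp == 0) {
      pos <- tibble(
        metric = "lr_positive", estimate = 0, conf.low = 0, conf.high = NaN,
        method = "log_normal", degenerate = TRUE
      )
    } else {
      se <- sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn))
      pos <- tibble(
        metric = "lr_positive", estimate = lr,
        conf.low = exp(log(lr) - z * se), conf.high = exp(log(lr) + z * se),
        method = "log_normal", degenerate = FALSE
      )
    }
  }

  if (fn == 0) {
    neg <- tibble(
      metric = "lr_negative", estimate = 0, conf.low = 0, conf.high = NaN,
      method = "log_normal", degenerate = TRUE
    )
  } else if (tn == 0) {
    neg <- tibble(
      metric = "lr_negative", estimate = Inf, conf.low = NaN, conf.high = Inf,
      method = "log_normal", degenerate = TRUE
    )
  } else {
    lr <- (1 - sens) / spec
    se <- sqrt(1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (fp + tn))
    neg <- tibble(
      metric = "lr_negative", estimate = lr,
      conf.low = exp(log(lr) - z * se), conf.high = exp(log(lr) + z * se),
      method = "log_normal", degenerate = FALSE
    )
  }
  bind_rows(pos, neg)
}
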