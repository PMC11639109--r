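#' Cohen's kappa for two raters with asymptotic confidence interval
#'
#' Chance-corrected agreement between two raters making binary calls on the
#' same observations: kappa = (p_o - p_e) / (1 - p_e), where p_o is the
#' observed agreement and p_e the agreement expected from the marginal
#' rating rates. The standard error is the Fleiss-Cohen-Everitt large-sample
#' estimate and the interval is normal-approximate, truncated to `[-1, 1]`.
#'
#' @param rater_a,rater_b Logical vectors of equal length (>= 2), complete
#'   paired ratings.
#' @param alpha Two-sided error level (default 0.05).
#' @return A one-row tibble: `kappa`, `p_o`, `p_e`, `se`, `conf.low`,
#'   `conf.high`, `n`. When both raters are constant and identical, chance
#'   agreement is 1 and kappa is undefined (`NA` with a warning).
#' @examples
#' cohen_kappa(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, FALSE, FALSE))
#' @export
cohen_kappa <- function(rater_a, rater_b, alpha = 0.05) {
  a <- as.logical(rater_a)
  b <- as.logical(rater_b)
  if (length(a) != length(b)) abort("Rating vectors must have equal length.")
  if (length(a) < 2) abort("Need at least two paired ratings.")
  if (anyNA(a) || anyNA(b)) abort("Paired ratings must be complete.")
  n <- length(a)

  # 2x2 table of proportions: rows rater A (+, -), columns rater B (+, -)
  p <- matrix(
    c(mean(a & b), mean(a & !b), mean(!a & b), mean(!a & !b)),
    nrow = 2, byrow = TRUE
  )
  row_m <- rowSums(p)
  col_m <- colSums(p)
  p_o <- p[1, 1] + p[2, 2]
  p_e <- sum(row_m * col_m)
  if (1 - p_e < .Machine$double.eps) {
    warn("Both raters constant and identical: chance agreement is 1, kappa undefined.")
    return(tibble(
      kappa = NA_real_, p_o = p_o, p_e = p_e, se = NA_real_,
      conf.low = NA_real_, conf.high = NA_real_, n = n
    ))
  }
  k <- (p_o - p_e) / (1 - p_e)

  # Fleiss, Cohen & Everitt large-sample variance of the kappa estimate
  diag_term <- sum(diag(p) * (1 - (row_m + col_m) * (1 - k))^2)
  off <- p * (outer(col_m, rep(1, 2)) + outer(rep(1, 2), row_m))^2
  # off[i, j] needs (col_m[i] + row_m[j])^2 for i != j
  off_term <- (1 - k)^2 * (off[1, 2] + off[2, 1])
  c_term <- (k - p_e * (1 - k))^2
  v <- (diag_term + off_term - c_term) / (n * (1 - p_e)^2)
  se <- sqrt(max(v, 0))
  z <- z_alpha(alpha)
  tibble(
    kappa = k, p_o = p_o, p_e = p_e, se = se,
    conf.low = max(-1, k - z * se), conf.high = min(1, k + z * se), n = n
  )
}
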