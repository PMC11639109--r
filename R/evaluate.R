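# one wide row of performance metrics for a dichotomized test vs reference
dichotomous_performance <- function(index_positive, reference_positive, alpha) {
  counts <- build_confusion(index_positive, reference_positive)
  acc <- accuracy_estimates(counts, alpha)
  lrs <- likelihood_ratios(counts, alpha)
  scores <- as.integer(index_positive)
  labels <- as.logical(reference_positive)
  dl <- if (sum(labels) >= 2 && sum(!labels) >= 2) {
    delong_ci(scores, labels, alpha)
  } else {
    tibble(auc = NA_real_, se = NA_real_, conf.low = NA_real_,
           conf.high = NA_real_)
  }
  wide <- function(metric, tbl) {
    row <- tbl[tbl$metric == metric, ]
    setNames(
      list(row$estimate, row$conf.low, row$conf.high),
      paste0(metric, c("", "_low", "_high"))
    )
  }
  tibble::as_tibble(c(
    list(
      n = counts$tp + counts$fp + counts$fn + counts$tn,
      tp = counts$tp, fp = counts$fp, fn = counts$fn, tn = counts$tn
    ),
    wide("sensitivity", acc), wide("specificity", acc),
    wide("ppv", acc), wide("npv", acc),
    wide("lr_positive", lrs), wide("lr_negative", lrs),
    list(auroc = dl$auc, auroc_low = dl$conf.low, auroc_high = dl$conf.high)
  ))
}

population_masks <- function(data) {
  masks <- list(all = rep(TRUE, nrow(data)))
  if ("cognitive_impairment" %in% names(data)) {
    masks$cognitive_impairment <- !is.na(data$cognitive_impairment) &
      data$cognitive_impairment
  }
  if ("elderly" %in% names(data)) {
    masks$elderly <- !is.na(data$elderly) & data$elderly
  }
  masks
}

#' Evaluate CAM-IMC diagnostic accuracy against the reference standard
#'
#' Runs the full accuracy analysis on scored observations: for each
#' population (all observations, cognitive impairment, elderly) and each
#' score cut-off, sensitivity, specificity, predictive values with
#' Clopper-Pearson intervals, likelihood ratios with log-method intervals,
#' and the AUROC of the dichotomized test with a DeLong interval; the same
#' estimates for each dichotomized item; the AUROC of the raw 0-10 score
#' with its DeLong interval and the Youden-optimal cut-off; and, where two
#' index raters assessed the same patient-day, Cohen's kappa for interrater
#' reliability of the positivity call.
#'
#' The unit of analysis is the observation (one index assessment paired with
#' the same-day reference diagnosis); within-patient clustering is ignored,
#' so confidence intervals are anti-conservative under strong clustering (a
#' warning notes this once per call).
#'
#' @param scored A data frame from [score_cam_imc()] (plus, optionally,
#'   [add_item_flags()] and [add_subgroup_flags()] columns) carrying
#'   `total`, `assessable` and `reference_delirium`; `patient_id`, `day` and
#'   `rater_id` are needed for the kappa block.
#' @param cutoffs Integer cut-offs to tabulate (default `c(3, 4, 5)`).
#' @param alpha Two-sided error level for all intervals (default 0.05).
#' @return An object of class `cam_accuracy`: a list with tibbles
#'   `performance` (population x cutoff), `items` (population x item),
#'   `overall_auroc`, `roc` (raw-score curve, all observations),
#'   `youden_cutoff`, `kappa`, and a record-count `ledger`.
#' @export
cam_evaluate <- function(scored, cutoffs = c(3L, 4L, 5L), alpha = 0.05) {
  needed <- c("total", "assessable", "reference_delirium")
  missing_cols <- setdiff(needed, names(scored))
  if (length(missing_cols) > 0) {
    abort(paste0("`scored` lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (any(cutoffs < 0 | cutoffs > 10)) abort("Cut-offs must lie in 0..10.")
  scored <- as_tibble(scored)
  n_input <- nrow(scored)
  usable <- scored$assessable & !is.na(scored$reference_delirium)
  data <- scored[usable, ]
  if (nrow(data) == 0) abort("No assessable observations with a reference diagnosis.")
  inform("Observations are treated as independent; intervals ignore within-patient clustering.")

  ref <- as.logical(data$reference_delirium)
  masks <- population_masks(data)

  perf <- purrr::imap(masks, function(mask, pop) {
    if (sum(mask) == 0 || length(unique(ref[mask])) < 2) {
      warn(sprintf("Population '%s' empty or single-class; section omitted.", pop))
      return(NULL)
    }
    purrr::map(cutoffs, function(co) {
      dplyr::bind_cols(
        tibble(population = pop, cutoff = as.integer(co)),
        dichotomous_performance(data$total[mask] >= co, ref[mask], alpha)
      )
    }) %>% bind_rows()
  }) %>% bind_rows()

  item_cols <- c(
    fluctuation = "fluctuation_positive",
    consciousness = "consciousness_positive",
    inattention = "inattention_positive",
    disorientation = "disorientation_positive"
  )
  have_items <- item_cols[item_cols %in% names(data)]
  items <- purrr::imap(masks, function(mask, pop) {
    purrr::imap(have_items, function(col, item) {
      flag <- data[[col]][mask]
      ok <- !is.na(flag)
      if (sum(ok) == 0 || length(unique(ref[mask][ok])) < 2) return(NULL)
      dplyr::bind_cols(
        tibble(population = pop, item = item),
        dichotomous_performance(flag[ok], ref[mask][ok], alpha)
      )
    }) %>% bind_rows()
  }) %>% bind_rows()

  if (length(unique(ref)) < 2) {
    warn("Reference diagnoses are single-class; ROC, AUROC and Youden selection are undefined.")
    roc <- NULL
    overall <- tibble(
      auc = NA_real_, se = NA_real_, conf.low = NA_real_,
      conf.high = NA_real_, n_pos = sum(ref), n_neg = sum(!ref),
      method = "delong"
    )
    youden <- NA_integer_
  } else {
    roc <- roc_points(data$total, ref)
    overall <- delong_ci(data$total, ref, alpha)
    youden <- youden_optimal(roc)
  }

  kappa <- NULL
  if (all(c("patient_id", "day", "rater_id") %in% names(data))) {
    pairs <- data %>%
      group_by(.data$patient_id, .data$day) %>%
      filter(dplyr::n_distinct(.data$rater_id) == 2, dplyr::n() == 2) %>%
      arrange(.data$rater_id, .by_group = TRUE) %>%
      mutate(.pos = .data$total >= cutoffs[1], .slot = dplyr::row_number()) %>%
      ungroup()
    if (nrow(pairs) >= 4) {
      a <- pairs$.pos[pairs$.slot == 1]
      b <- pairs$.pos[pairs$.slot == 2]
      kappa <- cohen_kappa(a, b, alpha)
    }
  }

  excl <- scored[!usable, ]
  reason_col <- if ("exclusion_reason" %in% names(excl)) {
    as.character(excl$exclusion_reason)
  } else {
    rep(NA_character_, nrow(excl))
  }
  reasons <- dplyr::count(
    tibble(reason = dplyr::coalesce(reason_col, "missing_reference")),
    .data$reason, name = "n"
  )
  ledger <- list(
    eligible = n_input, analyzed = nrow(data), excluded = n_input - nrow(data),
    exclusion_reasons = reasons,
    kappa_pairs = if (is.null(kappa)) 0L else kappa$n
  )

  structure(
    list(
      performance = perf, items = items, overall_auroc = overall, roc = roc,
      youden_cutoff = youden, kappa = kappa, ledger = ledger,
      cutoffs = as.integer(cutoffs), alpha = alpha
    ),
    class = "cam_accuracy"
  )
}

#' @export
print.cam_accuracy <- function(x, digits = 2, ...) {
  fmt <- function(est, lo, hi) {
    sprintf(
      "%.2f (%.2f-%.2f)",
      round_half_up(est, digits), round_half_up(lo, digits),
      round_half_up(hi, digits)
    )
  }
  cat("CAM-IMC diagnostic accuracy\n")
  cat(sprintf(
    "  %d observations analyzed (%d excluded of %d)\n",
    x$ledger$analyzed, x$ledger$excluded, x$ledger$eligible
  ))
  cat(sprintf(
    "  Raw-score AUROC %s | Youden-optimal cut-off: %d\n",
    fmt(x$overall_auroc$auc, x$overall_auroc$conf.low, x$overall_auroc$conf.high),
    x$youden_cutoff
  ))
  if (!is.null(x$kappa)) {
    cat(sprintf(
      "  Interrater kappa %s on %d paired assessments\n",
      fmt(x$kappa$kappa, x$kappa$conf.low, x$kappa$conf.high), x$kappa$n
    ))
  }
  if (is.null(x$performance) || nrow(x$performance) == 0) {
    cat("\nNo per-cutoff performance blocks (empty or single-class populations).\n")
    return(invisible(x))
  }
  cat("\nPer-cutoff performance:\n")
  tbl <- x$performance %>%
    mutate(
      sens = fmt(.data$sensitivity, .data$sensitivity_low, .data$sensitivity_high),
      spec = fmt(.data$specificity, .data$specificity_low, .data$specificity_high),
      `LR+` = fmt(.data$lr_positive, .data$lr_positive_low, .data$lr_positive_high),
      AUROC = fmt(.data$auroc, .data$auroc_low, .data$auroc_high)
    ) %>%
    select("population", "cutoff", "n", "sens", "spec", "LR+", "AUROC")
  print(as.data.frame(tbl), row.names = FALSE)
  invisible(x)
}

#' @describeIn cam_evaluate Long tibble of every estimate in the report
#'   (`population`, `block`, `level`, `metric`, `estimate`, `conf.low`,
#'   `conf.high`).
#' @param x A `cam_accuracy` object.
#' @param ... Unused.
#' @export
tidy.cam_accuracy <- function(x, ...) {
  lengthen <- function(tbl, block, level_col) {
    if (is.null(tbl) || nrow(tbl) == 0) return(NULL)
    tbl %>%
      mutate(block = block, level = as.character(.data[[level_col]])) %>%
      tidyr::pivot_longer(
        cols = c(
          tidyr::ends_with("_low"), tidyr::ends_with("_high"),
          "sensitivity", "specificity", "ppv", "npv",
          "lr_positive", "lr_negative", "auroc"
        ),
        names_to = "name", values_to = "value"
      ) %>%
      mutate(
        metric = sub("_(low|high)$", "", .data$name),
        part = dplyr::case_when(
          grepl("_low$", .data$name) ~ "conf.low",
          grepl("_high$", .data$name) ~ "conf.high",
          TRUE ~ "estimate"
        )
      ) %>%
      select("population", "block", "level", "metric", "part", "value") %>%
      tidyr::pivot_wider(names_from = "part", values_from = "value")
  }
  out <- bind_rows(
    lengthen(x$performance, "cutoff", "cutoff"),
    lengthen(x$items, "item", "item")
  )
  extra <- tibble(
    population = "all", block = "overall",
    level = c("raw_score", "raw_score", if (!is.null(x$kappa)) "index_raters"),
    metric = c("auroc", "youden_cutoff", if (!is.null(x$kappa)) "kappa"),
    estimate = c(
      x$overall_auroc$auc, as.numeric(x$youden_cutoff),
      if (!is.null(x$kappa)) x$kappa$kappa
    ),
    conf.low = c(
      x$overall_auroc$conf.low, NA,
      if (!is.null(x$kappa)) x$kappa$conf.low
    ),
    conf.high = c(
      x$overall_auroc$conf.high, NA,
      if (!is.null(x$kappa)) x$kappa$conf.high
    )
  )
  bind_rows(out, extra)
}

#' @describeIn cam_evaluate One-row summary: observations analyzed,
#'   prevalence, raw-score AUROC, Youden cut-off, kappa.
#' @export
glance.cam_accuracy <- function(x, ...) {
  perf <- x$performance
  all3 <- if (!is.null(perf) && nrow(perf) > 0) {
    perf[perf$population == "all" & perf$cutoff == x$cutoffs[1], ]
  } else {
    perf
  }
  tibble(
    n_obs = x$ledger$analyzed,
    n_excluded = x$ledger$excluded,
    prevalence = if (!is.null(all3) && nrow(all3) == 1) {
      (all3$tp + all3$fn) / all3$n
    } else {
      NA_real_
    },
    auroc_raw = x$overall_auroc$auc,
    youden_cutoff = as.integer(x$youden_cutoff),
    kappa = if (is.null(x$kappa)) NA_real_ else x$kappa$kappa,
    kappa_pairs = x$ledger$kappa_pairs
  )
}
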