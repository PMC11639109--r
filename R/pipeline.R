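#' Score an assessment table end to end
#'
#' The scoring stage of the pipeline: keeps the index-rater rows, fills any
#' missing `reference_delirium` from the same-day reference-rater rows,
#' applies [score_cam_imc()], [add_item_flags()] and (when a baseline table
#' is supplied) [add_subgroup_flags()], and records an exclusion ledger
#' (eligible = analyzed + excluded, with per-reason counts) as the
#' `"ledger"` attribute.
#'
#' @param assessments Assessment tibble (see [read_assessments()]).
#' @param baseline Optional baseline tibble (see [read_baseline()]).
#' @param cutoff Positivity cut-off (default 3).
#' @param policy Missing-data policy, `"strict"` or `"lenient"`.
#' @return A scored tibble of index observations.
#' @export
cam_score <- function(assessments, baseline = NULL, cutoff = 3L,
                      policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  assessments <- as_tibble(assessments)
  if (!"rater_role" %in% names(assessments)) {
    assessments$rater_role <- "index"
  }
  idx <- assessments %>% filter(.data$rater_role == "index")
  if (nrow(idx) == 0) abort("No index-rater rows to score.")

  refs <- assessments %>% filter(.data$rater_role == "reference")
  if ("reference_delirium" %in% names(idx) && nrow(refs) > 0 &&
      anyNA(idx$reference_delirium)) {
    lut <- refs %>%
      distinct(.data$patient_id, .data$day, ref_dx = .data$reference_delirium)
    idx <- idx %>%
      left_join(lut, by = c("patient_id", "day")) %>%
      mutate(
        reference_delirium = dplyr::coalesce(.data$reference_delirium, .data$ref_dx)
      ) %>%
      select(-"ref_dx")
  }

  scored <- idx %>%
    score_cam_imc(cutoff = cutoff, policy = policy) %>%
    add_item_flags(policy = policy)
  if (!is.null(baseline)) {
    scored <- add_subgroup_flags(scored, baseline)
  }

  excluded <- scored %>% filter(!.data$assessable)
  if (nrow(excluded) > 0) {
    inform(sprintf(
      "Excluded %d of %d index observations (%s).",
      nrow(excluded), nrow(scored),
      paste(
        sprintf(
          "%s: %d",
          names(table(excluded$exclusion_reason)),
          as.integer(table(excluded$exclusion_reason))
        ),
        collapse = ", "
      )
    ))
  }
  attr(scored, "ledger") <- list(
    eligible = nrow(scored),
    analyzed = sum(scored$assessable),
    excluded = sum(!scored$assessable),
    exclusion_reasons = dplyr::count(
      excluded, .data$exclusion_reason, name = "n"
    )
  )
  scored
}

#' Simulate a cohort and write its CSV bundle
#'
#' Pipeline wrapper around [simulate_cohort()] + [write_cohort_csv()]:
#' simulates, writes `assessments.csv`, `baseline.csv`, `truth.csv` and the
#' configuration, and prints a one-line summary.
#'
#' @inheritParams simulate_cohort
#' @param dir Output directory.
#' @return The `cam_cohort`, invisibly.
#' @export
cam_simulate <- function(config = cohort_config(), seed = NULL, dir = NULL) {
  cohort <- simulate_cohort(config, seed = seed)
  if (!is.null(dir)) write_cohort_csv(cohort, dir)
  print(cohort)
  invisible(cohort)
}

report_to_list <- function(report) {
  stopifnot(inherits(report, "cam_accuracy"))
  list(
    performance = report$performance,
    items = report$items,
    overall_auroc = report$overall_auroc,
    youden_cutoff = report$youden_cutoff,
    kappa = report$kappa,
    roc = if (is.null(report$roc)) NULL else as_tibble(report$roc),
    ledger = list(
      eligible = report$ledger$eligible,
      analyzed = report$ledger$analyzed,
      excluded = report$ledger$excluded,
      exclusion_reasons = report$ledger$exclusion_reasons,
      kappa_pairs = report$ledger$kappa_pairs
    ),
    alpha = report$alpha,
    cutoffs = report$cutoffs
  )
}

#' Write an accuracy report to disk
#'
#' Emits the full report as machine-readable JSON (`report.json`), CSV
#' tables mirroring the per-cutoff and per-item performance layouts
#' (`performance.csv`, `items.csv`), the raw-score ROC coordinates for
#' plotting (`roc.csv`), and a run manifest (`manifest.json`: inputs,
#' configuration hash, package and R versions, seed) beside the report.
#'
#' @param report A `cam_accuracy` object from [cam_evaluate()].
#' @param dir Output directory (created if absent).
#' @param inputs Optional character vector of input paths for the manifest.
#' @param seed Optional seed recorded in the manifest.
#' @return Invisibly, the paths written.
#' @export
write_accuracy_report <- function(report, dir, inputs = character(), seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    report = file.path(dir, "report.json"),
    performance = file.path(dir, "performance.csv"),
    items = file.path(dir, "items.csv"),
    roc = file.path(dir, "roc.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  jsonlite::write_json(
    report_to_list(report), paths[["report"]],
    auto_unbox = TRUE, digits = NA, na = "string", dataframe = "rows"
  )
  readr::write_csv(report$performance, paths[["performance"]], na = "")
  if (!is.null(report$items) && nrow(report$items) > 0) {
    readr::write_csv(report$items, paths[["items"]], na = "")
  }
  if (!is.null(report$roc)) {
    readr::write_csv(as_tibble(report$roc), paths[["roc"]], na = "")
  }
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "camimc",
    package_version = as.character(utils::packageVersion("camimc")),
    r_version = R.version.string,
    inputs = as.list(inputs),
    report_hash = rlang::hash(report_to_list(report)),
    seed = seed,
    alpha = report$alpha,
    cutoffs = report$cutoffs
  )
  jsonlite::write_json(
    manifest, paths[["manifest"]], auto_unbox = TRUE, null = "null"
  )
  invisible(paths)
}
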