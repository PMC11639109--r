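assessment_col_types <- function() {
  readr::cols(
    patient_id = readr::col_character(),
    day = readr::col_integer(),
    rater_id = readr::col_character(),
    rater_role = readr::col_character(),
    fluctuation = readr::col_character(),
    rass = readr::col_integer(),
    inattention_errors = readr::col_integer(),
    dis_age = readr::col_character(),
    dis_dob = readr::col_character(),
    dis_place = readr::col_character(),
    dis_year = readr::col_character(),
    dis_situation = readr::col_character(),
    reference_delirium = readr::col_logical(),
    .default = readr::col_guess()
  )
}

#' Read an assessment CSV
#'
#' One row per patient-day-rater with columns `patient_id`, `day`,
#' `rater_id`, `rater_role` (`index`/`reference`), `fluctuation`, `rass`,
#' `inattention_errors`, the five [disorientation_dimensions] columns and
#' `reference_delirium`. Missing values are empty fields. Malformed rows are
#' reported with their line numbers.
#'
#' @param path Path to a UTF-8 CSV with a header row.
#' @return A tibble.
#' @export
read_assessments <- function(path) {
  # readr's own parse warning is redundant: problems() is turned into a
  # line-numbered error below
  tbl <- suppressWarnings(readr::read_csv(
    path, col_types = assessment_col_types(), progress = FALSE
  ))
  required <- c(
    "patient_id", "day", "rater_id", "rater_role", cam_feature_columns(),
    "reference_delirium"
  )
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Assessment file lacks required columns: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  problems <- readr::problems(tbl)
  if (nrow(problems) > 0) {
    bad <- paste(
      sprintf("line %d (%s)", problems$row + 1L, problems$expected),
      collapse = "; "
    )
    abort(paste0("Malformed assessment rows: ", bad))
  }
  idx <- tbl$rater_role == "index"
  bad_role <- !tbl$rater_role %in% c("index", "reference")
  if (any(bad_role)) {
    abort(sprintf(
      "Invalid rater_role at data line(s): %s",
      paste(which(bad_role), collapse = ", ")
    ))
  }
  bad_fl <- idx & !(tbl$fluctuation %in% c("yes", "no") | is.na(tbl$fluctuation))
  if (any(bad_fl)) {
    abort(sprintf(
      "Invalid fluctuation value at data line(s): %s",
      paste(which(bad_fl), collapse = ", ")
    ))
  }
  tbl
}

#' Read a baseline CSV
#'
#' One row per patient: `patient_id`, `age`, `sex`, `minicog`,
#' `baseline_orientation`, `baseline_rass`, plus any optional covariates.
#'
#' @param path Path to a UTF-8 CSV with a header row.
#' @return A tibble.
#' @export
read_baseline <- function(path) {
  tbl <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      age = readr::col_integer(),
      sex = readr::col_character(),
      minicog = readr::col_integer(),
      .default = readr::col_guess()
    ),
    progress = FALSE
  )
  required <- c("patient_id", "age", "sex", "minicog")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Baseline file lacks required columns: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyDuplicated(tbl$patient_id)) abort("Duplicate patient_id in baseline file.")
  tbl
}

#' Write a simulated cohort to CSV files
#'
#' Emits `assessments.csv`, `baseline.csv` and `truth.csv` in the dialects
#' [read_assessments()] and [read_baseline()] consume (missing values as
#' empty fields), plus `config.yml`-style plain-text configuration
#' (`config.txt`, key: value lines, round-trippable for scalar fields).
#'
#' @param cohort A `cam_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cam_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    assessments = file.path(dir, "assessments.csv"),
    baseline = file.path(dir, "baseline.csv"),
    truth = file.path(dir, "truth.csv"),
    config = file.path(dir, "config.txt")
  )
  readr::write_csv(cohort$assessments, paths[["assessments"]], na = "")
  readr::write_csv(cohort$baseline, paths[["baseline"]], na = "")
  readr::write_csv(cohort$truth, paths[["truth"]], na = "")
  writeLines(serialize_config(cohort$config, cohort$seed), paths[["config"]])
  invisible(paths)
}

serialize_config <- function(config, seed = NULL) {
  cov <- config$covariates
  c(
    sprintf("n_patients: %d", config$n_patients),
    sprintf("n_days: %d", config$n_days),
    sprintf("delirium_incidence: %.10g", config$delirium_incidence),
    sprintf("incidence_level: %s", config$incidence_level),
    sprintf("persistence: %.10g", config$persistence),
    sprintf("rater_agreement: %.10g", config$rater_agreement),
    sprintf("reference_error: %.10g", config$reference_error),
    sprintf("missing_rate: %.10g", config$missing_rate),
    sprintf(
      "item_model: %s",
      paste(
        sprintf("%s=%.10g/%.10g", config$item_model$item,
                config$item_model$sens, config$item_model$spec),
        collapse = " "
      )
    ),
    sprintf(
      "covariates: age=%.10g/%.10g range=%g-%g p_female=%.10g",
      cov$age_mean, cov$age_sd, cov$age_range[1], cov$age_range[2],
      cov$p_female
    ),
    if (!is.null(seed)) sprintf("seed: %d", seed)
  )
}

parse_config_file <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  vals <- setNames(
    vapply(kv, function(x) paste(x[-1], collapse = ": "), character(1)),
    vapply(kv, `[[`, character(1), 1)
  )
  im_parts <- strsplit(strsplit(vals[["item_model"]], " ")[[1]], "[=/]")
  item_model <- tibble(
    item = vapply(im_parts, `[[`, character(1), 1),
    sens = as.numeric(vapply(im_parts, `[[`, character(1), 2)),
    spec = as.numeric(vapply(im_parts, `[[`, character(1), 3))
  )
  cohort_config(
    n_patients = as.integer(vals[["n_patients"]]),
    n_days = as.integer(vals[["n_days"]]),
    delirium_incidence = as.numeric(vals[["delirium_incidence"]]),
    incidence_level = vals[["incidence_level"]],
    persistence = as.numeric(vals[["persistence"]]),
    item_model = item_model,
    rater_agreement = as.numeric(vals[["rater_agreement"]]),
    reference_error = as.numeric(vals[["reference_error"]]),
    missing_rate = as.numeric(vals[["missing_rate"]]),
    seed = if ("seed" %in% names(vals)) as.integer(vals[["seed"]]) else NULL
  )
}
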