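#' CAM-IMC disorientation dimensions
#'
#' Column names used for the five verbal disorientation dimensions: the
#' patient's age, date of birth, current place, current year, and situational
#' awareness (how the patient got to hospital). Each holds `"correct"`,
#' `"error"` or `NA` (not assessed).
#'
#' @export
disorientation_dimensions <- c(
  "dis_age", "dis_dob", "dis_place", "dis_year", "dis_situation"
)

cam_feature_columns <- function() {
  c("fluctuation", "rass", "inattention_errors", disorientation_dimensions)
}

#' Score the inattention component
#'
#' The inattention task asks the patient to squeeze the examiner's hand at
#' every letter "A" while a ten-letter word (ANANASBAUM or CASABLANCA) is read
#' aloud. Each mistake (missed or false squeeze) adds one point, capped at
#' three points.
#'
#' @param errors Integer vector of error counts, 0-10 (`NA` = not assessed).
#' @return Integer vector of points, 0-3; `NA` where input is missing.
#' @examples
#' score_inattention(c(0, 2, 7))
#' @export
score_inattention <- function(errors) {
  bad <- !is.na(errors) & (errors < 0 | errors > 10 | errors != floor(errors))
  if (any(bad)) {
    abort("`errors` must be whole numbers in 0..10 (ten-letter task).")
  }
  as.integer(pmin(errors, 3L))
}

#' Score the altered-level-of-consciousness component
#'
#' One point for any Richmond Agitation-Sedation Scale (RASS) value other
#' than 0 (alert and calm). Patients at RASS -4 or -5 cannot be assessed at
#' all (no response to voice), so the score is `NA` there; record-level
#' handling of such observations is done by [score_cam_imc()].
#'
#' @param rass Integer vector of RASS values in -5..+4 (`NA` = not assessed).
#' @return Integer vector: 1 if RASS != 0, 0 if RASS == 0, `NA` if missing or
#'   unarousable (RASS <= -4).
#' @examples
#' score_consciousness(c(0, 1, -2))
#' @export
score_consciousness <- function(rass) {
  bad <- !is.na(rass) & (rass < -5 | rass > 4 | rass != floor(rass))
  if (any(bad)) abort("`rass` must be whole numbers in -5..+4.")
  out <- ifelse(rass != 0, 1L, 0L)
  out[!is.na(rass) & rass <= -4] <- NA_integer_
  as.integer(out)
}

#' Score the disorientation component
#'
#' One point per dimension answered in error, across the five dimensions
#' (age, date of birth, place, year, situational awareness); maximum five
#' points.
#'
#' @param dims A data frame or matrix with the five columns named in
#'   [disorientation_dimensions], each `"correct"`, `"error"` or `NA`; or a
#'   single character vector of length five for one assessment.
#' @param policy Missing-dimension policy. `"strict"` (default): any missing
#'   dimension makes the component unassessable (`NA`). `"lenient"`: errors
#'   are counted among the answered dimensions (all-missing still gives
#'   `NA`).
#' @return Integer vector of points, 0-5.
#' @examples
#' score_disorientation(c("correct", "correct", "error", "error", "error"))
#' @export
score_disorientation <- function(dims, policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  if (is.atomic(dims) && is.null(dim(dims))) {
    dims <- matrix(dims, nrow = 1)
  }
  dims <- as.matrix(as.data.frame(dims))
  if (ncol(dims) != 5) {
    abort("`dims` must supply exactly five disorientation dimensions.")
  }
  ok <- dims %in% c("correct", "error") | is.na(dims)
  if (!all(ok)) {
    abort("Disorientation results must be \"correct\", \"error\" or missing.")
  }
  n_err <- rowSums(dims == "error", na.rm = TRUE)
  n_missing <- rowSums(is.na(dims))
  out <- as.integer(n_err)
  if (policy == "strict") {
    out[n_missing > 0] <- NA_integer_
  } else {
    out[n_missing == 5] <- NA_integer_
  }
  out
}

#' Score CAM-IMC assessments
#'
#' Computes the four CAM-IMC point components, the 0-10 total and positivity
#' for each row of an assessment table. The components are additive: one
#' point for an acute change or fluctuating course of mental status, one for
#' RASS != 0, up to three for inattention errors and up to five for
#' disorientation errors. An observation is positive when the total reaches
#' the cut-off (three points by default, the Youden-optimal value).
#'
#' Observations at RASS -4/-5 are unarousable and never assessable. Under the
#' `"strict"` missing-data policy (default) any missing feature makes the
#' record unassessable; under `"lenient"` missing features contribute zero
#' points and the record is flagged `partial` (an all-missing record is still
#' unassessable).
#'
#' @param data Data frame with columns `fluctuation` (`"yes"`/`"no"`/`NA`),
#'   `rass` (-5..+4), `inattention_errors` (0-10) and the five columns in
#'   [disorientation_dimensions]. Extra columns are carried through.
#' @param cutoff Positivity threshold on the total score (default 3).
#' @param policy `"strict"` or `"lenient"` missing-data handling.
#' @return The input with columns `pts_fluctuation`, `pts_consciousness`,
#'   `pts_inattention`, `pts_disorientation`, `total`, `positive`,
#'   `assessable`, `exclusion_reason` and `partial` appended, as a tibble.
#' @examples
#' tibble::tibble(
#'   fluctuation = c("no", "yes"), rass = c(0L, 1L),
#'   inattention_errors = c(0L, 4L),
#'   dis_age = "correct", dis_dob = "correct", dis_place = c("correct", "error"),
#'   dis_year = "correct", dis_situation = "correct"
#' ) |> score_cam_imc()
#' @export
score_cam_imc <- function(data, cutoff = 3L, policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff >= 0, cutoff <= 10)
  missing_cols <- setdiff(cam_feature_columns(), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Assessment data lacks required columns: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  fl <- data$fluctuation
  if (!all(fl %in% c("yes", "no") | is.na(fl))) {
    abort("`fluctuation` must be \"yes\", \"no\" or missing.")
  }

  pts_fl <- ifelse(fl == "yes", 1L, 0L)
  pts_co <- score_consciousness(data$rass)
  pts_in <- score_inattention(data$inattention_errors)
  dis <- as.matrix(as.data.frame(data)[, disorientation_dimensions])
  pts_di <- score_disorientation(dis, policy = policy)

  unarousable <- !is.na(data$rass) & data$rass <= -4
  n_missing <- is.na(fl) + is.na(data$rass) + is.na(data$inattention_errors) +
    rowSums(is.na(dis))
  all_missing <- n_missing == 8L

  if (policy == "strict") {
    assessable <- !unarousable & n_missing == 0L
    partial <- rep(FALSE, nrow(data))
  } else {
    assessable <- !unarousable & !all_missing
    partial <- assessable & n_missing > 0L
    pts_fl[is.na(pts_fl)] <- 0L
    pts_co[is.na(data$rass)] <- 0L
    pts_in[is.na(pts_in)] <- 0L
    pts_di[is.na(pts_di)] <- 0L
  }

  reason <- dplyr::case_when(
    unarousable ~ "unarousable",
    policy == "strict" & n_missing > 0L ~ "missing_feature",
    policy == "lenient" & all_missing ~ "all_features_missing",
    TRUE ~ NA_character_
  )

  total <- pts_fl + pts_co + pts_in + pts_di
  out <- as_tibble(data)
  out$pts_fluctuation <- ifelse(assessable, pts_fl, NA_integer_)
  out$pts_consciousness <- ifelse(assessable, pts_co, NA_integer_)
  out$pts_inattention <- ifelse(assessable, pts_in, NA_integer_)
  out$pts_disorientation <- ifelse(assessable, pts_di, NA_integer_)
  out$total <- ifelse(assessable, total, NA_integer_)
  out$positive <- out$total >= cutoff
  out$assessable <- assessable
  out$exclusion_reason <- reason
  out$partial <- partial
  attr(out, "cutoff") <- as.integer(cutoff)
  attr(out, "policy") <- policy
  out
}

#' Add per-item positivity flags
#'
#' Dichotomizes each CAM-IMC item at its operating cut-off, as used for the
#' item-level accuracy analysis: inattention positive at three or more errors
#' on the ten-letter task, disorientation positive at two or more dimension
#' errors, altered level of consciousness at RASS != 0, and fluctuation when
#' an acute change or fluctuating course is present.
#'
#' @inheritParams score_cam_imc
#' @return The input with logical columns `fluctuation_positive`,
#'   `consciousness_positive`, `inattention_positive` and
#'   `disorientation_positive` appended (`NA` where the item cannot be
#'   determined under the policy).
#' @export
add_item_flags <- function(data, policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  missing_cols <- setdiff(cam_feature_columns(), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Assessment data lacks required columns: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  dis <- as.matrix(as.data.frame(data)[, disorientation_dimensions])
  dis_errors <- score_disorientation(dis, policy = policy)
  out <- as_tibble(data)
  out$fluctuation_positive <- data$fluctuation == "yes"
  out$consciousness_positive <- ifelse(
    !is.na(data$rass) & data$rass <= -4, NA, data$rass != 0
  )
  out$inattention_positive <- data$inattention_errors >= 3L
  out$disorientation_positive <- dis_errors >= 2L
  out
}

#' Add subgroup membership flags
#'
#' Flags the two pre-specified subgroups: elderly patients (age >= 65 years)
#' and patients with pre-existing cognitive impairment (preoperative Mini-Cog
#' result < 3). A missing Mini-Cog leaves `cognitive_impairment` `NA`, so
#' the record drops out of that subgroup only.
#'
#' @param data Assessment-level data frame carrying `patient_id` (or already
#'   carrying `age`/`minicog`).
#' @param baseline Optional per-patient baseline table with `patient_id`,
#'   `age` and `minicog`, joined onto `data` first.
#' @return `data` with logical columns `elderly` and `cognitive_impairment`.
#' @export
add_subgroup_flags <- function(data, baseline = NULL) {
  out <- as_tibble(data)
  if (!is.null(baseline)) {
    keep <- intersect(c("patient_id", "age", "minicog"), names(baseline))
    if (!all(c("patient_id", "age", "minicog") %in% keep)) {
      abort("`baseline` must carry patient_id, age and minicog.")
    }
    out <- left_join(
      out, dplyr::select(as_tibble(baseline), dplyr::all_of(keep)),
      by = "patient_id"
    )
  }
  if (!all(c("age", "minicog") %in% names(out))) {
    abort("Need `age` and `minicog` (supply `baseline` or include them).")
  }
  out$elderly <- out$age >= 65
  out$cognitive_impairment <- out$minicog < 3
  out
}
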