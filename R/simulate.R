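# ---- calibration helpers ---------------------------------------------------

# pmf proportional to r^k on 0..max_k; r < 1 is a truncated geometric,
# r > 1 its increasing mirror (needed when most of the mass sits in the tail)
count_pmf <- function(r, max_k) {
  w <- r^(0:max_k)
  w / sum(w)
}

# solve r so that P(X >= k) = target under count_pmf(r, max_k)
solve_count_ratio <- function(target, k, max_k) {
  stopifnot(target > 0, target < 1)
  f <- function(log_r) {
    p <- count_pmf(exp(log_r), max_k)
    sum(p[(k + 1):(max_k + 1)]) - target
  }
  exp(uniroot(f, c(-25, 25), tol = 1e-12)$root)
}

# solve per-dimension error probability so that P(Binomial(5, p) >= 2) = target
solve_dis_prob <- function(target) {
  stopifnot(target > 0, target < 1)
  f <- function(p) 1 - stats::pbinom(1, 5, p) - target
  uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
}

pmf_convolve <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
  }
  out
}

# per-day marginal probabilities of the latent delirium state under a
# two-state Markov chain: onset on day 1 and from a non-delirious day with
# probability `onset`, persistence from a delirious day with `persistence`
markov_day_probs <- function(onset, persistence, n_days) {
  p <- numeric(n_days)
  p[1] <- onset
  if (n_days > 1) {
    for (t in 2:n_days) {
      p[t] <- p[t - 1] * persistence + (1 - p[t - 1]) * onset
    }
  }
  p
}

solve_onset <- function(target, persistence, n_days, level = "observation") {
  if (target == 0) return(0)
  if (level == "patient") {
    # P(delirious on any day) = 1 - (1 - onset)^n_days under this chain
    return(1 - (1 - target)^(1 / n_days))
  }
  f <- function(g) mean(markov_day_probs(g, persistence, n_days)) - target
  uniroot(f, c(1e-10, 1 - 1e-10), tol = 1e-12)$root
}

# full calibration of the generative model from a cohort configuration
cohort_calibration <- function(config) {
  im <- config$item_model
  pr <- function(item, col) im[[col]][im$item == item]
  p_item <- list(
    D = c(
      fluctuation = pr("fluctuation", "sens"),
      consciousness = pr("consciousness", "sens"),
      inattention = pr("inattention", "sens"),
      disorientation = pr("disorientation", "sens")
    ),
    N = c(
      fluctuation = 1 - pr("fluctuation", "spec"),
      consciousness = 1 - pr("consciousness", "spec"),
      inattention = 1 - pr("inattention", "spec"),
      disorientation = 1 - pr("disorientation", "spec")
    )
  )
  r_inatt <- lapply(p_item, function(p) {
    solve_count_ratio(p[["inattention"]], k = 3, max_k = 10)
  })
  pi_dis <- lapply(p_item, function(p) solve_dis_prob(p[["disorientation"]]))

  score_pmf <- function(state) {
    p <- p_item[[state]]
    bern <- function(q) c(1 - q, q)
    inatt_counts <- count_pmf(r_inatt[[state]], 10)
    inatt_pts <- c(inatt_counts[1:3], sum(inatt_counts[4:11]))
    dis_pts <- stats::dbinom(0:5, 5, pi_dis[[state]])
    Reduce(
      pmf_convolve,
      list(bern(p[["fluctuation"]]), bern(p[["consciousness"]]),
           inatt_pts, dis_pts)
    )
  }
  pmf_D <- score_pmf("D")
  pmf_N <- score_pmf("N")
  p_pos <- function(pmf, cutoff) sum(pmf[(cutoff + 1):length(pmf)])

  onset <- solve_onset(
    config$delirium_incidence, config$persistence, config$n_days,
    config$incidence_level
  )
  day_probs <- markov_day_probs(onset, config$persistence, config$n_days)
  prevalence <- mean(day_probs)

  list(
    p_item = p_item, r_inatt = r_inatt, pi_dis = pi_dis,
    pmf_D = pmf_D, pmf_N = pmf_N, p_pos = p_pos,
    onset = onset, day_probs = day_probs, obs_prevalence = prevalence
  )
}

# kappa between two index raters whose responses are identical with
# probability w (shared presentation) and conditionally independent given
# the latent state otherwise; closed form from the state-conditional
# positivity probabilities
kappa_given_mixing <- function(w, p_D, p_N, prev) {
  states <- c(prev, 1 - prev)
  ps <- c(p_D, p_N)
  p_both_pos <- sum(states * (w * ps + (1 - w) * ps^2))
  p_both_neg <- sum(states * (w * (1 - ps) + (1 - w) * (1 - ps)^2))
  marg <- sum(states * ps)
  p_o <- p_both_pos + p_both_neg
  p_e <- marg^2 + (1 - marg)^2
  (p_o - p_e) / (1 - p_e)
}

solve_mixing <- function(target_kappa, p_D, p_N, prev) {
  k0 <- kappa_given_mixing(0, p_D, p_N, prev)
  if (target_kappa > 1 || target_kappa < k0 - 1e-9) {
    abort(sprintf(
      "Rater agreement target %.3f is outside the feasible range [%.3f, 1] for this item model.",
      target_kappa, k0
    ))
  }
  if (target_kappa >= 1) return(1)
  f <- function(w) kappa_given_mixing(w, p_D, p_N, prev) - target_kappa
  uniroot(f, c(0, 1), tol = 1e-12)$root
}

# ---- configuration ---------------------------------------------------------

#' Synthetic-cohort configuration
#'
#' Parameterizes the observation-level cohort simulator. The defaults
#' reproduce the structure of the CAM-IMC development cohort: 155 elective
#' cardiac-surgery patients assessed by two independent index raters plus
#' one reference rater over three postoperative days, about 9% of
#' observations reference-positive for delirium, whole-cohort item operating
#' characteristics (sensitivity/specificity 0.83/0.81 for fluctuation,
#' 0.35/0.89 for RASS != 0, 0.83/0.99 for inattention, 0.80/0.99 for
#' disorientation), a target interrater kappa of 0.80, and an assessment
#' completion rate chosen so roughly 624 of the 930 possible index
#' assessments are observed.
#'
#' Latent per-patient delirium follows a two-state Markov chain (daily
#' onset solved from the incidence target, persistence 0.5 by default).
#' Item error counts are drawn from one-parameter count families solved so
#' their dichotomizations (>= 3 inattention errors, >= 2 disorientation
#' errors) hit the configured rates. The two index raters share the
#' identical presentation with a mixing probability calibrated by
#' root-finding so the positivity kappa equals `rater_agreement`.
#'
#' @param n_patients Number of patients (default 155).
#' @param n_days Postoperative assessment days (default 3).
#' @param delirium_incidence Target probability an observation (or patient,
#'   see `incidence_level`) is reference-positive; default 54/624.
#' @param incidence_level `"observation"` (default) or `"patient"`.
#' @param persistence P(delirious tomorrow | delirious today); default 0.5.
#' @param item_model Tibble with columns `item`
#'   (fluctuation/consciousness/inattention/disorientation), `sens`, `spec`:
#'   per-item P(positive | delirium) and 1 - P(positive | no delirium).
#' @param rater_agreement Target Cohen's kappa between the two index raters'
#'   positivity calls (default 0.80).
#' @param reference_error Probability the reference rater misclassifies the
#'   latent state (default 0: reference = truth).
#' @param missing_rate Probability each index assessment is not completed
#'   (default 1 - 624/930).
#' @param covariates List of baseline distributions: `age_mean`, `age_sd`,
#'   `age_range` (truncation bounds), `p_female`, `minicog_probs`
#'   (probabilities for scores 0..5), `orientation_probs` (scores 3..5),
#'   `rass_probs` (values -1..1).
#' @param seed Optional default seed used by [simulate_cohort()].
#' @return A list of class `cohort_config`.
#' @examples
#' cfg <- cohort_config()
#' cfg$n_patients
#' @export
cohort_config <- function(n_patients = 155L,
                          n_days = 3L,
                          delirium_incidence = 54 / 624,
                          incidence_level = c("observation", "patient"),
                          persistence = 0.5,
                          item_model = default_item_model(),
                          rater_agreement = 0.80,
                          reference_error = 0,
                          missing_rate = 1 - 624 / 930,
                          covariates = default_covariates(),
                          seed = NULL) {
  incidence_level <- match.arg(incidence_level)
  config <- list(
    n_patients = as.integer(n_patients), n_days = as.integer(n_days),
    delirium_incidence = delirium_incidence,
    incidence_level = incidence_level, persistence = persistence,
    item_model = as_tibble(item_model), rater_agreement = rater_agreement,
    reference_error = reference_error, missing_rate = missing_rate,
    covariates = modifyList(default_covariates(), covariates), seed = seed
  )
  validate_cohort_config(config)
  structure(config, class = "cohort_config")
}

default_item_model <- function() {
  tibble(
    item = c("fluctuation", "consciousness", "inattention", "disorientation"),
    sens = c(0.83, 0.35, 0.83, 0.80),
    spec = c(0.81, 0.89, 0.99, 0.99)
  )
}

default_covariates <- function() {
  list(
    age_mean = 67, age_sd = 9, age_range = c(50, 95),
    p_female = 0.213,
    minicog_probs = c(0.03, 0.07, 0.15, 0.15, 0.25, 0.35),
    orientation_probs = c(0.05, 0.10, 0.85),
    rass_probs = c(0.03, 0.94, 0.03)
  )
}

validate_cohort_config <- function(config) {
  probs <- c(
    config$delirium_incidence, config$persistence, config$rater_agreement,
    config$reference_error, config$missing_rate,
    config$item_model$sens, config$item_model$spec
  )
  if (config$n_patients < 1) abort("`n_patients` must be at least 1.")
  if (config$n_days < 1) abort("`n_days` must be at least 1.")
  if (any(probs < 0 | probs > 1)) {
    abort("All probabilities must lie in [0, 1].")
  }
  needed <- c("fluctuation", "consciousness", "inattention", "disorientation")
  if (!setequal(config$item_model$item, needed)) {
    abort("`item_model` must cover exactly: fluctuation, consciousness, inattention, disorientation.")
  }
  invisible(config)
}

#' Analytic operating characteristics implied by a configuration
#'
#' Convolves the configured per-item point distributions into the latent
#' state-conditional distribution of the CAM-IMC total and reports the
#' implied instrument sensitivity P(total >= cutoff | delirium), specificity
#' 1 - P(total >= cutoff | no delirium), observation-level prevalence, and
#' per-item positivity rates. These are the simulator's configured truths
#' that parameter-recovery checks compare against.
#'
#' @param config A [cohort_config()] object.
#' @param cutoff Positivity cut-off on the total (default 3).
#' @return A one-row tibble: `sensitivity`, `specificity`, `prevalence`, and
#'   `item_sens_*` / `item_spec_*` columns.
#' @export
expected_performance <- function(config = cohort_config(), cutoff = 3L) {
  cal <- cohort_calibration(config)
  out <- tibble(
    sensitivity = cal$p_pos(cal$pmf_D, cutoff),
    specificity = 1 - cal$p_pos(cal$pmf_N, cutoff),
    prevalence = cal$obs_prevalence
  )
  for (item in names(cal$p_item$D)) {
    out[[paste0("item_sens_", item)]] <- cal$p_item$D[[item]]
    out[[paste0("item_spec_", item)]] <- 1 - cal$p_item$N[[item]]
  }
  out
}

# ---- simulation ------------------------------------------------------------

draw_feature_responses <- function(states, cal) {
  n <- length(states)
  p_of <- function(item) {
    ifelse(states, cal$p_item$D[[item]], cal$p_item$N[[item]])
  }
  fluct <- ifelse(runif(n) < p_of("fluctuation"), "yes", "no")
  altered <- runif(n) < p_of("consciousness")
  rass_vals <- c(-3L, -2L, -1L, 1L, 2L)
  rass_wts <- c(0.05, 0.15, 0.30, 0.35, 0.15)
  rass <- ifelse(altered, sample(rass_vals, n, replace = TRUE, prob = rass_wts), 0L)
  inatt <- integer(n)
  for (s in c(TRUE, FALSE)) {
    idx <- which(states == s)
    if (length(idx) > 0) {
      pmf <- count_pmf(cal$r_inatt[[if (s) "D" else "N"]], 10)
      inatt[idx] <- sample(0:10, length(idx), replace = TRUE, prob = pmf)
    }
  }
  dis_p <- ifelse(states, cal$pi_dis$D, cal$pi_dis$N)
  dis <- matrix(
    ifelse(runif(n * 5) < rep(dis_p, 5), "error", "correct"),
    nrow = n
  )
  colnames(dis) <- disorientation_dimensions
  dplyr::bind_cols(
    tibble(fluctuation = fluct, rass = as.integer(rass),
           inattention_errors = as.integer(inatt)),
    as_tibble(dis)
  )
}

#' Simulate a synthetic assessment cohort
#'
#' Generates observation-level CAM-IMC assessment data with the statistical
#' structure the accuracy analysis assumes: a latent two-state Markov
#' delirium course per patient, two index raters whose feature responses are
#' drawn from the calibrated state-conditional count models (sharing the
#' identical presentation with the calibrated mixing probability), one
#' reference rater per patient-day, uniform index-assessment missingness,
#' and baseline covariates drawn from the configured distributions truncated
#' to the inclusion criteria (age >= 50).
#'
#' Output is reproducible: the same configuration and seed give identical
#' tables.
#'
#' @param config A [cohort_config()] object.
#' @param seed Integer seed; falls back to `config$seed`.
#' @return A list of class `cam_cohort` with tibbles `assessments` (one row
#'   per patient-day-rater, index and reference rows, with the day's
#'   `reference_delirium` on every row), `baseline` (one row per patient)
#'   and `truth` (latent state per patient-day), plus the `config` used.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_patients = 20), seed = 1)
#' nrow(cohort$baseline)
#' @export
simulate_cohort <- function(config = cohort_config(), seed = NULL) {
  validate_cohort_config(config)
  seed <- seed %||% config$seed
  if (is.null(seed)) abort("Supply `seed` (or set it in the config).")
  set.seed(as.integer(seed))
  cal <- cohort_calibration(config)
  p_pos_D <- cal$p_pos(cal$pmf_D, 3L)
  p_pos_N <- cal$p_pos(cal$pmf_N, 3L)
  w <- solve_mixing(
    config$rater_agreement, p_pos_D, p_pos_N, cal$obs_prevalence
  )

  np <- config$n_patients
  nd <- config$n_days
  cov <- config$covariates

  # baseline covariates, age from a normal truncated to the inclusion window
  lo <- stats::pnorm(cov$age_range[1], cov$age_mean, cov$age_sd)
  hi <- stats::pnorm(cov$age_range[2], cov$age_mean, cov$age_sd)
  age <- round(stats::qnorm(runif(np, lo, hi), cov$age_mean, cov$age_sd))
  baseline <- tibble(
    patient_id = sprintf("P%04d", seq_len(np)),
    age = as.integer(age),
    sex = ifelse(runif(np) < cov$p_female, "female", "male"),
    minicog = sample(0:5, np, replace = TRUE, prob = cov$minicog_probs),
    baseline_orientation = sample(3:5, np, replace = TRUE,
                                  prob = cov$orientation_probs),
    baseline_rass = sample(-1:1, np, replace = TRUE, prob = cov$rass_probs)
  )

  # latent delirium course: day-1 onset, then Markov transitions
  states <- matrix(FALSE, nrow = np, ncol = nd)
  states[, 1] <- runif(np) < cal$onset
  if (nd > 1) {
    for (t in 2:nd) {
      p_t <- ifelse(states[, t - 1], config$persistence, cal$onset)
      states[, t] <- runif(np) < p_t
    }
  }
  truth <- tibble(
    patient_id = rep(baseline$patient_id, each = nd),
    day = rep(seq_len(nd), times = np),
    true_delirium = as.vector(t(states))
  )

  st <- truth$true_delirium
  n_pd <- nrow(truth)
  resp_a <- draw_feature_responses(st, cal)
  resp_b <- draw_feature_responses(st, cal)
  share <- runif(n_pd) < w
  resp_b[share, ] <- resp_a[share, ]

  ref_flip <- runif(n_pd) < config$reference_error
  reference_delirium <- xor(st, ref_flip)

  index_a <- dplyr::bind_cols(
    truth[, c("patient_id", "day")],
    tibble(rater_id = "idx1", rater_role = "index"), resp_a
  )
  index_b <- dplyr::bind_cols(
    truth[, c("patient_id", "day")],
    tibble(rater_id = "idx2", rater_role = "index"), resp_b
  )
  index <- bind_rows(index_a, index_b)
  index <- index[runif(nrow(index)) >= config$missing_rate, ]

  ref_rows <- dplyr::bind_cols(
    truth[, c("patient_id", "day")],
    tibble(
      rater_id = "ref", rater_role = "reference",
      fluctuation = NA_character_, rass = NA_integer_,
      inattention_errors = NA_integer_
    ),
    as_tibble(matrix(
      NA_character_, nrow = n_pd, ncol = 5,
      dimnames = list(NULL, disorientation_dimensions)
    ))
  )

  ref_lookup <- dplyr::bind_cols(
    truth[, c("patient_id", "day")],
    tibble(reference_delirium = reference_delirium)
  )
  assessments <- bind_rows(index, ref_rows) %>%
    left_join(ref_lookup, by = c("patient_id", "day")) %>%
    arrange(.data$patient_id, .data$day, .data$rater_role, .data$rater_id)

  structure(
    list(
      assessments = assessments, baseline = baseline, truth = truth,
      config = config, seed = as.integer(seed)
    ),
    class = "cam_cohort"
  )
}

#' @export
print.cam_cohort <- function(x, ...) {
  n_index <- sum(x$assessments$rater_role == "index")
  prev <- mean(x$truth$true_delirium)
  cat(sprintf(
    "Synthetic CAM-IMC cohort: %d patients x %d days\n  %d index assessments, %d reference ratings\n  observation-level delirium prevalence %.1f%% (seed %d)\n",
    x$config$n_patients, x$config$n_days, n_index, nrow(x$truth),
    100 * prev, x$seed
  ))
  invisible(x)
}
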