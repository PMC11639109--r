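test_that("default configuration matches the emulated cohort design", {
  cfg <- cohort_config()
  expect_identical(cfg$n_patients, 155L)
  expect_identical(cfg$n_days, 3L)
  expect_equal(cfg$rater_agreement, 0.80)
  expect_equal(cfg$delirium_incidence, 54 / 624)
  expect_equal(
    cfg$item_model$sens[cfg$item_model$item == "inattention"], 0.83
  )
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(missing_rate = 1.2), "probabilities")
})

test_that("simulation is deterministic given config and seed", {
  cfg <- cohort_config(n_patients = 40)
  a <- simulate_cohort(cfg, seed = 123)
  b <- simulate_cohort(cfg, seed = 123)
  expect_identical(a$assessments, b$assessments)
  expect_identical(a$baseline, b$baseline)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(cfg, seed = 124)
  expect_false(identical(a$assessments, c$assessments))
  expect_error(simulate_cohort(cfg), "seed")
})

test_that("zero incidence yields no reference-positive observations", {
  cfg <- cohort_config(n_patients = 60, delirium_incidence = 0)
  cohort <- simulate_cohort(cfg, seed = 2)
  expect_false(any(cohort$truth$true_delirium))
  expect_false(any(cohort$assessments$reference_delirium))
})

test_that("infeasible rater-agreement targets are rejected with the feasible range", {
  expect_error(
    simulate_cohort(cohort_config(n_patients = 10, rater_agreement = 0.1),
                    seed = 1),
    "feasible range"
  )
})

test_that("prevalence and item operating characteristics are recovered", {
  cfg <- cohort_config(n_patients = 4000)
  cohort <- simulate_cohort(cfg, seed = 31)
  truth <- cohort$truth

  # observation-level prevalence: patients cluster days, so use the
  # empirical between-patient standard error
  target <- 54 / 624
  pat_means <- tapply(truth$true_delirium, truth$patient_id, mean)
  se <- sd(pat_means) / sqrt(length(pat_means))
  expect_lt(abs(mean(truth$true_delirium) - target), 3 * se)

  # item dichotomization rates, one rater's assessments (independent draws
  # conditional on the latent state)
  idx <- dplyr::inner_join(
    dplyr::filter(cohort$assessments, .data$rater_id == "idx1"),
    truth, by = c("patient_id", "day")
  )
  flags <- add_item_flags(idx)
  ep <- expected_performance(cfg)
  for (item in c("fluctuation", "consciousness", "inattention",
                 "disorientation")) {
    fl <- flags[[paste0(item, "_positive")]]
    sens_cfg <- ep[[paste0("item_sens_", item)]]
    spec_cfg <- ep[[paste0("item_spec_", item)]]
    n_d <- sum(flags$true_delirium)
    n_n <- sum(!flags$true_delirium)
    sens_hat <- mean(fl[flags$true_delirium])
    spec_hat <- 1 - mean(fl[!flags$true_delirium])
    expect_lt(abs(sens_hat - sens_cfg),
              3 * sqrt(sens_cfg * (1 - sens_cfg) / n_d))
    expect_lt(abs(spec_hat - spec_cfg),
              3 * sqrt(spec_cfg * (1 - spec_cfg) / n_n))
  }
})

test_that("interrater agreement is calibrated to the configured kappa", {
  cfg <- cohort_config(n_patients = 4000)
  cohort <- simulate_cohort(cfg, seed = 17)
  scored <- suppressMessages(cam_score(cohort$assessments))
  pairs <- scored |>
    dplyr::group_by(.data$patient_id, .data$day) |>
    dplyr::filter(dplyr::n() == 2) |>
    dplyr::arrange(.data$rater_id, .by_group = TRUE) |>
    dplyr::summarise(a = .data$positive[1], b = .data$positive[2],
                     .groups = "drop")
  expect_gt(nrow(pairs), 5000)
  got <- cohen_kappa(pairs$a, pairs$b)
  expect_lt(abs(got$kappa - 0.80), 0.05)
})

test_that("baseline covariate marginals match their configuration", {
  cohort <- simulate_cohort(cohort_config(n_patients = 5000), seed = 23)
  bl <- cohort$baseline
  q <- quantile(bl$age, c(0.25, 0.5, 0.75))
  expect_lt(abs(q[[1]] - 61), 2.5)
  expect_lt(abs(q[[2]] - 68), 2.5)
  expect_lt(abs(q[[3]] - 73), 2.5)
  expect_true(all(bl$age >= 50 & bl$age <= 95))
  p_f <- 0.213
  expect_lt(abs(mean(bl$sex == "female") - p_f),
            3 * sqrt(p_f * (1 - p_f) / nrow(bl)))
  expect_true(all(bl$minicog %in% 0:5))
  expect_equal(median(bl$minicog), 4)
})

test_that("cohort CSV bundle round-trips through the readers", {
  dir <- withr::local_tempdir()
  cohort <- simulate_cohort(cohort_config(n_patients = 25, seed = 5))
  paths <- write_cohort_csv(cohort, dir)
  back <- read_assessments(paths[["assessments"]])
  expect_equal(nrow(back), nrow(cohort$assessments))
  expect_identical(back$rass, cohort$assessments$rass)
  bl <- read_baseline(paths[["baseline"]])
  expect_identical(bl$patient_id, cohort$baseline$patient_id)
  cfg2 <- camimc:::parse_config_file(paths[["config"]])
  expect_identical(cfg2$n_patients, 25L)
  expect_equal(cfg2$delirium_incidence, 54 / 624)
  expect_equal(cfg2$item_model, cohort$config$item_model)
  expect_identical(cfg2$seed, 5L)
})
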