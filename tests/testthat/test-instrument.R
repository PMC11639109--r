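test_that("component scores follow the instrument rules", {
  # inattention: one point per error, capped at three
  expect_identical(score_inattention(c(0L, 2L, 3L, 7L, 10L)),
                   c(0L, 2L, 3L, 3L, 3L))
  expect_true(all(diff(score_inattention(0:10)) >= 0))
  expect_identical(score_inattention(NA_integer_), NA_integer_)
  expect_error(score_inattention(-1), "0..10")
  expect_error(score_inattention(11), "0..10")

  # consciousness: one point for any RASS other than 0; unarousable is NA
  expect_identical(score_consciousness(c(0L, 1L, -2L, 4L)), c(0L, 1L, 1L, 1L))
  expect_identical(score_consciousness(c(-4L, -5L)),
                   c(NA_integer_, NA_integer_))
  expect_error(score_consciousness(5), "-5")

  # disorientation: one point per dimension in error, maximum five
  expect_identical(score_disorientation(rep("correct", 5)), 0L)
  expect_identical(
    score_disorientation(c("correct", "correct", "error", "error", "error")),
    3L
  )
  expect_identical(score_disorientation(rep("error", 5)), 5L)
  expect_error(score_disorientation(rep("error", 4)), "five")
  expect_error(score_disorientation(rep("wrong", 5)))
})

test_that("disorientation missing-dimension policies differ as documented", {
  partial <- c("error", "error", NA, "correct", "correct")
  expect_identical(score_disorientation(partial, policy = "strict"),
                   NA_integer_)
  expect_identical(score_disorientation(partial, policy = "lenient"), 2L)
  all_na <- rep(NA_character_, 5)
  expect_identical(score_disorientation(all_na, policy = "lenient"),
                   NA_integer_)
})

test_that("total score is additive and positivity follows the cut-off", {
  # single-feature triggers: three inattention errors alone are positive,
  # three disorientation errors alone are positive
  inatt_only <- make_assessment(inattention_errors = 3L)
  s <- score_cam_imc(inatt_only)
  expect_identical(s$total, 3L)
  expect_true(s$positive)

  dis_only <- make_assessment(dis_errors = 3L)
  s <- score_cam_imc(dis_only)
  expect_identical(s$total, 3L)
  expect_true(s$positive)

  # fluctuation + altered consciousness alone stay below the cut-off
  both_minor <- make_assessment(fluctuation = "yes", rass = 1L)
  s <- score_cam_imc(both_minor)
  expect_identical(s$total, 2L)
  expect_false(s$positive)

  normal <- score_cam_imc(make_assessment())
  expect_identical(normal$total, 0L)
  expect_false(normal$positive)

  # cut-off is a parameter
  s4 <- score_cam_imc(make_assessment(dis_errors = 3L), cutoff = 4L)
  expect_false(s4$positive)
})

test_that("every discrete response combination obeys additivity, range and triggers", {
  grid <- response_grid()
  scored <- score_cam_imc(grid)
  expect_true(all(scored$assessable))
  expect_true(all(scored$total >= 0L & scored$total <= 10L))
  recomputed <- scored$pts_fluctuation + scored$pts_consciousness +
    scored$pts_inattention + scored$pts_disorientation
  expect_identical(scored$total, as.integer(recomputed))

  dis_errs <- rowSums(as.matrix(grid[, disorientation_dimensions]) == "error")
  expect_true(all(scored$positive[grid$inattention_errors >= 3]))
  expect_true(all(scored$positive[dis_errs >= 3]))
  # fluctuation plus RASS != 0 with clean cognition is never positive
  quiet <- grid$fluctuation == "yes" & grid$rass != 0 &
    grid$inattention_errors == 0 & dis_errs == 0
  expect_true(all(!scored$positive[quiet]))

  # monotonicity: one extra inattention error never lowers the total or
  # flips a positive to negative
  bumped <- grid
  bumped$inattention_errors <- pmin(bumped$inattention_errors + 1L, 10L)
  s2 <- score_cam_imc(bumped)
  expect_true(all(s2$total >= scored$total))
  expect_true(all(!(scored$positive & !s2$positive)))
})

test_that("missing-data policy and unarousable patients control assessability", {
  rows <- dplyr::bind_rows(
    make_assessment(rass = -5L),                       # unarousable
    make_assessment(rass = -4L),                       # unarousable
    make_assessment() |> dplyr::mutate(fluctuation = NA_character_),
    make_assessment() |> dplyr::mutate(inattention_errors = NA_integer_),
    make_assessment(fluctuation = "yes", rass = 2L)    # complete
  )
  strict <- score_cam_imc(rows, policy = "strict")
  expect_identical(strict$assessable, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(
    strict$exclusion_reason[1:4],
    c("unarousable", "unarousable", "missing_feature", "missing_feature")
  )
  expect_true(all(is.na(strict$total[1:4])))

  lenient <- score_cam_imc(rows, policy = "lenient")
  # missing features score zero but the record is flagged partial
  expect_identical(lenient$assessable, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_identical(lenient$total[3:5], c(0L, 0L, 2L))
  expect_identical(lenient$partial[3:5], c(TRUE, TRUE, FALSE))

  all_missing <- make_assessment() |>
    dplyr::mutate(
      fluctuation = NA_character_, rass = NA_integer_,
      inattention_errors = NA_integer_,
      dplyr::across(dplyr::all_of(disorientation_dimensions),
                    ~NA_character_)
    )
  expect_false(score_cam_imc(all_missing, policy = "lenient")$assessable)
})

test_that("item flags dichotomize at the published item cut-offs", {
  rows <- dplyr::bind_rows(
    make_assessment(inattention_errors = 2L),
    make_assessment(inattention_errors = 3L),
    make_assessment(dis_errors = 1L),
    make_assessment(dis_errors = 2L),
    make_assessment(rass = -1L),
    make_assessment(fluctuation = "yes")
  )
  f <- add_item_flags(rows)
  expect_identical(f$inattention_positive[1:2], c(FALSE, TRUE))
  expect_identical(f$disorientation_positive[3:4], c(FALSE, TRUE))
  expect_true(f$consciousness_positive[5])
  expect_true(f$fluctuation_positive[6])
  # a fully normal record raises no flag
  f0 <- add_item_flags(make_assessment())
  expect_false(any(unlist(f0[, c(
    "fluctuation_positive", "consciousness_positive",
    "inattention_positive", "disorientation_positive"
  )])))
})

test_that("subgroup flags apply the age and Mini-Cog thresholds at boundaries", {
  baseline <- tibble::tibble(
    patient_id = c("A", "B", "C", "D"),
    age = c(68L, 64L, 65L, 70L),
    minicog = c(4L, 2L, 3L, NA)
  )
  data <- tibble::tibble(patient_id = c("A", "B", "C", "D"))
  out <- add_subgroup_flags(data, baseline)
  expect_identical(out$elderly, c(TRUE, FALSE, TRUE, TRUE))
  expect_identical(out$cognitive_impairment, c(FALSE, TRUE, FALSE, NA))
})
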