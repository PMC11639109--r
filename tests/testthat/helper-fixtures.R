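# Fixture builders used across the suite; everything is generated in code.

# one or more assessment rows, all features normal unless overridden
make_assessment <- function(n = 1, fluctuation = "no", rass = 0L,
                            inattention_errors = 0L, dis_errors = 0L,
                            patient_id = sprintf("P%03d", seq_len(n)),
                            day = 1L, rater_id = "idx1") {
  dis <- matrix("correct", nrow = n, ncol = 5,
                dimnames = list(NULL, disorientation_dimensions))
  for (i in seq_len(n)) {
    k <- rep_len(dis_errors, n)[i]
    if (k > 0) dis[i, seq_len(k)] <- "error"
  }
  dplyr::bind_cols(
    tibble::tibble(
      patient_id = patient_id, day = day, rater_id = rater_id,
      rater_role = "index",
      fluctuation = rep_len(fluctuation, n),
      rass = rep_len(as.integer(rass), n),
      inattention_errors = rep_len(as.integer(inattention_errors), n)
    ),
    tibble::as_tibble(dis)
  )
}

# index/reference call vectors reconstructed from published cut-off-3
# classification counts: 52 true positives, 32 false positives,
# 2 false negatives, 538 true negatives over 624 paired observations
printed_calls <- function() {
  list(
    index = rep(c(TRUE, TRUE, FALSE, FALSE), c(52, 32, 2, 538)),
    reference = rep(c(TRUE, FALSE, TRUE, FALSE), c(52, 32, 2, 538))
  )
}

# exhaustive grid of discrete feature responses (assessable range):
# fluctuation yes/no x RASS -3..+4 x 0..10 errors x all 2^5 disorientation
# patterns; used for the instrument property checks
response_grid <- function() {
  dis_patterns <- expand.grid(rep(list(c("correct", "error")), 5),
                              stringsAsFactors = FALSE)
  names(dis_patterns) <- disorientation_dimensions
  grid <- tidyr::crossing(
    fluctuation = c("yes", "no"),
    rass = -3:4,
    inattention_errors = 0:10,
    dis_id = seq_len(nrow(dis_patterns))
  )
  dplyr::bind_cols(grid, dis_patterns[grid$dis_id, ]) |>
    dplyr::select(-dis_id)
}
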