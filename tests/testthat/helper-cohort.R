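# Fixtures built in code: a tiny hand-checkable cohort and scaled-down
# synthetic configurations used across the test files.

toy_records <- function() {
  tibble::tibble(
    sample_id = c("S1", "S1", "S1", "S2", "S2", "S3"),
    cdr3_aa = c("CASSLAPGATNEKLFF", "CAVRDSNYQLIW", "CASSFDWGGDTQYF",
                "CASSLAPGATNEKLFF", "CASSIRSSYEQYF", "CAVRDSNYQLIW"),
    cdr3_nt = NA_character_,
    chain = c("TRB", "TRA", "TRB", "TRB", "TRB", "TRA"),
    v_call = NA_character_,
    j_call = NA_character_,
    read_count = c(12L, 3L, 2L, 5L, 4L, 7L)
  )
}

toy_metadata <- function() {
  tibble::tibble(
    sample_id = c("S1", "S2", "S3"),
    patient_id = c("P01", "P01", "P02"),
    location = c("L1", "L2", "L1"),
    timepoint = c(1L, 1L, 1L),
    sample_type = c("biopsy", "biopsy", "brush"),
    subtype = c("proliferative", "proliferative", ""),
    outcome = c("regressive", "progressive/persistent", "unknown")
  )
}

toy_cohort <- function() build_cohort(toy_records(), toy_metadata())

# Scaled-down study conditions used for fast unit tests: 12 patients, 2
# timepoints x 2 locations plus 2 brushes each, slightly deeper sampling
# so that 6 planted expansions always fit, overridable via ...
small_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_patients = 12, timepoints_per_patient = 2,
         locations_per_patient = 2, brushes_per_patient = 2,
         depth_log_mean = 5.0, n_planted_expanded = 6, seed = seed),
    list(...))
  do.call(synthetic_config, args)
}

# All planted effects switched off: no re-use boosts, no outcome effect on
# diversity, no planted expansions, and every clone drawn from the shared
# pool (p_public_draw = 1) so samples are exchangeable across patients --
# patient-private pools would otherwise elevate within-patient sharing on
# their own.
null_config <- function(seed, ...) {
  small_config(seed, within_patient_overlap_boost = 1, same_time_boost = 1,
               same_location_boost = 1, outcome_effect = 1,
               n_planted_expanded = 0, p_recurrent_expansion = 0,
               p_public_draw = 1, ...)
}

# deterministic distinct CDR3 strings for fixtures (digits -> amino acids)
.random_cdr3_fixture <- function(n) {
  sprintf("CASSL%sEQYF", chartr("0123456789", "GAVLIPFWYM",
                                sprintf("%03d", seq_len(n))))
}

# Independent brute-force oracle for the two-sided Fisher p-value: direct
# enumeration of all tables with the observed margins via binomial
# coefficients (no dhyper).
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  prob <- vapply(support, function(x) {
    exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
  }, numeric(1))
  obs <- prob[support == a]
  sum(prob[prob <= obs * (1 + 1e-7)])
}
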