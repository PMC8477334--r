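make_exp_cohort <- function(counts_by_sample, timepoints = NULL,
                            locations = NULL, patients = NULL) {
  n <- length(counts_by_sample)
  recs <- do.call(rbind, lapply(names(counts_by_sample), function(s) {
    counts <- counts_by_sample[[s]]
    tibble::tibble(
      sample_id = s, cdr3_aa = .random_cdr3_fixture(length(counts)),
      cdr3_nt = NA_character_, chain = "TRB",
      v_call = NA_character_, j_call = NA_character_,
      read_count = as.integer(counts))
  }))
  meta <- tibble::tibble(
    sample_id = names(counts_by_sample),
    patient_id = if (is.null(patients)) paste0("P", seq_len(n)) else patients,
    location = if (is.null(locations)) rep("L1", n) else locations,
    timepoint = if (is.null(timepoints)) rep(1L, n) else as.integer(timepoints),
    sample_type = "biopsy", subtype = "", outcome = "unknown")
  build_cohort(recs, meta)
}

test_that("CPT normalisation sums to 1000 per retained sample", {
  sim <- generate_cohort(small_config(14))
  exp <- call_expansions(sim$cohort)
  sums <- tapply(exp$calls$cpt, exp$calls$sample_id, sum)
  expect_true(all(abs(sums - 1000) < 1e-9))
  retained_reads <- sim$cohort$totals$total_reads[
    match(unique(exp$calls$sample_id), sim$cohort$totals$sample_id)]
  expect_true(all(retained_reads >= 250))
  expect_equal(exp$threshold$cutoff,
               exp$threshold$mean_cpt + 3 * exp$threshold$sd_cpt)
})

test_that("degenerate and extreme abundance patterns are called correctly", {
  # all observations at the same CPT: SD 0, cutoff = mean, no expansions
  flat <- make_exp_cohort(list(A = rep(100, 4), B = rep(100, 4)))
  calls <- call_expansions(flat, min_reads = 100)
  expect_equal(calls$threshold$sd_cpt, 0)
  expect_false(any(calls$calls$expanded))

  # one clone at ~900 CPT among many near-uniform clones is expanded
  dom <- make_exp_cohort(list(A = c(2700, rep(10, 30)),
                              B = rep(10, 30), C = rep(10, 30)))
  calls2 <- call_expansions(dom, min_reads = 100)
  top <- calls2$calls[order(-calls2$calls$cpt), ][1, ]
  expect_true(top$expanded)
  expect_equal(sum(calls2$calls$expanded), 1)
})

test_that("the read filter is monotone and errors when nothing passes", {
  sim <- generate_cohort(small_config(15))
  lo <- call_expansions(sim$cohort, min_reads = 250)
  hi <- call_expansions(sim$cohort, min_reads = 500)
  expect_true(all(unique(hi$calls$sample_id) %in% unique(lo$calls$sample_id)))
  expect_lte(hi$threshold$n_samples_used, lo$threshold$n_samples_used)
  expect_error(call_expansions(sim$cohort, min_reads = 1e9), "reaches")
})

test_that("planted expansions are recovered with high sensitivity and low FPR", {
  sim <- generate_cohort(small_config(16))
  exp <- call_expansions(sim$cohort)
  truth <- sim$truth$expansions
  retained <- unique(exp$calls$sample_id)
  planted <- paste(truth$sample_id, truth$key)[truth$sample_id %in% retained]
  called <- paste(exp$calls$sample_id, exp$calls$key)[exp$calls$expanded]
  expect_gte(mean(planted %in% called), 0.8)
  fpr <- length(setdiff(called, planted)) / (nrow(exp$calls) - length(planted))
  expect_lte(fpr, 0.01)
})

test_that("depth-bias check flags planted proportional bias and passes the null", {
  # expanded-clone counts proportional to depth: one extreme clone per
  # sample, detectable only in shallow samples is *not* the case here --
  # instead plant k expansions in proportion to depth
  depths <- c(300, 600, 1200, 2400)
  cohorts <- lapply(seq_along(depths), function(i) {
    n_exp <- i  # 1, 2, 3, 4 dominant clones
    base <- rep(5, 50)
    dom <- rep(round(depths[i] * 0.6 / n_exp), n_exp)
    c(dom, base)
  })
  names(cohorts) <- paste0("S", seq_along(depths))
  co <- make_exp_cohort(cohorts)
  exp <- call_expansions(co, min_reads = 100)
  bias <- depth_bias_check(exp, co$totals)
  expect_false(bias$pass)
  expect_gt(bias$estimate, 0.9)

  expect_error(depth_bias_check(
    call_expansions(make_exp_cohort(list(A = rep(50, 10), B = rep(50, 10))),
                    min_reads = 100),
    make_exp_cohort(list(A = rep(50, 10), B = rep(50, 10)))$totals),
    "3 retained")

  # null generator: expansion counts unrelated to depth in most runs
  passes <- vapply(1:5, function(s) {
    sim <- generate_cohort(small_config(s))
    depth_bias_check(call_expansions(sim$cohort), sim$cohort$totals)$pass
  }, logical(1))
  expect_gte(mean(passes), 0.6)
})

test_that("recurrence test is deterministic, add-one bounded, and label-preserving", {
  sim <- generate_cohort(small_config(17))
  exp <- call_expansions(sim$cohort)
  r1 <- recurrent_expansion_test(exp, sim$cohort$samples, n_perm = 99,
                                 seed = 42)
  r2 <- recurrent_expansion_test(exp, sim$cohort$samples, n_perm = 99,
                                 seed = 42)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$observed, r2$observed)
  expect_gte(r1$p_value, 1 / 100)

  # when every observation is expanded, permutation cannot change anything
  all_exp <- exp
  all_exp$calls$expanded <- TRUE
  r3 <- recurrent_expansion_test(all_exp, sim$cohort$samples, n_perm = 50,
                                 seed = 1)
  expect_equal(r3$p_value, 1)

  # no expansions: zero observed recurrences, p = 1
  none <- exp
  none$calls$expanded <- FALSE
  r4 <- recurrent_expansion_test(none, sim$cohort$samples, n_perm = 50,
                                 seed = 1)
  expect_equal(r4$observed, 0)
  expect_equal(r4$p_value, 1)
})

test_that("recurrently planted clones drive a small permutation p", {
  res <- t(vapply(1:6, function(s) {
    sim <- generate_cohort(small_config(s, p_recurrent_expansion = 1,
                                        timepoints_per_patient = 3,
                                        brushes_per_patient = 3,
                                        n_planted_expanded = 10))
    exp <- call_expansions(sim$cohort)
    r <- recurrent_expansion_test(exp, sim$cohort$samples, n_perm = 300,
                                  seed = 7)
    stopifnot(nrow(r$recurrent_triples) == r$observed)
    c(observed = r$observed, p = r$p_value)
  }, numeric(2)))
  expect_true(all(res[, "observed"] >= 1))
  expect_gte(sum(res[, "p"] < 0.05), 4)
})

test_that("expansion is enriched among within-patient shared clonotypes", {
  # constructed cohort: clones k1/k2 multi-sample within P1, k3-k5 single
  co <- make_exp_cohort(
    list(A = c(400, 200, 200, 200), B = c(300, 300, 400)),
    patients = c("P1", "P1"), locations = c("L1", "L2"))
  # sample A: k1..k4; sample B: k1..k3 -> k1,k2,k3 multi-within, k4 single
  rec <- co$records
  keysA <- .random_cdr3_fixture(4)
  keysB <- .random_cdr3_fixture(3)
  expect_equal(sort(unique(rec$cdr3_aa)), sort(unique(c(keysA, keysB))))

  exp <- call_expansions(co, min_reads = 100)
  res <- expansion_sharing_enrichment(exp, co)
  expect_s3_class(res, "tcr_test")
  expect_equal(sum(res$counts$n_clonotypes), 4)

  # the sample-OR convention on counts like the observed single- vs
  # multi-sample expansion rates: 10.3% of 1000 vs 3.1% of 1000
  arith <- fisher_exact_2x2(103, 897, 31, 969)
  expect_equal(arith$estimate, (103 * 969) / (897 * 31), tolerance = 1e-12)
  expect_equal(round(arith$estimate, 2), 3.59)
  expect_lt(arith$p_value, 0.001)

  # generator property at study scale: planted expansions sit in the
  # patient's re-use pool, so expansion is enriched among within-patient
  # shared clonotypes
  sim <- generate_cohort(synthetic_config())
  r <- expansion_sharing_enrichment(call_expansions(sim$cohort), sim$cohort)
  expect_gt(r$estimate, 1)
  expect_lt(r$p_value, 0.05)
})
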