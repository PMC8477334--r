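make_div_cohort <- function(counts_by_sample) {
  recs <- do.call(rbind, lapply(names(counts_by_sample), function(s) {
    counts <- counts_by_sample[[s]]
    tibble::tibble(
      sample_id = s,
      cdr3_aa = .random_cdr3_fixture(length(counts)),
      cdr3_nt = NA_character_, chain = "TRB",
      v_call = NA_character_, j_call = NA_character_,
      read_count = as.integer(counts))
  }))
  meta <- tibble::tibble(
    sample_id = names(counts_by_sample),
    patient_id = paste0("P", seq_along(counts_by_sample)),
    location = "L1", timepoint = 1L, sample_type = "biopsy",
    subtype = "proliferative", outcome = "unknown")
  build_cohort(recs, meta)
}


test_that("diversity metrics match their definitions", {
  co <- make_div_cohort(list(A = rep(20, 10)))  # 10 clones, 200 reads
  d <- compute_diversity(co)
  expect_equal(d$cpk, 50)

  co2 <- make_div_cohort(list(A = rep(1, 8)))   # every read its own clone
  d2 <- compute_diversity(co2)
  expect_equal(d2$cpk, 1000)
  expect_equal(d2$simpson, 1 - 1 / 8)

  co3 <- make_div_cohort(list(A = c(3, 1, 1)))
  d3 <- compute_diversity(co3)
  expect_equal(d3$shannon,
               -(0.6 * log(0.6) + 2 * 0.2 * log(0.2)), tolerance = 1e-12)
  expect_equal(d3$shannon, 0.9502705, tolerance = 1e-6)
  expect_equal(d3$simpson, 1 - (0.36 + 0.04 + 0.04), tolerance = 1e-12)
})

test_that("diversity is invariant to record order and bounded by ln(richness)", {
  sim <- generate_cohort(small_config(8))
  co <- sim$cohort
  d1 <- compute_diversity(co)
  withr::with_seed(2, perm <- sample(nrow(co$records)))
  rec <- co$records[perm, ]
  co2 <- build_cohort(rec[setdiff(names(rec), "key")], co$samples)
  d2 <- compute_diversity(co2)
  expect_equal(d1[order(d1$sample_id), ], d2[order(d2$sample_id), ])
  expect_true(all(d1$shannon <= log(d1$unique_clonotypes) + 1e-12))
  expect_true(all(d1$cpk > 0 & d1$cpk <= 1000))
})

test_that("subsampling reads never raises richness and keeps CPK in range", {
  withr::with_seed(13, {
    counts <- c(50, 20, 10, 5, 5, 3, 2, 2, 2, 1)
    reads <- rep(seq_along(counts), counts)
    for (frac in c(0.8, 0.5, 0.2)) {
      sub <- table(sample(reads, round(length(reads) * frac)))
      co <- make_div_cohort(list(A = as.integer(sub)))
      d <- compute_diversity(co)
      expect_lte(d$unique_clonotypes, length(counts))
      expect_true(d$cpk > 0 && d$cpk <= 1000)
      expect_lte(d$shannon, log(d$unique_clonotypes) + 1e-12)
    }
  })
})

test_that("metagene score is the mean per-gene z-score with guards", {
  expr <- matrix(rep(c(1, 2, 3, 4), 3), nrow = 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"), paste0("S", 1:4)))
  expr["g2", ] <- 5  # zero variance: dropped
  expect_message(sc <- metagene_score(expr, c("g1", "g2", "g3")),
                 "zero-variance")
  z <- as.numeric(scale(c(1, 2, 3, 4)))
  expect_equal(sc$score, z, tolerance = 1e-12)

  # a single standardised gene is returned unchanged
  one <- matrix(z, nrow = 1, dimnames = list("g1", paste0("S", 1:4)))
  expect_equal(metagene_score(one, "g1")$score, z, tolerance = 1e-12)

  # perfectly anticorrelated genes cancel to zero
  two <- rbind(g1 = z, g2 = -z)
  colnames(two) <- paste0("S", 1:4)
  expect_equal(metagene_score(two, c("g1", "g2"))$score, rep(0, 4),
               tolerance = 1e-12)

  expect_error(metagene_score(expr, c("nope1", "nope2")), "nope1")
  all_const <- matrix(2, 2, 3, dimnames = list(c("g1", "g2"), paste0("S", 1:3)))
  expect_equal(suppressMessages(metagene_score(all_const, c("g1", "g2")))$score,
               rep(0, 3))
})

test_that("depth dependence requires repeated patients and ranks metrics", {
  sim <- generate_cohort(small_config(9))
  div <- compute_diversity(sim$cohort, sample_type = "biopsy")
  pat <- sim$cohort$samples$patient_id[match(div$sample_id,
                                             sim$cohort$samples$sample_id)]
  expect_error(depth_dependence(div[1:4, ], "cpk", rep("P1", 4)), "patients")
  # Shannon tracks read depth far more strongly than CPK by construction
  p_cpk <- depth_dependence(div, "cpk", pat)$p_value
  p_sha <- depth_dependence(div, "shannon", pat)$p_value
  expect_lt(p_sha, p_cpk)
})

test_that("CPK-module association is negative on the planted cohort", {
  sim <- generate_cohort(small_config(10))
  div <- compute_diversity(sim$cohort, sample_type = "biopsy")
  pat <- sim$cohort$samples$patient_id[match(div$sample_id,
                                             sim$cohort$samples$sample_id)]
  sc <- metagene_score(sim$expression, sim$module_genes)
  assoc <- diversity_module_association(div, sc, pat)
  expect_lt(assoc$estimate, 0)
  expect_lt(assoc$p_value, 0.05)
})

test_that("outcome comparison filters by subtype and detects the planted effect", {
  # a reduced clone pool in regressive lesions lowers their CPK; with the
  # proliferative subset being small, assert the direction and the
  # rejection over a majority of replicates
  res <- t(vapply(1:5, function(s) {
    sim <- generate_cohort(small_config(s, outcome_effect = 0.6,
                                        n_patients = 24))
    div <- compute_diversity(sim$cohort, sample_type = "biopsy")
    oc <- outcome_comparison(div, sim$cohort$samples)
    # direction on the median: CPK has a long right tail from shallow
    # samples and the comparison itself is a rank test
    lower <- oc$summary$median_cpk[oc$summary$outcome == "regressive"] <
      oc$summary$median_cpk[oc$summary$outcome == "progressive/persistent"]
    c(lower = lower, sig = oc$test$p_value < 0.05)
  }, logical(2)))
  expect_gte(sum(res[, "lower"]), 4)
  expect_gte(sum(res[, "sig"]), 3)

  # restricting to a non-existent subtype empties a group
  sim <- generate_cohort(small_config(11))
  div <- compute_diversity(sim$cohort, sample_type = "biopsy")
  expect_error(outcome_comparison(div, sim$cohort$samples,
                                  subtype = "no-such-subtype"), "nonempty")
})
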