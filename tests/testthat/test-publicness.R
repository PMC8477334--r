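make_pub_cohort <- function() {
  recs <- tibble::tibble(
    sample_id = c("S1", "S1", "S1", "S2", "S3", "S3"),
    cdr3_aa = c("CASSSHAREDAF", "CASSREFONLYF", "CAVREFALPHAW",
                "CASSSHAREDAF", "CASSPRIVATEF", "CAVREFALPHAW"),
    cdr3_nt = NA_character_,
    chain = c("TRB", "TRB", "TRA", "TRB", "TRB", "TRA"),
    v_call = NA_character_, j_call = NA_character_,
    read_count = c(5L, 3L, 2L, 4L, 6L, 1L))
  meta <- tibble::tibble(
    sample_id = c("S1", "S2", "S3"),
    patient_id = c("P1", "P2", "P1"),
    location = c("L1", "L1", "MS"),
    timepoint = 1L,
    sample_type = c("biopsy", "biopsy", "brush"),
    subtype = "", outcome = "unknown")
  build_cohort(recs, meta)
}

test_that("publicness follows the two-patient / beta-reference rule", {
  co <- make_pub_cohort()
  ref <- c("CASSREFONLYF", "CAVREFALPHAW")
  ann <- classify_public(co, ref)

  get <- function(aa) ann[ann$cdr3_aa == aa, ]
  expect_true(get("CASSSHAREDAF")$public)        # P1 and P2
  expect_equal(get("CASSSHAREDAF")$n_patients, 2L)
  expect_true(get("CASSREFONLYF")$public)        # one patient, beta + in ref
  expect_true(get("CASSREFONLYF")$in_reference)
  # alpha chain never qualifies through the beta reference
  expect_false(get("CAVREFALPHAW")$public)
  expect_false(get("CAVREFALPHAW")$in_reference)
  expect_false(get("CASSPRIVATEF")$public)

  # empty reference reduces exactly to the n_patients >= 2 rule
  ann0 <- classify_public(co)
  expect_equal(ann0$public, ann0$n_patients >= 2)
})

test_that("publicness is monotone under adding samples", {
  co <- make_pub_cohort()
  ann_before <- classify_public(co)
  rec <- co$records
  extra <- rec[rec$sample_id == "S3" & rec$cdr3_aa == "CASSPRIVATEF", ]
  extra$sample_id <- "S4"
  meta2 <- rbind(co$samples, tibble::tibble(
    sample_id = "S4", patient_id = "P3", location = "L1", timepoint = 1L,
    sample_type = "biopsy", subtype = "", outcome = "unknown"))
  rec2 <- rbind(rec, extra)
  co2 <- build_cohort(rec2[setdiff(names(rec2), "key")], meta2)
  ann_after <- classify_public(co2)
  shared <- intersect(ann_before$key, ann_after$key)
  before <- ann_before$public[match(shared, ann_before$key)]
  after <- ann_after$public[match(shared, ann_after$key)]
  expect_true(all(after >= before))
  expect_true(ann_after$public[ann_after$cdr3_aa == "CASSPRIVATEF"])
})

test_that("database annotation matches exactly and chain-aware", {
  co <- make_pub_cohort()
  ann <- classify_public(co)
  mcpas <- tibble::tibble(db = "McPAS-TCR", cdr3_aa = "CASSSHAREDAF",
                          chain = "TRB", antigen = "pp65", species = "CMV")
  vdjdb <- tibble::tibble(db = "VDJdb",
                          cdr3_aa = c("CASSSHAREDAF", "CAVREFALPHAW"),
                          chain = c("TRB", "TRB"),
                          antigen = c("pp65", "M1"),
                          species = c("CMV", "InfluenzaA"))
  out <- annotate_databases(ann, list(mcpas, vdjdb))
  expect_equal(out$n_db_hits[out$cdr3_aa == "CASSSHAREDAF"], 2L)
  # TRB-declared row does not match the TRA clonotype of the same sequence
  expect_equal(out$n_db_hits[out$cdr3_aa == "CAVREFALPHAW"], 0L)
  # chain-agnostic rows ("" chain) match any chain
  vdjdb$chain <- ""
  out2 <- annotate_databases(ann, list(vdjdb))
  expect_equal(out2$n_db_hits[out2$cdr3_aa == "CAVREFALPHAW"], 1L)
  # no matches at all
  none <- annotate_databases(ann, list(tibble::tibble(
    db = "VDJdb", cdr3_aa = "CASSABSENTF", chain = "", antigen = "x",
    species = "y")))
  expect_true(all(none$n_db_hits == 0))
})

test_that("database readers skip malformed rows and reject bad schemas", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("CDR3.beta.aa,CDR3.alpha.aa,Pathology,Antigen.protein",
               "CASSLGQAYEQYF,,CMV,pp65",
               ",,CMV,pp65",
               "CASS*BAD,,EBV,BMLF1"), f)
  expect_message(tab <- read_mcpas(f), "2 malformed")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$chain, "TRB")
  writeLines("wrong,header", f)
  expect_error(read_mcpas(f), "McPAS column")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cdr3\tgene\tantigen.epitope\tantigen.species",
               "CASSLGQAYEQYF\tTRB\tpp65\tCMV",
               "\tTRB\tpp65\tCMV"), f2)
  expect_message(tab2 <- read_vdjdb(f2), "1 malformed")
  expect_equal(nrow(tab2), 1)
})

test_that("db enrichment needs both classes and some hits", {
  co <- make_pub_cohort()
  ann <- classify_public(co, c("CASSREFONLYF"))
  expect_error(db_enrichment_public_vs_private(ann), "annotate_databases")
  ann <- annotate_databases(ann, list(tibble::tibble(
    db = "VDJdb", cdr3_aa = "CASSSHAREDAF", chain = "TRB",
    antigen = "pp65", species = "CMV")))
  res <- db_enrichment_public_vs_private(ann)
  expect_true(res$estimate > 1)
  expect_equal(res$rates$n_hit, c(1L, 0L))

  all_pub <- ann
  all_pub$public <- TRUE
  expect_error(db_enrichment_public_vs_private(all_pub), "both classes")
})

test_that("public_among_expanded reports both comparison sets and degeneracy", {
  sim <- generate_cohort(small_config(19))
  ref <- generate_reference_set(small_config(19))
  ann <- classify_public(sim$cohort, ref)
  exp <- call_expansions(sim$cohort)
  res <- public_among_expanded(ann, exp)
  expect_false(res$test_all$degenerate)
  expect_false(res$test_observed$degenerate)
  expect_true(is.finite(res$test_all$test$estimate))

  # all clones public: the table degenerates and is flagged
  ann2 <- ann
  ann2$public <- TRUE
  res2 <- public_among_expanded(ann2, exp)
  expect_true(res2$test_all$degenerate)

  none <- exp
  none$calls$expanded <- FALSE
  expect_error(public_among_expanded(ann, none), "no expanded")

  # recurrent triples feed the recurrent public fraction
  rec <- recurrent_expansion_test(exp, sim$cohort$samples, n_perm = 50,
                                  seed = 2)
  if (nrow(rec$recurrent_triples) > 0) {
    res3 <- public_among_expanded(ann, exp, rec$recurrent_triples)
    expect_true(res3$recurrent_public_fraction >= 0 &&
                  res3$recurrent_public_fraction <= 1)
  }
})

test_that("removing public clonotypes leaves the planted conclusions intact", {
  sim <- generate_cohort(small_config(20))
  ref <- generate_reference_set(small_config(20))
  ann <- classify_public(sim$cohort, ref)
  sc <- metagene_score(sim$expression, sim$module_genes)
  sens <- sensitivity_without_public(sim$cohort, ann, sc)
  expect_equal(nrow(sens), 6)
  expect_setequal(unique(sens$cohort), c("full", "private_only"))
  full <- sens[sens$cohort == "full", ]
  priv <- sens[sens$cohort == "private_only", ]
  # same signs for the CPK-module slope, both sharing ANOVAs significant
  slope <- function(d) d$estimate[d$analysis == "cpk_module_association"]
  expect_equal(sign(slope(full)), sign(slope(priv)))
  expect_lt(full$p_value[full$analysis == "sharing_group_anova"], 0.05)
  expect_lt(priv$p_value[priv$analysis == "sharing_group_anova"], 0.05)

  # an all-public cohort cannot be re-run
  ann_all <- ann
  ann_all$public <- TRUE
  expect_error(sensitivity_without_public(sim$cohort, ann_all, sc),
               "no private")
})
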