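# Clonal-expansion calling. Within-sample clone abundances are normalised
# to counts per thousand reads (CPT); a clone is called expanded when its
# CPT exceeds the cohort-wide mean + 3 SD of all pooled (clonotype, sample)
# CPT observations. Samples with fewer than 250 total TCR reads are removed
# first, because low totals inflate per-clone normalised counts.

#' Call expanded clones
#'
#' @param cohort A `tcr_cohort`.
#' @param min_reads Minimum total TCR reads for a sample to enter the
#'   analysis (default 250).
#' @param sd_multiplier Threshold is `mean + sd_multiplier * SD` of the
#'   pooled CPT observations (default 3).
#' @param sample_type Sample type analysed (default `"biopsy"`).
#' @return A list with `threshold` (fields `mean_cpt`, `sd_cpt`, `cutoff`,
#'   `n_samples_used`, `n_samples_filtered`) and `calls` (tibble:
#'   `sample_id`, `key`, `chain`, `cdr3_aa`, `cpt`, `expanded`). Clones
#'   absent from a sample contribute no zero observations: the mean/SD are
#'   taken over detected clones only.
#' @export
call_expansions <- function(cohort, min_reads = 250, sd_multiplier = 3,
                            sample_type = "biopsy") {
  stopifnot(inherits(cohort, "tcr_cohort"))
  meta <- cohort$samples[cohort$samples$sample_type == sample_type, ,
                         drop = FALSE]
  tot <- cohort$totals[match(meta$sample_id, cohort$totals$sample_id), ]
  keep <- tot$total_reads >= min_reads
  if (!any(keep)) {
    stop("no ", sample_type, " sample reaches ", min_reads, " total reads")
  }
  retained <- tot$sample_id[keep]
  rec <- cohort$records[cohort$records$sample_id %in% retained, , drop = FALSE]
  totals <- tot$total_reads[match(rec$sample_id, tot$sample_id)]
  cpt <- rec$read_count / totals * 1000
  mean_cpt <- mean(cpt)
  sd_cpt <- stats::sd(cpt)
  if (is.na(sd_cpt)) sd_cpt <- 0
  cutoff <- mean_cpt + sd_multiplier * sd_cpt
  calls <- tibble::tibble(
    sample_id = rec$sample_id,
    key = rec$key,
    chain = rec$chain,
    cdr3_aa = rec$cdr3_aa,
    cpt = cpt,
    expanded = cpt > cutoff
  )
  list(
    threshold = list(mean_cpt = mean_cpt, sd_cpt = sd_cpt, cutoff = cutoff,
                     n_samples_used = sum(keep),
                     n_samples_filtered = sum(!keep)),
    calls = calls
  )
}

#' Depth-bias check for expansion calls
#'
#' Pearson correlation between a sample's number of expanded clones and
#' its total TCR reads. The read filter is adequate when this association
#' is non-significant (`pass` is `TRUE` when p > 0.05).
#'
#' @param expansions Output of [call_expansions()].
#' @param totals The cohort `totals` tibble (or any tibble with
#'   `sample_id`, `total_reads`).
#' @return A [tcr_test] with an extra `pass` field.
#' @export
depth_bias_check <- function(expansions, totals) {
  calls <- expansions$calls
  samples <- unique(calls$sample_id)
  if (length(samples) < 3) stop("need at least 3 retained samples")
  n_exp <- vapply(samples, function(s) {
    sum(calls$expanded[calls$sample_id == s])
  }, numeric(1))
  reads <- totals$total_reads[match(samples, totals$sample_id)]
  if (stats::sd(n_exp) == 0) {
    # no variation in expanded-clone counts: no depth association possible
    res <- tcr_test(NA_real_, 1, 0, "pearson correlation (constant counts)")
  } else {
    res <- correlation_test(n_exp, reads, method = "pearson")
  }
  res$pass <- res$p_value > 0.05
  res
}

.recurrence_count <- function(expanded, patient, location, key, timepoint) {
  idx <- which(expanded)
  if (length(idx) == 0) return(0L)
  trip <- paste(patient[idx], location[idx], key[idx], sep = "\r")
  tp_by_trip <- split(timepoint[idx], trip)
  sum(vapply(tp_by_trip, function(t) length(unique(t)) >= 2, logical(1)))
}

#' Permutation test for recurrent expansion
#'
#' The observed statistic is the number of distinct (patient, location,
#' clonotype) triples expanded at two or more timepoints. The null is
#' built by shuffling the expanded / not-expanded labels uniformly across
#' all (clonotype, sample) observations of the retained samples,
#' preserving the total number of expanded labels, and recounting
#' recurrences; the p-value uses the add-one rule, so exceeding all 1000
#' default draws reports `p = 1/1001 < 0.001`.
#'
#' @param expansions Output of [call_expansions()].
#' @param metadata Sample metadata with `sample_id`, `patient_id`,
#'   `location`, `timepoint`.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Seed for the permutation draws (default 17).
#' @return A list with `observed`, `p_value`, `n_perm`, and
#'   `recurrent_triples` (tibble: `patient_id`, `location`, `key`).
#' @export
recurrent_expansion_test <- function(expansions, metadata, n_perm = 1000,
                                     seed = 17) {
  calls <- expansions$calls
  m <- metadata[match(calls$sample_id, metadata$sample_id), , drop = FALSE]
  observed <- .recurrence_count(calls$expanded, m$patient_id, m$location,
                                calls$key, m$timepoint)
  null_draws <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      .recurrence_count(sample(calls$expanded), m$patient_id, m$location,
                        calls$key, m$timepoint)
    }, numeric(1))
  })
  idx <- which(calls$expanded)
  trip <- paste(m$patient_id[idx], m$location[idx], calls$key[idx],
                sep = "\r")
  rec_trip <- names(which(vapply(split(m$timepoint[idx], trip),
                                 function(t) length(unique(t)) >= 2,
                                 logical(1))))
  parts <- strsplit(rec_trip, "\r", fixed = TRUE)
  recurrent_triples <- tibble::tibble(
    patient_id = vapply(parts, `[`, "", 1),
    location = vapply(parts, `[`, "", 2),
    key = vapply(parts, `[`, "", 3)
  )
  list(observed = observed,
       p_value = permutation_p(observed, null_draws),
       n_perm = n_perm,
       recurrent_triples = recurrent_triples)
}

#' Expansion enrichment among within-patient shared clonotypes
#'
#' Compares the expansion rate of clonotypes found in a single sample with
#' that of clonotypes found in two or more samples of the same patient
#' (clonotypes shared only across patients are excluded). A clonotype
#' counts as expanded when it is expanded in at least one retained sample.
#'
#' @param expansions Output of [call_expansions()].
#' @param cohort The `tcr_cohort` the calls came from.
#' @param sample_type Sample type over which occurrence is counted
#'   (default `"biopsy"`).
#' @return A [tcr_test] (Fisher's exact test) with an extra `counts`
#'   field: per-category clonotype and expanded-clonotype counts.
#' @export
expansion_sharing_enrichment <- function(expansions, cohort,
                                         sample_type = "biopsy") {
  calls <- expansions$calls
  meta <- cohort$samples
  rec <- cohort$records[
    cohort$records$sample_id %in%
      meta$sample_id[meta$sample_type == sample_type], , drop = FALSE]
  pat <- meta$patient_id[match(rec$sample_id, meta$sample_id)]
  n_samples <- tapply(rec$sample_id, rec$key,
                      function(s) length(unique(s)))
  max_within <- tapply(seq_len(nrow(rec)), rec$key, function(i) {
    max(table(pat[i]))
  })
  category <- ifelse(n_samples == 1, "single_sample",
                     ifelse(max_within >= 2, "multi_within_patient", NA))
  expanded_keys <- unique(calls$key[calls$expanded])
  keys <- names(n_samples)
  keep <- !is.na(category)
  if (!any(category[keep] == "single_sample") ||
      !any(category[keep] == "multi_within_patient")) {
    stop("both sharing categories must be nonempty")
  }
  is_exp <- keys %in% expanded_keys
  a <- sum(is_exp & category == "multi_within_patient", na.rm = TRUE)
  b <- sum(!is_exp & category == "multi_within_patient", na.rm = TRUE)
  c <- sum(is_exp & category == "single_sample", na.rm = TRUE)
  d <- sum(!is_exp & category == "single_sample", na.rm = TRUE)
  res <- fisher_exact_2x2(a, b, c, d)
  res$counts <- tibble::tibble(
    category = c("multi_within_patient", "single_sample"),
    n_clonotypes = c(a + b, c + d),
    n_expanded = c(a, c),
    pct_expanded = c(a / (a + b), c / (c + d)) * 100
  )
  res
}
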