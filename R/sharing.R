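# All-pairs clone-sharing enrichment between biopsies. Every unordered
# pair of biopsy repertoires is tested by Fisher's exact test on the 2x2
# table (shared, A-only, B-only, neither) against the cohort-wide
# clonotype universe, FDR is controlled jointly over all pairs, and pairs
# are grouped by whether they share patient, anatomic location, and
# timepoint.

.SHARING_GROUPS <- c("different_patient", "same_patient_only",
                     "same_patient_same_location", "same_patient_same_time")

#' 2x2 sharing table for a pair of repertoires
#'
#' Cells, row-major: `a` = clonotypes shared by both samples, `b` = in A
#' only, `c` = in B only, `d` = in neither (universe minus the union).
#'
#' @param keys_a,keys_b Character vectors of clonotype keys of the two
#'   samples.
#' @param universe_size Size of the cohort clonotype universe; must be at
#'   least the size of the union.
#' @return Integer vector `c(a, b, c, d)`.
#' @export
pair_table <- function(keys_a, keys_b, universe_size) {
  keys_a <- unique(keys_a); keys_b <- unique(keys_b)
  a <- length(intersect(keys_a, keys_b))
  b <- length(keys_a) - a
  c <- length(keys_b) - a
  if (universe_size < a + b + c) {
    stop("universe smaller than the union of the two repertoires")
  }
  c(a = a, b = b, c = c, d = as.integer(universe_size) - a - b - c)
}

.pair_group <- function(same_patient, same_location, same_time) {
  ifelse(!same_patient, "different_patient",
         ifelse(same_time, "same_patient_same_time",
                ifelse(same_location, "same_patient_same_location",
                       "same_patient_only")))
}

#' All-pairs clone-sharing enrichment
#'
#' Tests every unordered pair of biopsy samples for enrichment of shared
#' clonotypes by Fisher's exact test against the cohort clonotype universe
#' (which includes brushes when loaded), adjusts the p-values jointly by
#' BH-FDR, and labels each pair by shared patient/location/timepoint. A
#' pair is `enriched` when `fdr < fdr_threshold` and the odds ratio
#' exceeds 1. Samples with empty repertoires are excluded with a message.
#'
#' @param cohort A `tcr_cohort`.
#' @param sample_type Sample type to pair (default `"biopsy"`).
#' @param fdr_threshold Enrichment FDR cut-off (default 0.01).
#' @return A tibble with one row per pair: `sample_a`, `sample_b`,
#'   `shared`, `a_only`, `b_only`, `neither`, `or_estimate`, `log2_or`,
#'   `p`, `fdr`, `enriched`, `group`.
#' @export
pairwise_enrichment <- function(cohort, sample_type = "biopsy",
                                fdr_threshold = 0.01) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  meta <- cohort$samples[cohort$samples$sample_type == sample_type, ,
                         drop = FALSE]
  tot <- cohort$totals[match(meta$sample_id, cohort$totals$sample_id), ]
  empty <- tot$unique_clonotypes == 0
  if (any(empty)) {
    message(sum(empty), " empty-repertoire sample(s) excluded from pairing")
    meta <- meta[!empty, , drop = FALSE]
  }
  if (nrow(meta) < 2) stop("need at least two non-empty samples to pair")
  univ <- length(cohort$universe)

  rec <- cohort$records[cohort$records$sample_id %in% meta$sample_id, ]
  si <- match(rec$sample_id, meta$sample_id)
  ki <- match(rec$key, cohort$universe)
  inc <- Matrix::sparseMatrix(i = ki, j = si, x = 1,
                              dims = c(univ, nrow(meta)))
  shared_mat <- as.matrix(Matrix::crossprod(inc))
  sizes <- diag(shared_mat)

  idx <- utils::combn(nrow(meta), 2)
  ia <- idx[1, ]; ib <- idx[2, ]
  a <- shared_mat[cbind(ia, ib)]
  b <- sizes[ia] - a
  c <- sizes[ib] - a
  d <- univ - a - b - c

  p <- vapply(seq_along(a), function(i) {
    .fisher_p_two_sided(a[i], a[i] + b[i], c[i] + d[i], a[i] + c[i])
  }, numeric(1))
  or <- vapply(seq_along(a), function(i) .haldane_or(a[i], b[i], c[i], d[i]),
               numeric(1))
  fdr <- bh_fdr(pmin(1, p))

  res <- tibble::tibble(
    sample_a = meta$sample_id[ia],
    sample_b = meta$sample_id[ib],
    shared = as.integer(a), a_only = as.integer(b),
    b_only = as.integer(c), neither = as.integer(d),
    or_estimate = or, log2_or = log2(or),
    p = pmin(1, p), fdr = fdr,
    enriched = fdr < fdr_threshold & or > 1,
    group = .pair_group(meta$patient_id[ia] == meta$patient_id[ib],
                        meta$location[ia] == meta$location[ib],
                        meta$timepoint[ia] == meta$timepoint[ib])
  )
  attr(res, "universe_size") <- univ
  attr(res, "fdr_threshold") <- fdr_threshold
  res
}

#' Group summary of pair-sharing results
#'
#' Counts enriched and non-enriched pairs, the percent enriched, and the
#' mean (Haldane-corrected) odds ratio and mean log2 odds ratio per
#' sharing group. Groups with no pairs are omitted with a message.
#'
#' @param results Output of [pairwise_enrichment()].
#' @return A tibble with `group`, `non_enriched_pairs`, `enriched_pairs`,
#'   `percent_enriched`, `mean_or`, `mean_log2_or`.
#' @export
group_summary <- function(results) {
  if (nrow(results) == 0) stop("no pairs to summarise")
  present <- .SHARING_GROUPS[.SHARING_GROUPS %in% results$group]
  absent <- setdiff(.SHARING_GROUPS, present)
  if (length(absent) > 0) {
    message("group(s) with zero pairs omitted: ",
            paste(absent, collapse = ", "))
  }
  rows <- lapply(present, function(g) {
    r <- results[results$group == g, , drop = FALSE]
    n_enr <- sum(r$enriched)
    tibble::tibble(
      group = g,
      non_enriched_pairs = nrow(r) - n_enr,
      enriched_pairs = n_enr,
      percent_enriched = n_enr / nrow(r) * 100,
      mean_or = mean(r$or_estimate),
      mean_log2_or = mean(r$log2_or)
    )
  })
  do.call(rbind, rows)
}

#' Compare sharing groups on log2 odds ratio
#'
#' One-way ANOVA with Tukey HSD post hoc comparisons over per-pair log2
#' odds ratios grouped by shared patient/location/timepoint.
#'
#' @param results Output of [pairwise_enrichment()].
#' @return As [anova_tukey()]: a list with `anova` and `pairs`.
#' @export
compare_groups <- function(results) {
  anova_tukey(results$log2_or, results$group)
}
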