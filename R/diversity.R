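# Per-sample repertoire diversity and its associations with read depth,
# the immune metagene score, and lesion outcome.

#' Per-sample repertoire diversity
#'
#' Computes, for every sample with at least one TCR read, the number of
#' unique clonotypes, clonotypes per kilo-read (CPK = unique clonotypes /
#' total reads x 1000), Shannon entropy (natural log, on read-count
#' proportions) and the Gini-Simpson index (1 - sum p^2). Zero-read
#' samples are excluded with a message.
#'
#' @param cohort A `tcr_cohort`.
#' @param sample_type Optional filter: `"biopsy"` or `"brush"`.
#' @return A tibble with columns `sample_id`, `total_reads`,
#'   `unique_clonotypes`, `cpk`, `shannon`, `simpson`.
#' @export
compute_diversity <- function(cohort, sample_type = NULL) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  tot <- cohort$totals
  if (!is.null(sample_type)) {
    keep <- cohort$samples$sample_id[cohort$samples$sample_type == sample_type]
    tot <- tot[tot$sample_id %in% keep, , drop = FALSE]
  }
  zero <- tot$total_reads == 0
  if (any(zero)) {
    message(sum(zero), " zero-read sample(s) excluded from diversity")
    tot <- tot[!zero, , drop = FALSE]
  }
  counts_by_sample <- split(cohort$records$read_count,
                            cohort$records$sample_id)
  ent <- vapply(tot$sample_id, function(s) {
    p <- counts_by_sample[[s]] / sum(counts_by_sample[[s]])
    c(shannon = -sum(p * log(p)), simpson = 1 - sum(p^2))
  }, numeric(2))
  tibble::tibble(
    sample_id = tot$sample_id,
    total_reads = tot$total_reads,
    unique_clonotypes = tot$unique_clonotypes,
    cpk = tot$unique_clonotypes / tot$total_reads * 1000,
    shannon = ent["shannon", ],
    simpson = ent["simpson", ]
  )
}

#' Depth dependence of a diversity metric
#'
#' Mixed-model association of a diversity metric with total TCR reads,
#' with a patient random intercept. Used to rank candidate metrics: a
#' depth-robust metric (such as CPK) should show a much weaker association
#' than entropy-based metrics.
#'
#' @param diversity Output of [compute_diversity()].
#' @param metric One of `"cpk"`, `"shannon"`, `"simpson"`.
#' @param patient_ids Patient identifier per diversity row.
#' @return A [tcr_test] from [lmm_association()].
#' @export
depth_dependence <- function(diversity, metric = c("cpk", "shannon",
                                                   "simpson"),
                             patient_ids) {
  metric <- match.arg(metric)
  stopifnot(length(patient_ids) == nrow(diversity))
  lmm_association(diversity[[metric]], diversity$total_reads, patient_ids)
}

#' Immune metagene score
#'
#' Mean per-gene z-score (standardised across samples) over a gene set.
#' Genes with zero variance are dropped; if every module gene is
#' zero-variance the scores are all zero.
#'
#' @param expression Numeric matrix, genes in rows (rownames = gene
#'   symbols), samples in columns.
#' @param gene_set Character vector of gene symbols.
#' @return A tibble with `sample_id` and `score`.
#' @export
metagene_score <- function(expression, gene_set) {
  present <- intersect(gene_set, rownames(expression))
  if (length(present) == 0) {
    stop("no module gene found in the expression matrix; missing: ",
         paste(utils::head(gene_set, 10), collapse = ", "))
  }
  sub <- expression[present, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    message(sum(sds == 0), " zero-variance module gene(s) dropped")
  }
  sub <- sub[sds > 0, , drop = FALSE]
  score <- if (nrow(sub) == 0) {
    rep(0, ncol(expression))
  } else {
    z <- t(scale(t(sub)))
    colMeans(z)
  }
  tibble::tibble(sample_id = colnames(expression), score = unname(score))
}

#' Association between CPK and the immune module score
#'
#' Mixed-model association of per-sample CPK with the metagene score,
#' patient as the random intercept (LRT p-value). The sign of the slope is
#' the quantity of interest: a negative slope means higher immune-module
#' expression in more clonal (less diverse) samples.
#'
#' @param diversity Output of [compute_diversity()].
#' @param scores Output of [metagene_score()].
#' @param patient_ids Patient identifier per diversity row (matched by
#'   `sample_id` to `scores`).
#' @return A [tcr_test].
#' @export
diversity_module_association <- function(diversity, scores, patient_ids) {
  stopifnot(length(patient_ids) == nrow(diversity))
  idx <- match(diversity$sample_id, scores$sample_id)
  keep <- !is.na(idx)
  lmm_association(diversity$cpk[keep], scores$score[idx[keep]],
                  patient_ids[keep])
}

#' CPK by lesion outcome
#'
#' Two-sided Mann-Whitney U test of CPK between regressive and
#' progressive/persistent samples, optionally restricted to one molecular
#' subtype. No patient adjustment is applied (the comparison set typically
#' lacks repeated measures per patient).
#'
#' @param diversity Output of [compute_diversity()].
#' @param metadata Sample metadata with `sample_id`, `subtype`, `outcome`.
#' @param subtype Restrict to this molecular subtype (default
#'   `"proliferative"`); `NULL` uses all samples with known outcome.
#' @return A list with `test` (a [tcr_test]) and `summary` (per-group `n`,
#'   `mean_cpk`, `median_cpk`).
#' @export
outcome_comparison <- function(diversity, metadata,
                               subtype = "proliferative") {
  m <- metadata[match(diversity$sample_id, metadata$sample_id), , drop = FALSE]
  keep <- m$outcome %in% c("regressive", "progressive/persistent")
  if (!is.null(subtype)) keep <- keep & !is.na(m$subtype) & m$subtype == subtype
  d <- diversity[keep, , drop = FALSE]
  out <- m$outcome[keep]
  reg <- d$cpk[out == "regressive"]
  pro <- d$cpk[out == "progressive/persistent"]
  if (length(reg) == 0 || length(pro) == 0) {
    stop("both outcome groups must be nonempty after filtering")
  }
  summary <- tibble::tibble(
    outcome = c("regressive", "progressive/persistent"),
    n = c(length(reg), length(pro)),
    mean_cpk = c(mean(reg), mean(pro)),
    median_cpk = c(stats::median(reg), stats::median(pro))
  )
  list(test = mann_whitney_u(reg, pro), summary = summary)
}
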