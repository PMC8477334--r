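# Public vs private clonotype classification and antigen-specificity
# database annotation. A clonotype is public when it is found in two or
# more patients of the cohort (biopsies and brushes both count) or, for
# the beta chain, when its CDR3 is present in an external healthy-donor
# reference list; otherwise it is private.

#' Classify clonotypes as public or private
#'
#' @param cohort A `tcr_cohort`; patient counts are taken over all its
#'   samples (biopsies and brushes).
#' @param reference_beta Character vector of beta-chain CDR3 amino-acid
#'   sequences from an external healthy-donor cohort (may be empty, in
#'   which case the rule reduces to presence in two or more patients).
#' @return A tibble with `key`, `chain`, `cdr3_aa`, `n_patients`,
#'   `in_reference`, `public`.
#' @export
classify_public <- function(cohort, reference_beta = character()) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  rec <- cohort$records
  pat <- cohort$samples$patient_id[match(rec$sample_id,
                                         cohort$samples$sample_id)]
  n_pat <- tapply(pat, rec$key, function(p) length(unique(p)))
  first <- !duplicated(rec$key)
  keys <- rec$key[first]
  ann <- tibble::tibble(
    key = keys,
    chain = rec$chain[first],
    cdr3_aa = rec$cdr3_aa[first],
    n_patients = as.integer(n_pat[keys])
  )
  ann$in_reference <- ann$chain == "TRB" & ann$cdr3_aa %in% reference_beta
  ann$public <- ann$n_patients >= 2 | ann$in_reference
  ann[order(ann$key), , drop = FALSE]
}

#' Read a McPAS-TCR-style database table
#'
#' Comma-separated, with CDR3 columns `CDR3.beta.aa` / `CDR3.alpha.aa` and
#' annotation columns `Pathology` and `Antigen.protein`. Rows without a
#' CDR3 in either column are skipped with a message.
#'
#' @param path Path to the CSV file.
#' @return A normalised tibble with `db`, `cdr3_aa`, `chain`, `antigen`,
#'   `species`.
#' @export
read_mcpas <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  .normalize_mcpas(raw)
}

.normalize_mcpas <- function(raw) {
  required <- c("CDR3.beta.aa", "CDR3.alpha.aa", "Pathology",
                "Antigen.protein")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required McPAS column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  beta <- trimws(ifelse(is.na(raw$CDR3.beta.aa), "", raw$CDR3.beta.aa))
  alpha <- trimws(ifelse(is.na(raw$CDR3.alpha.aa), "", raw$CDR3.alpha.aa))
  cdr3 <- ifelse(beta != "", beta, alpha)
  chain <- ifelse(beta != "", "TRB", ifelse(alpha != "", "TRA", ""))
  bad <- cdr3 == "" | !.valid_cdr3(cdr3)
  if (any(bad)) message(sum(bad), " malformed McPAS row(s) skipped")
  tibble::tibble(db = "McPAS-TCR", cdr3_aa = cdr3[!bad],
                 chain = chain[!bad], antigen = raw$Antigen.protein[!bad],
                 species = raw$Pathology[!bad])
}

#' Read a VDJdb-style database table
#'
#' Tab-separated, with columns `cdr3`, `gene`, `antigen.epitope`,
#' `antigen.species`. Rows without a valid CDR3 are skipped with a
#' message.
#'
#' @param path Path to the TSV file.
#' @return A normalised tibble with `db`, `cdr3_aa`, `chain`, `antigen`,
#'   `species`.
#' @export
read_vdjdb <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  .normalize_vdjdb(raw)
}

.normalize_vdjdb <- function(raw) {
  required <- c("cdr3", "gene", "antigen.epitope", "antigen.species")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required VDJdb column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  cdr3 <- trimws(ifelse(is.na(raw$cdr3), "", raw$cdr3))
  bad <- cdr3 == "" | !.valid_cdr3(cdr3)
  if (any(bad)) message(sum(bad), " malformed VDJdb row(s) skipped")
  tibble::tibble(db = "VDJdb", cdr3_aa = cdr3[!bad],
                 chain = .normalize_chain(raw$gene[!bad]),
                 antigen = raw$antigen.epitope[!bad],
                 species = raw$antigen.species[!bad])
}

# Accept either the normalised layout (db/cdr3_aa/chain/antigen/species) or
# a raw McPAS-/VDJdb-style table.
.normalize_db_table <- function(tab) {
  if (all(c("db", "cdr3_aa", "chain") %in% names(tab))) return(tab)
  if ("CDR3.beta.aa" %in% names(tab)) return(.normalize_mcpas(tab))
  if ("cdr3" %in% names(tab)) return(.normalize_vdjdb(tab))
  stop("unrecognised database table layout: columns ",
       paste(utils::head(names(tab), 5), collapse = ", "))
}

#' Annotate clonotypes against antigen-specificity databases
#'
#' Exact matching on the CDR3 amino-acid sequence; chain-aware when the
#' database row declares a chain, chain-agnostic otherwise. Multiple hits
#' per clonotype are retained.
#'
#' @param annotations Output of [classify_public()].
#' @param db_tables List of normalised database tibbles (from
#'   [read_mcpas()] / [read_vdjdb()], or
#'   [generate_annotation_db()] tables passed through those readers'
#'   column layout: `db`, `cdr3_aa`, `chain`, `antigen`, `species`).
#' @return `annotations` with added columns `n_db_hits` and `db_hits` (a
#'   list-column of per-clonotype hit tibbles).
#' @export
annotate_databases <- function(annotations, db_tables) {
  db <- do.call(rbind, lapply(unname(db_tables), .normalize_db_table))
  if (is.null(db) || nrow(db) == 0) {
    annotations$n_db_hits <- 0L
    annotations$db_hits <- rep(list(tibble::tibble()), nrow(annotations))
    return(annotations)
  }
  hits <- lapply(seq_len(nrow(annotations)), function(i) {
    m <- db$cdr3_aa == annotations$cdr3_aa[i] &
      (db$chain == "" | db$chain == "unknown" |
         db$chain == annotations$chain[i])
    db[m, , drop = FALSE]
  })
  annotations$n_db_hits <- vapply(hits, nrow, integer(1))
  annotations$db_hits <- hits
  annotations
}

#' Database-hit enrichment among public vs private clonotypes
#'
#' Fisher's exact test on the 2x2 table of public/private by has-hit /
#' no-hit.
#'
#' @param annotations Output of [annotate_databases()].
#' @return A [tcr_test] with an extra `rates` field (per-class hit
#'   percentages).
#' @export
db_enrichment_public_vs_private <- function(annotations) {
  if (!"n_db_hits" %in% names(annotations)) {
    stop("annotations lack database hits; run annotate_databases() first")
  }
  pub <- annotations$public
  hit <- annotations$n_db_hits > 0
  if (!any(pub) || all(pub)) stop("both classes must be nonempty")
  if (!any(hit)) stop("no database hits: enrichment odds ratio undefined")
  a <- sum(pub & hit); b <- sum(pub & !hit)
  c <- sum(!pub & hit); d <- sum(!pub & !hit)
  res <- fisher_exact_2x2(a, b, c, d)
  res$rates <- tibble::tibble(
    class = c("public", "private"),
    n = c(a + b, c + d),
    n_hit = c(a, c),
    pct_hit = c(a / (a + b), c / (c + d)) * 100
  )
  res
}

#' Publicness among expanded clones
#'
#' Fisher's exact test on expanded / not-expanded by public / private.
#' Because the natural comparison set is ambiguous, both are reported:
#' against all annotated clonotypes and against clonotypes observed in the
#' paired sample type only. When recurrent triples are supplied, the
#' public fraction among recurrently expanded clonotypes is also
#' reported.
#'
#' @param annotations Output of [classify_public()].
#' @param expansions Output of [call_expansions()].
#' @param recurrent_triples Optional tibble from
#'   [recurrent_expansion_test()].
#' @return A list with `test_all`, `test_observed` (both [tcr_test] with a
#'   `rates` field or `NULL` when degenerate, flagged via `degenerate`),
#'   and optionally `recurrent_public_fraction`.
#' @export
public_among_expanded <- function(annotations, expansions,
                                  recurrent_triples = NULL) {
  expanded_keys <- unique(expansions$calls$key[expansions$calls$expanded])
  if (length(expanded_keys) == 0) stop("no expanded clone")
  observed_keys <- unique(expansions$calls$key)

  one_test <- function(keys) {
    ann <- annotations[annotations$key %in% keys, , drop = FALSE]
    is_exp <- ann$key %in% expanded_keys
    a <- sum(is_exp & ann$public); b <- sum(is_exp & !ann$public)
    c <- sum(!is_exp & ann$public); d <- sum(!is_exp & !ann$public)
    if ((a + c) == 0 || (b + d) == 0 || (a + b) == 0 || (c + d) == 0) {
      return(list(test = NULL, degenerate = TRUE,
                  counts = c(a = a, b = b, c = c, d = d)))
    }
    res <- fisher_exact_2x2(a, b, c, d)
    res$rates <- tibble::tibble(
      class = c("expanded", "not_expanded"),
      n = c(a + b, c + d),
      n_public = c(a, c),
      pct_public = c(a / (a + b), c / (c + d)) * 100
    )
    list(test = res, degenerate = FALSE)
  }
  out <- list(
    test_all = one_test(annotations$key),
    test_observed = one_test(observed_keys)
  )
  if (!is.null(recurrent_triples) && nrow(recurrent_triples) > 0) {
    rec_keys <- unique(recurrent_triples$key)
    pub <- annotations$public[match(rec_keys, annotations$key)]
    out$recurrent_public_fraction <- mean(pub, na.rm = TRUE)
    out$n_recurrent <- length(rec_keys)
  }
  out
}

#' Sensitivity analysis: re-run key analyses without public clonotypes
#'
#' Removes all public clonotypes from the cohort and re-runs the sharing
#' group comparison, the CPK-module association and the outcome
#' comparison, reporting full-cohort and private-only statistics side by
#' side. Conclusions are considered robust when signs and significance
#' agree.
#'
#' @param cohort A `tcr_cohort` (biopsies and brushes).
#' @param annotations Output of [classify_public()].
#' @param scores Output of [metagene_score()] for the biopsy samples.
#' @param subtype Subtype filter for the outcome comparison.
#' @param fdr_threshold Sharing enrichment FDR cut-off.
#' @return A tibble with one row per (analysis, cohort-version) giving the
#'   headline estimate and p-value.
#' @export
sensitivity_without_public <- function(cohort, annotations, scores,
                                       subtype = "proliferative",
                                       fdr_threshold = 0.01) {
  public_keys <- annotations$key[annotations$public]
  rec_priv <- cohort$records[!cohort$records$key %in% public_keys, ,
                             drop = FALSE]
  if (nrow(rec_priv) == 0) {
    stop("no private clonotype left: cannot re-run on the private-only cohort")
  }
  priv <- build_cohort(rec_priv[setdiff(names(rec_priv), "key")],
                       cohort$samples, pool_chains = cohort$pool_chains)

  run_one <- function(co, label) {
    div <- compute_diversity(co, sample_type = "biopsy")
    meta <- co$samples[match(div$sample_id, co$samples$sample_id), ]
    pairs <- pairwise_enrichment(co, fdr_threshold = fdr_threshold)
    grp <- compare_groups(pairs)
    assoc <- diversity_module_association(div, scores, meta$patient_id)
    outc <- outcome_comparison(div, co$samples, subtype = subtype)
    tibble::tibble(
      cohort = label,
      analysis = c("sharing_group_anova", "cpk_module_association",
                   "outcome_comparison"),
      estimate = c(grp$anova$estimate, assoc$estimate, outc$test$estimate),
      p_value = c(grp$anova$p_value, assoc$p_value, outc$test$p_value)
    )
  }
  rbind(run_one(cohort, "full"), run_one(priv, "private_only"))
}
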