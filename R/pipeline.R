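# End-to-end orchestration. Each stage reads its inputs from the files an
# earlier stage wrote into the output directory (the AIRR clonotype table
# and metadata TSV are the interchange format throughout), so partial
# re-runs are possible and the reader/writer path is exercised on every
# run. All outputs are plain TSV/JSON; identical configuration and seed
# give byte-identical outputs.

.PIPELINE_STAGES <- c("simulate", "diversity", "sharing", "expansion",
                      "publicness", "report")

.write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

.require_outputs <- function(out_dir, files, stage, needed_from) {
  paths <- file.path(out_dir, files)
  missing_files <- files[!file.exists(paths)]
  if (length(missing_files) > 0) {
    stop("stage '", stage, "' requires ", paste(missing_files, collapse = ", "),
         " in ", out_dir, "; run stage '", needed_from, "' first")
  }
  invisible(paths)
}

.load_cohort <- function(out_dir, min_cdr3_aa) {
  records <- read_clonotype_table(file.path(out_dir, "airr.tsv"), "airr")
  records <- filter_short_cdr3(records, min_cdr3_aa)
  metadata <- read_sample_metadata(file.path(out_dir, "metadata.tsv"))
  build_cohort(records, metadata)
}

.test_json <- function(t) {
  list(method = t$method, estimate = t$estimate, statistic = t$statistic,
       p_value = t$p_value)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in canonical order: `simulate` (synthetic
#' cohort + reference + databases), `diversity`, `sharing`, `expansion`,
#' `publicness`, `report` (run manifest with checksums). Later stages read
#' the files earlier stages wrote into `out_dir` and fail with an
#' actionable error when a dependency is missing.
#'
#' @param config A [synthetic_config()] (used by the `simulate` stage).
#' @param out_dir Output directory (created if needed).
#' @param stages Subset of the canonical stages to run.
#' @param min_cdr3_aa CDR3 length filter applied at load time (default 6).
#' @param min_sample_reads Read filter for expansion calling (default 250).
#' @param expansion_sd_multiplier SD multiplier of the expansion threshold
#'   (default 3).
#' @param fdr_threshold Sharing enrichment FDR cut-off (default 0.01).
#' @param n_permutations Permutations for the recurrence test (default
#'   1000).
#' @param seed Optional integer overriding `config$seed`; all stage seeds
#'   derive deterministically from it.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = synthetic_config(), out_dir,
                         stages = .PIPELINE_STAGES,
                         min_cdr3_aa = 6, min_sample_reads = 250,
                         expansion_sd_multiplier = 3, fdr_threshold = 0.01,
                         n_permutations = 1000, seed = NULL) {
  stages <- match.arg(stages, .PIPELINE_STAGES, several.ok = TRUE)
  stages <- .PIPELINE_STAGES[.PIPELINE_STAGES %in% stages]
  if (!is.null(seed)) config$seed <- as.integer(seed)
  .validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if ("simulate" %in% stages) {
    sim <- generate_cohort(config)
    write_airr(sim$cohort, file.path(out_dir, "airr.tsv"))
    write_sample_metadata(sim$cohort$samples, file.path(out_dir, "metadata.tsv"))
    expr <- data.frame(gene = rownames(sim$expression), sim$expression,
                       check.names = FALSE)
    .write_tsv(expr, file.path(out_dir, "expression.tsv"))
    writeLines(sim$module_genes, file.path(out_dir, "module_genes.txt"))
    writeLines(generate_reference_set(config),
               file.path(out_dir, "reference_beta.txt"))
    db <- generate_annotation_db(config)
    utils::write.csv(as.data.frame(db$mcpas),
                     file.path(out_dir, "mcpas.csv"), row.names = FALSE)
    .write_tsv(db$vdjdb, file.path(out_dir, "vdjdb.tsv"))
    .write_tsv(sim$truth$clonotypes, file.path(out_dir, "truth_clonotypes.tsv"))
    .write_tsv(sim$truth$expansions, file.path(out_dir, "truth_expansions.tsv"))
    .write_tsv(sim$truth$samples, file.path(out_dir, "truth_samples.tsv"))
  }

  if ("diversity" %in% stages) {
    .require_outputs(out_dir, c("airr.tsv", "metadata.tsv",
                                "expression.tsv", "module_genes.txt"),
                     "diversity", "simulate")
    cohort <- .load_cohort(out_dir, min_cdr3_aa)
    div <- compute_diversity(cohort, sample_type = "biopsy")
    .write_tsv(div, file.path(out_dir, "diversity.tsv"))
    expr_df <- utils::read.delim(file.path(out_dir, "expression.tsv"),
                                 check.names = FALSE)
    expr <- as.matrix(expr_df[, -1, drop = FALSE])
    rownames(expr) <- expr_df$gene
    genes <- readLines(file.path(out_dir, "module_genes.txt"))
    scores <- metagene_score(expr, genes)
    .write_tsv(scores, file.path(out_dir, "module_scores.tsv"))
    pat <- cohort$samples$patient_id[match(div$sample_id,
                                           cohort$samples$sample_id)]
    tests <- list(
      depth_dependence = lapply(
        stats::setNames(c("cpk", "shannon", "simpson"),
                        c("cpk", "shannon", "simpson")),
        function(m) .test_json(depth_dependence(div, m, pat))),
      cpk_module_association =
        .test_json(diversity_module_association(div, scores, pat))
    )
    outc <- tryCatch(outcome_comparison(div, cohort$samples), error = identity)
    if (!inherits(outc, "error")) {
      tests$outcome_comparison <- c(.test_json(outc$test),
                                    list(groups = outc$summary))
    } else {
      tests$outcome_comparison <- list(error = conditionMessage(outc))
    }
    .write_json(tests, file.path(out_dir, "diversity_tests.json"))
  }

  if ("sharing" %in% stages) {
    .require_outputs(out_dir, c("airr.tsv", "metadata.tsv"), "sharing",
                     "simulate")
    cohort <- .load_cohort(out_dir, min_cdr3_aa)
    pairs <- pairwise_enrichment(cohort, fdr_threshold = fdr_threshold)
    .write_tsv(pairs, file.path(out_dir, "sharing_pairs.tsv"))
    .write_tsv(group_summary(pairs), file.path(out_dir, "sharing_groups.tsv"))
    cmp <- compare_groups(pairs)
    .write_json(list(universe_size = attr(pairs, "universe_size"),
                     n_pairs = nrow(pairs),
                     anova = .test_json(cmp$anova),
                     tukey = cmp$pairs),
                file.path(out_dir, "sharing_tests.json"))
  }

  if ("expansion" %in% stages) {
    .require_outputs(out_dir, c("airr.tsv", "metadata.tsv"), "expansion",
                     "simulate")
    cohort <- .load_cohort(out_dir, min_cdr3_aa)
    exp <- call_expansions(cohort, min_reads = min_sample_reads,
                           sd_multiplier = expansion_sd_multiplier)
    .write_tsv(exp$calls[c("sample_id", "chain", "cdr3_aa", "cpt",
                           "expanded")],
               file.path(out_dir, "expansion_calls.tsv"))
    .write_json(exp$threshold, file.path(out_dir, "expansion_threshold.json"))
    bias <- depth_bias_check(exp, cohort$totals)
    rec <- recurrent_expansion_test(exp, cohort$samples,
                                    n_perm = n_permutations,
                                    seed = config$seed + 101L)
    shr <- expansion_sharing_enrichment(exp, cohort)
    .write_json(list(
      depth_bias = c(.test_json(bias), list(pass = bias$pass)),
      recurrence = list(observed = rec$observed, p_value = rec$p_value,
                        n_perm = rec$n_perm,
                        triples = rec$recurrent_triples),
      sharing_enrichment = c(.test_json(shr), list(counts = shr$counts))
    ), file.path(out_dir, "expansion_tests.json"))
  }

  if ("publicness" %in% stages) {
    .require_outputs(out_dir, c("airr.tsv", "metadata.tsv",
                                "reference_beta.txt", "mcpas.csv",
                                "vdjdb.tsv"), "publicness", "simulate")
    .require_outputs(out_dir, "module_scores.tsv", "publicness", "diversity")
    .require_outputs(out_dir, "expansion_calls.tsv", "publicness", "expansion")
    cohort <- .load_cohort(out_dir, min_cdr3_aa)
    ref <- readLines(file.path(out_dir, "reference_beta.txt"))
    ann <- classify_public(cohort, ref)
    ann <- annotate_databases(ann, list(
      read_mcpas(file.path(out_dir, "mcpas.csv")),
      read_vdjdb(file.path(out_dir, "vdjdb.tsv"))))
    .write_tsv(ann[setdiff(names(ann), "db_hits")],
               file.path(out_dir, "publicness.tsv"))
    exp <- call_expansions(cohort, min_reads = min_sample_reads,
                           sd_multiplier = expansion_sd_multiplier)
    rec <- recurrent_expansion_test(exp, cohort$samples,
                                    n_perm = n_permutations,
                                    seed = config$seed + 101L)
    pae <- public_among_expanded(ann, exp, rec$recurrent_triples)
    scores <- tibble::as_tibble(
      utils::read.delim(file.path(out_dir, "module_scores.tsv")))
    sens <- sensitivity_without_public(cohort, ann, scores,
                                       fdr_threshold = fdr_threshold)
    .write_tsv(sens, file.path(out_dir, "sensitivity_without_public.tsv"))
    tests <- list(
      n_clonotypes = nrow(ann),
      n_public = sum(ann$public),
      pct_public = mean(ann$public) * 100,
      db_enrichment = local({
        t <- tryCatch(db_enrichment_public_vs_private(ann), error = identity)
        if (inherits(t, "error")) list(error = conditionMessage(t))
        else c(.test_json(t), list(rates = t$rates))
      }),
      public_among_expanded = list(
        all = if (pae$test_all$degenerate) list(degenerate = TRUE)
              else c(.test_json(pae$test_all$test),
                     list(rates = pae$test_all$test$rates)),
        observed = if (pae$test_observed$degenerate) list(degenerate = TRUE)
                   else c(.test_json(pae$test_observed$test),
                          list(rates = pae$test_observed$test$rates)),
        recurrent_public_fraction = pae$recurrent_public_fraction
      )
    )
    .write_json(tests, file.path(out_dir, "publicness_tests.json"))
  }

  if ("report" %in% stages) {
    produced <- sort(setdiff(list.files(out_dir), "manifest.json"))
    if (length(produced) == 0) {
      stop("stage 'report' requires prior stage outputs in ", out_dir,
           "; run stage 'simulate' first")
    }
    manifest <- list(
      package = "pmltcr",
      version = as.character(utils::packageVersion("pmltcr")),
      seed = config$seed,
      thresholds = list(min_cdr3_aa = min_cdr3_aa,
                        min_sample_reads = min_sample_reads,
                        expansion_sd_multiplier = expansion_sd_multiplier,
                        fdr_threshold = fdr_threshold,
                        n_permutations = n_permutations),
      config = unclass(config),
      checksums = as.list(tools::md5sum(file.path(out_dir, produced)))
    )
    names(manifest$checksums) <- produced
    .write_json(manifest, file.path(out_dir, "manifest.json"))
  }
  invisible(out_dir)
}
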