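#!/usr/bin/env Rscript
# Stage 4: clonal-expansion calling and recurrence.
#
# Normalises clone abundances to counts per thousand reads (CPT) within
# each biopsy with >= 250 TCR reads, calls clones above the cohort mean +
# 3 SD as expanded, verifies the read filter removed the depth bias
# (Pearson), and tests by permutation whether the same clone is expanded
# at the same location across timepoints more often than chance.

suppressPackageStartupMessages(library(pmltcr))
out <- commandArgs(trailingOnly = TRUE)
out <- if (length(out) >= 1) out[1] else "results/study"

run_pipeline(synthetic_config(), out, stages = "expansion")

thr <- jsonlite::read_json(file.path(out, "expansion_threshold.json"))
cat(sprintf("threshold: mean %.2f + 3 x SD %.2f = %.2f CPT (%d samples used, %d below 250 reads)\n",
            thr$mean_cpt, thr$sd_cpt, thr$cutoff, thr$n_samples_used,
            thr$n_samples_filtered))
tests <- jsonlite::read_json(file.path(out, "expansion_tests.json"))
calls <- utils::read.delim(file.path(out, "expansion_calls.tsv"))
cat("expanded clone calls:", sum(calls$expanded), "of", nrow(calls),
    "observations\n")
cat("depth-bias check: Pearson p =",
    format(tests$depth_bias$p_value, digits = 3),
    if (isTRUE(tests$depth_bias$pass)) "(PASS: no depth association)" else
      "(FAIL)", "\n")
cat("recurrent expansion: observed =", tests$recurrence$observed,
    "triples expanded at >= 2 timepoints, permutation p =",
    format(tests$recurrence$p_value, digits = 3), "\n")
cat("expansion among within-patient shared clonotypes: OR =",
    format(tests$sharing_enrichment$estimate, digits = 3),
    ", p =", format(tests$sharing_enrichment$p_value, digits = 3), "\n")
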