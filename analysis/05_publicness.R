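#!/usr/bin/env Rscript
# Stage 5: public/private classification and database annotation.
#
# A clonotype is public when found in >= 2 patients (biopsies and brushes
# both count) or, for the beta chain, in the healthy-donor reference list.
# Clonotypes are matched exactly against the McPAS-TCR-like and
# VDJdb-like antigen-specificity tables; enrichment of database hits
# among public clones and of public clones among expansions is tested by
# Fisher's exact test. A sensitivity analysis re-runs the headline
# analyses without public clonotypes. Finishes with the run manifest.

suppressPackageStartupMessages(library(pmltcr))
out <- commandArgs(trailingOnly = TRUE)
out <- if (length(out) >= 1) out[1] else "results/study"

run_pipeline(synthetic_config(), out, stages = c("publicness", "report"))

tests <- jsonlite::read_json(file.path(out, "publicness_tests.json"))
cat(sprintf("public clonotypes: %d of %d (%.1f%%)\n", tests$n_public,
            tests$n_clonotypes, tests$pct_public))
cat("database hits, public vs private: OR =",
    format(tests$db_enrichment$estimate, digits = 3),
    ", p =", format(tests$db_enrichment$p_value, digits = 3), "\n")
cat("public among expanded (all clonotypes): OR =",
    format(tests$public_among_expanded$all$estimate, digits = 3),
    ", p =", format(tests$public_among_expanded$all$p_value, digits = 3),
    "\n")
sens <- utils::read.delim(file.path(out, "sensitivity_without_public.tsv"))
cat("\nsensitivity analysis without public clonotypes:\n")
print(sens, row.names = FALSE, digits = 3)
cat("\nrun manifest written to", file.path(out, "manifest.json"), "\n")
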