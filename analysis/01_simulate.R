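#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# Emulates a lung-cancer screening cohort: 50 patients, 3 yearly
# bronchoscopies with biopsies at 2 anatomic locations plus a mainstem
# brush each, log-normal TCR read depth, a shared public clone pool,
# patient-private pools with within-patient re-use boosts (strongest at
# shared timepoints), 40 planted clonal expansions (some recurring at the
# same location), and a regressive-lesion effect that lowers diversity.
# Writes the AIRR clonotype table, metadata, expression matrix, reference
# list, annotation databases and ground truth under results/study/.

suppressPackageStartupMessages(library(pmltcr))
out <- commandArgs(trailingOnly = TRUE)
out <- if (length(out) >= 1) out[1] else "results/study"

cfg <- synthetic_config()
run_pipeline(cfg, out, stages = "simulate")

cohort <- build_cohort(
  filter_short_cdr3(read_clonotype_table(file.path(out, "airr.tsv"), "airr")),
  read_sample_metadata(file.path(out, "metadata.tsv")))
print(cohort)
tot <- cohort$totals
bio <- cohort$samples$sample_type == "biopsy"
cat(sprintf("biopsies with >= 250 TCR reads: %d of %d\n",
            sum(tot$total_reads[bio] >= 250), sum(bio)))
cat("outputs written to ", out, "\n", sep = "")
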