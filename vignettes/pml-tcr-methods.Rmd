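---
title: "Methods: TCR repertoire analysis of bronchial premalignant lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TCR repertoire analysis of bronchial premalignant lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and data model

`pmltcr` analyses TCR CDR3 clonotype tables assembled from bulk RNA-seq of
endobronchial biopsies and brushes collected from high-risk patients
screened at roughly yearly intervals. The unit of observation is a
*clonotype record*: one CDR3 amino-acid sequence in one sample, with its
chain (TRA/TRB/TRG/TRD) and the number of supporting TCR reads. Assembly
itself (TRUST, MiXCR), alignment, and derivation of the expression modules
and molecular subtypes are out of scope; the package starts from the
assembled tables.

Clonotype identity is the pair **(chain, CDR3 amino-acid sequence)**.
V/J calls and nucleotide sequences are ignored for matching: repertoire
comparisons in this setting are conventionally made on the CDR3 peptide,
and keeping the chain in the key avoids counting a coincidental TRA/TRB
sequence collision as one clone. Where an analysis should deliberately
pool chains, `build_cohort(pool_chains = TRUE)` collapses the key to the
sequence alone.

At read time, sequences shorter than 6 aa are excluded (likely assembly
fragments), as are sequences containing `*` or `X` (non-productive or
ambiguous assemblies, unusable for cross-sample matching). Fractional
TRUST read estimates are rounded half-up so that all downstream
contingency tables are integer-valued. Duplicate (sample, clonotype) rows
are summed during cohort assembly, never at parse time, so the reader is
a faithful image of the input file.

## Diversity

For each biopsy with at least one TCR read we report unique clonotypes,
**CPK** (clonotypes per kilo-read, `unique / total_reads * 1000`),
Shannon entropy in nats on read-count proportions, and the Gini-Simpson
index `1 - sum(p^2)`. Shannon and Simpson are named but not defined in
most repertoire papers; these are the common conventions.

Associations involving per-sample quantities must respect the repeated
sampling of patients, so depth dependence (`metric ~ total_reads`) and
the CPK-immune-module association are tested with a linear mixed model
with a patient random intercept, fitted by maximum likelihood
(`lme4::lmer`), with the slope tested by a likelihood-ratio test against
the intercept-only model. LRT was fixed (over Wald) because it is the
more conservative and more conventional choice for a single fixed
effect; singular fits fall back to ordinary least squares on
patient-demeaned variables, flagged in the result's `method` field. The
CPK-by-outcome comparison is a plain two-sided Mann-Whitney U test
without patient adjustment: the proliferative-subtype subset is small
and typically lacks repeated measures per patient, and the package
reports both group means and medians since a rank test is directional on
the latter.

The immune *metagene score* is the mean per-gene z-score (standardised
across samples) over the module gene set, with zero-variance genes
dropped. The upstream publication that defined the modules did not
restate a formula; the mean z-score is the simplest faithful choice and
is also what the synthetic generator emits.

## Sharing

Every unordered pair of biopsies is tested for enrichment of shared
clonotypes with Fisher's exact test on the table
(shared, A-only, B-only, neither), where *neither* is filled against the
cohort-wide clonotype **universe** — all distinct clonotypes across
biopsies *and* brushes when brushes are loaded. The universe choice
mirrors how such backgrounds are constructed when assembly is run over
all samples at once; the run log records the value used.

The two-sided p-value is computed by enumeration of all tables with the
observed margins, summing the probabilities of tables no more probable
than the observed one (the standard conditional-test convention; a
relative slack of 1e-7 absorbs floating-point ties, matching common
implementations). The reported effect is the **sample odds ratio**
`(a d)/(b c)`, with the Haldane correction (+0.5 to every cell) applied
only when some cell is zero — disjoint repertoires therefore get a
finite, conservative OR instead of 0 or infinity. Note one consequence:
for two small repertoires sharing nothing, the Haldane OR
`~ 0.5 d / (b c)` is large because `d` is the whole universe; group
contrasts are therefore computed on log2 ORs within the same cohort, and
are never compared across cohorts with different universes.

FDR is controlled by Benjamini-Hochberg **once across all pairs jointly**
(cross-patient pairs included), matching a single cohort-wide threshold;
a pair is *enriched* at FDR < 0.01 and OR > 1. Pairs are labelled with
mutually exclusive groups: different patient; same patient only
(different location *and* different timepoint); same patient + location;
same patient + timepoint. Same patient + location + timepoint cannot
occur: that is a single biopsy, and the metadata reader enforces it.
Group means of log2 OR are compared by one-way ANOVA with Tukey HSD
(studentized-range p-values, pooled within-group variance); when the
pooled variance is zero the comparison is degenerate and all p-values
are reported as 1.

## Clonal expansion

Within each biopsy that has at least `min_reads = 250` total TCR reads,
clone abundances are normalised to counts per thousand reads (CPT); the
250-read floor exists because low totals inflate per-clone CPT. A clone
is **expanded** when its CPT exceeds `mean + 3 SD` computed over the
pooled set of all (clonotype, sample) CPT observations of retained
samples. Two readings of "mean across all samples" were possible; the
pooled-observation reading is used because the alternative (per-clonotype
thresholds) would make the rule depend on the cohort's clonotype universe
and be undefined for cohort-unique clones. Clones absent from a sample
contribute no structural zeros to the mean/SD for the same reason. The
`depth_bias_check` verifies the filter did its job: Pearson correlation
of per-sample expanded-clone counts with total reads, passing at
p > 0.05.

Recurrence is tested by permutation: the observed statistic is the number
of distinct (patient, location, clonotype) triples expanded at two or
more timepoints; the null shuffles the expanded/not-expanded labels
uniformly over all (clonotype, sample) observations of retained samples,
preserving the number of expanded labels, and the p-value uses the
add-one rule `p = (1 + #{null >= obs}) / (1 + n_perm)` — conservative and
never zero, so exceeding all 1000 default draws reports `p < 0.001`.
Labels are shuffled globally (not within sample): the exchangeability
hypothesis being tested is that *any* observed clone was equally likely
to carry an expanded label.

## Publicness

A clonotype is **public** when observed in two or more patients —
brushes are included here to maximise the chance of catching a second
carrier — or, for TRB only, when its CDR3 appears in an external
healthy-donor beta-chain reference list (supplied as a one-sequence-
per-line text file, so a real peripheral-blood cohort list can be dropped
in). Database annotation is an exact CDR3 match against McPAS-TCR-like
CSV and VDJdb-like TSV tables, chain-aware when the row declares a chain
and chain-agnostic otherwise. Enrichment of database hits among public
vs private clones, and of public clones among expanded clones, are
Fisher tests; because the natural comparison set for the latter is
ambiguous (all clonotypes vs biopsy-observed clonotypes), both are
reported. A sensitivity analysis drops all public clonotypes and re-runs
the sharing ANOVA, the CPK-module association and the outcome
comparison side by side.

## The synthetic cohort generator

The generator (`synthetic_config()` / `generate_cohort()`) emulates the
cohort structure the analysis assumes, with planted ground truth. Its
defaults are the study conditions used throughout the tests:

* **Design**: 50 patients x 3 procedures x 2 biopsied locations plus one
  mainstem brush per procedure (300 biopsies, 150 brushes).
* **Depth**: per-sample TCR reads are log-normal, `meanlog = 4.7`,
  `sdlog = 1.2` (median ~110 reads), putting roughly a quarter of
  biopsies above the 250-read expansion filter — the regime in which the
  filter actually matters.
* **Clone pools**: a shared public pool (600 clones) and disjoint
  per-patient private pools (300 clones each); each active clone is
  public with probability 0.25. Chains are drawn TRB-heavy
  (0.55/0.35/0.05/0.05), as in short-read assemblies. CDR3s are random
  valid peptides of length 8-20 framed C...F; there is no V(D)J
  realism and no generation-probability model.
* **Diversity scale**: a sample's active clone count is
  `active_rate = 0.04` per read, so CPK sits near 40 before multinomial
  dropout, independent of depth (which is what makes CPK the
  depth-robust metric, while Shannon grows with depth). Samples from
  regressive lesions have their active count multiplied by
  `outcome_effect = 0.8`, lowering their CPK.
* **Sharing structure**: when a patient's sample draws clones, clones
  the patient used before are up-weighted 10x, with extra factors of 6x
  if previously used at the same timepoint and 3x at the same location —
  multiplicative, so the expected ordering of pair-sharing enrichment is
  same-time > same-location > same-patient-only > cross-patient.
  Cross-patient sharing arises only through the public pool.
* **Abundances**: Dirichlet-multinomial with per-clone concentration 0.8
  (realistically overdispersed).
* **Planted expansions**: 40 (sample, clone) pairs in biopsies passing
  the read filter, at most one per sample, each given a deterministic
  weight of `expansion_fold = 50` times the mean clone weight — so the
  planted abundance is a controlled multiple and recovery is well
  defined. With probability 0.6 an expansion recurs at the same location
  at the next timepoint. Planted clones also join their patient's re-use
  pool from the start (persistent clones), which is what makes expansion
  enriched among within-patient shared clonotypes. Planted clones are
  public-pool clones with probability 0.45, above the background 0.25,
  so expansions are enriched for public clones.
* **Module score**: the per-biopsy score is minus the standardised CPK
  plus N(0, 0.5) noise, and the expression matrix carries 25 module
  genes equal to the score plus N(0, 0.4) gene noise (plus 50 decoy
  genes), so the CPK-module association is negative by construction and
  `metagene_score` recovers it.
* **Annotation databases**: public-pool clones are annotated at 8.7%,
  private clones at 1.5%, split across the two database tables with
  decoy entries added. Because downstream publicness is *empirical*
  (two patients or the beta reference), pool-public clones seen in only
  one patient and absent from the beta reference land in the private
  class, which attenuates the realised public-vs-private odds ratio to
  roughly 3-6 rather than the ~6.3 implied by the raw rates.

Everything is deterministic given the configuration seed; the reference
list and databases take separate decoy seeds derived from it, so
changing them replaces decoys but never the public core.

What the generator does **not** emulate: sequence-level realism,
HLA restriction, true clonal lineages, batch effects, or histology
grades. Passing tests therefore demonstrate that the estimators and
tests recover the statistical structure they target — not that the
biological effect sizes of any real cohort will match.

### Null configuration

For calibration checks, "all effects off" means: all re-use boosts 1, no
outcome effect, no planted expansions, **and every clone drawn from the
shared pool** (`p_public_draw = 1`). The last point matters: with
private pools active, two samples of one patient share private clones by
construction even with boosts off, so within-patient pairs would not be
exchangeable with cross-patient pairs and no test should be expected to
calibrate against that structure.

## Problem sizes and numerical choices

The test suite exercises the full study scale (50 patients) for the
parameter-recovery checks — expansion sensitivity/FPR on the default
seed, sharing-group ordering and the CPK-module association over 20
seeds — and a reduced cohort (12 patients, 2 procedures x 2 locations,
slightly deeper sampling) for fast unit tests and for the 200-replicate
null-calibration run, where rejection rates of the outcome Mann-Whitney,
the Tukey contrasts and the recurrence permutation test are required to
sit within a doubled binomial band around the nominal 5%. Exact-test
equivalence is verified against a direct binomial-coefficient enumeration
oracle on 500 random tables with N <= 40 (tolerance 1e-10), and the
Benjamini-Hochberg step against an independent prefix-minima oracle.

Degenerate inputs are handled explicitly rather than by exception:
all-zero 2x2 tables error; zero-variance groups give p = 1 in the Tukey
comparison; zero-variance module genes are dropped (all-zero scores if
none remain); empty repertoires are excluded from pairing with a logged
count; samples below the read filter are counted and reported; a cohort
in which every clonotype is public refuses the private-only sensitivity
re-run with a clear error.

## Limitations

* Identity matching only: no fuzzy CDR3 matching, so sharing is a lower
  bound under sequencing error.
* The Haldane-corrected OR is biased upward for sparse pairs; group
  contrasts should be read on the log2 scale within one cohort.
* The permutation null treats expanded labels as globally exchangeable;
  a within-sample-stratified variant would test a different (sharper)
  hypothesis and is not currently exposed.
* Mixed-model p-values rely on the chi-square approximation to the LRT,
  which is anti-conservative for very few patients; the package requires
  at least two patients with repeated samples and the tests calibrate it
  at the cohort sizes above.
* The pipeline's pair count includes all non-empty biopsy pairs; cohorts
  with other exclusion rules will produce different totals, which is why
  the run log always records the number of pairs and the universe size.
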