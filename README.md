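# tilstrat

Prognostic stratification of bulk tumor cohorts by tumor-infiltrating
T-cell (TIL) signatures derived from multiplexed single-cell profiling.

Multiplexed CITE-seq-style experiments profile T cells from several
patients and conditions in one lane: hashtag oligos (HTOs) mark the sample
of origin, antibody-derived tags (ADTs) measure surface proteins, and
paired TCR sequencing captures clonality. Subpopulations found this way
(e.g. regulatory or exhausted T-cell states) can be turned into gene
signatures and asked a clinical question: do patients in an independent
bulk cohort whose tumors are *enriched* for a signature survive differently
from patients whose tumors are *depleted* of it?

`tilstrat` implements that chain end to end:

- **`demux_hto()`** — per-barcode HTO normalization to a fixed total of 100
  and assignment to a tag, "negative" or "doublet".
- **`depth_scale_adt()` / `clr_normalize()` / `cluster_profiles()` /
  `link_by_correlation()` / `link_by_gsea()`** — ADT normalization
  (centered log-ratio within cell) and linkage of stimulated to
  nonstimulated clusters by Pearson correlation of mean ADT profiles or by
  marker-set enrichment.
- **`rank_sum_markers()` / `correlation_signature()` / `score_cells()`** —
  cluster marker signatures (one-vs-rest Wilcoxon rank-sum with a strict
  detection-fraction filter, top ~100 genes) and co-expression signatures
  (top 20–30 genes correlated with a reference gene).
- **`build_clonotypes()` / `clone_frequencies()` / `clonal_composition()` /
  `tcr_sharing_test()`** — TCR clonotypes keyed on TRB CDR3 within patient,
  clone frequencies per patient × tissue, expansion bins, and a
  within-patient permutation test of clonotype sharing between clusters.
- **`per_patient_zranks()` / `enrichment_score()` / `gsea_cohort()` /
  `classify_patients()`** — per-patient preranked gene-set enrichment: each
  patient's genes ranked by cohort-standardized z, weighted
  Kolmogorov–Smirnov enrichment score
  (hits add |z|^p / Σ|z|^p, misses subtract 1/(N−N_hits); ES is the signed
  extremum of the running sum), gene-sampling permutation null, NES,
  Benjamini–Hochberg adjustment; patients become enriched (NES > 0,
  adjusted p < 0.05), depleted (NES < 0, adjusted p < 0.05) or neither.
- **`km_estimate()` / `logrank_test()` / `stratified_survival()` /
  `stage_composition()` / `classification_overlap()`** — Kaplan–Meier
  curves and log-rank comparison of enriched vs depleted patients, stage
  restriction, stage composition and classification overlap.
- **`simulate_multiplexed_run()` / `simulate_bulk_cohort()`** — synthetic
  droplet runs and bulk survival cohorts with complete ground truth
  (negative-binomial counts, planted markers and signatures, proportional
  hazards by class and stage), plus plain-text fixture writers
  (`write_fixtures()`, MTX/CSV/GMT).

See the methods vignette
(`vignettes/til-stratification-methods.Rmd`) for the model details,
parameter conventions and the generator's assumptions.

## Worked example

```r
library(tilstrat)

# a multiplexed run: 2,000 droplets, 4 hashtags, 8% doublets, 5% ambient
run <- simulate_multiplexed_run(multiplex_sim_config(seed = 11))
demux_summary(demux_hto(run$hto))
#> doublet    HTO1    HTO2    HTO3    HTO4
#>     132     485     443     457     483

# a bulk cohort with a planted 100-gene signature and class-dependent hazard
sim <- simulate_bulk_cohort(cohort_sim_config(seed = 5))
params <- enrichment_params(n_perm = 1000, seed = 2)
res <- classify_patients(
  gsea_cohort(sim$cohort$expr, list(sig = sim$signature$genes), params),
  params)
table(res$class)
#> depleted enriched  neither
#>       60       60      180

cls <- setNames(res$class, res$patient)
sv <- stratified_survival(sim$cohort$clinical, cls)
sv$test[c("chisq", "p")]
#> $chisq
#> [1] 9.852237
#> $p
#> [1] 0.0016995
```

The demultiplexer calls 132 of 2,000 droplets doublets (the simulation
planted 8%, minus those whose second hashtag stays below threshold) and
splits the rest across the four samples. In the cohort, the enrichment
engine classifies exactly the planted 20% + 20% of patients as enriched /
depleted, and the log-rank test separates their overall survival
(χ² = 9.85, p ≈ 0.002) — the depleted class was simulated with a 3-fold
hazard.

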