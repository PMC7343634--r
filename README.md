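# tcrfocus

T-cell receptor (TCR) β-chain CDR3 repertoire analysis for matched
tumor/blood cohorts, with infiltration-integrated prognostic modelling.

## The problem

Tumor-infiltrating lymphocytes (TILs) predict outcome in ovarian cancer, but
the count of T cells alone does not say *which* clones infiltrated, how
focused the infiltrate is, or how it relates to the circulating repertoire.
`tcrfocus` implements an analysis pipeline for cohorts with deep TCR
sequencing of paired TIL and PBMC samples, immunohistochemistry (IHC) T-cell
densities, tumor-antigen serology, and survival follow-up. It is aimed at
computational immunologists and biostatisticians who need the repertoire
summary statistics, compartment-overlap metrics, and stratified
proportional-hazards models for this design in one tested toolchain — plus a
seeded synthetic cohort generator so every stage can be validated without
patient data.

## What it computes

For a repertoire with clone frequencies `p(1) ≥ p(2) ≥ … ≥ p(N)`:

* **Shannon entropy** `H(p) = −Σ p_k log2 p_k` (bits) and
  **clonality** `C(p) = 1 − H(p)/log2 N` (one minus Pielou's evenness);
* **TOP1** `p(1)`, the strength of monoclonality;
* **N25** `min{k : Σ_{j≤k} p(j) > 0.25}` (strict inequality);
* **CPK**, unique CDR3 calls per kiloread of TCR-region coverage.

For a patient's matched pair: clone- and read-level **overlap** in both
directions (e.g. the chance a random PBMC clone is also found in the tumor,
and the fraction of PBMC reads on shared clones), the **PBMC-exclusive
fraction**, and a rarefaction-based **diversity ratio** of PBMC to TIL
unique-clone counts at a common read depth. Across patients, a
**sharing table** of public clones. Integrating IHC, the **focus ratio**
(unique TIL clones per CD3/CD8/CD4 cell density): values near zero mean a
focal, monoclonal infiltrate.

Prognostic models: stage-adjusted Cox proportional hazards with hazard
ratios per unit standard deviation, log-rank tests (including the
three-way infiltration/diversity grouping), Kaplan–Meier medians,
restricted mean survival (capped at 60 months) along a covariate grid, a
Bonferroni-corrected per-clone survival screen of public clones, and a
deviance test for serology × repertoire interactions.

Standard filters from the two data dialects are built in: the 20-copy
low-level-noise rule (a clone with exactly 20 copies is kept), the
complete-CDR3 rule (initial cysteine, terminal phenylalanine) for
assembly-derived tables, and a primer-efficiency normalization hook.

## Worked example

```r
library(tcrfocus)

cfg <- cohort_config(n_patients = 30, seed = 7, fast = TRUE,
                     depth_til = c(5e3, 2e4), depth_pbmc = c(1e4, 8e4))
coh <- generate_cohort(cfg)
summarize_repertoire(coh$tils[["P001"]])
#>   patient_id compartment entropy_bits clonality diversity   top1 n25   cpk  depth
#> 1       P001         TIL        4.732     0.356       163 0.3097   1 11.27  14457
overlap_summary(coh$pbmcs[["P001"]], coh$tils[["P001"]])
#>   patient_id shared_clones clone_overlap_pbmc clone_overlap_til
#> 1       P001            48              0.015             0.294
#>   read_overlap_pbmc read_overlap_til pbmc_exclusive_clones pbmc_exclusive_reads
#> 1            0.0406            0.793                 0.985                0.959
```

Patient P001's tumor repertoire is moderately focused (clonality 0.36, the
top clone carrying 31% of reads, so N25 = 1), and only 1.5% of blood clones
— 4% of blood reads — are found in the tumor: 96% of the peripheral
repertoire is "spent" on clones that do not traffic to the tumor.

The full pipeline (filter → summarize → overlap → features → survival)
writes a tab-separated report bundle:

```r
res <- run_pipeline(pipeline_config(sim = cfg, out_dir = "report",
                                    min_copies = 0, min_share = 10, seed = 2))
head(res$models)
#>                model    hr ci_low ci_high     p  n events
#> 1          focus_cd3 1.156  0.826    1.62 0.397 30     27
#> 2 clone_overlap_pbmc 1.108  0.756    1.63 0.598 30     27
#> 3  read_overlap_pbmc 1.128  0.802    1.59 0.488 30     27
#> 4    diversity_ratio 0.883  0.581    1.34 0.562 30     27
#> 5    tertile_logrank    NA     NA      NA 0.567 30     27
#> 6 serology_x_overlap    NA     NA      NA 0.999 30     27
```

Hazard ratios are per standard deviation of the feature, adjusted for the
low/high stage stratum; at this toy cohort size none reaches significance,
as expected under the null configuration (`betas` default to 0 for the
repertoire features). A thin command-line wrapper with `simulate`,
`summarize`, `overlap`, `features`, `survival` and `run` subcommands is in
`inst/cli/tcrfocus-cli.R`.

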