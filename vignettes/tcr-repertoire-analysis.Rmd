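---
title: "Methods: TCR repertoire statistics, compartment overlap, and prognostic modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TCR repertoire statistics, compartment overlap, and prognostic modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrfocus)
```

This vignette documents the models and conventions behind `tcrfocus`: what
each statistic assumes, which choices were genuinely open and how they were
resolved, what the synthetic cohort generator does and does not emulate,
and the numerical details that matter for reproducibility.

## Data model

A *clone* (clonotype) is a unique CDR3 amino-acid sequence with a copy
number — a normalized count of reads per unique amino-acid sequence.
Nucleotide variants that translate to the same amino-acid sequence are
aggregated by summing copies: clone identity is the protein sequence.
Copy numbers are kept as reals because amplification-bias normalization
can make them fractional; the vendor's normalization itself is out of
scope and exposed only as the identity hook `normalize_copies()`.

Two table dialects are read. ImmunoSEQ-like tables carry per-clone copies;
TRUST-like tables (CDR3 calls assembled from bulk RNA-seq) carry
supporting read counts plus a sample-level TCR-region read total used by
CPK. For TRUST-like data, fragmentary calls are removed by the
complete-CDR3 rule: a sequence must start with the initial cysteine and
end with the terminal phenylalanine. Whether that rule should also apply
to deep-sequencing tables is not settled; it is exposed for both dialects
(`complete_cdr3` in `pipeline_config()`) and off by default for the
ImmunoSEQ-like path.

Copy-number filtering drops clones with *fewer than* 20 copies as
low-level noise — the boundary value 20 is kept, and the threshold is
compared against the (possibly fractional) normalized copies. Whether
summary statistics should be computed before or after filtering is also
ambiguous in practice; here the filter configuration governs the entire
run, so pre-filter values are obtained by running with `min_copies = 0`.
Both orders are supported for the overlap metrics for the same reason.

## Repertoire summary statistics

With frequencies sorted descending, ties broken lexicographically by
sequence for determinism:

* entropy `H(p) = -Σ p_k log2 p_k` in bits, with `0·log 0 ≡ 0`;
* clonality `C(p) = 1 - H(p)/log2 N`, in [0, 1]. A single-clone
  repertoire makes Pielou's index 0/0; the package defines `C = 1`
  (maximally clonal), which is the natural limit and keeps the statistic
  defined on degenerate repertoires;
* TOP1 `= p(1)`; diversity `= N`;
* N25 `= min{k : Σ_{j≤k} p(j) > 0.25}` with a *strict* inequality, so a
  uniform 8-clone repertoire has N25 = 3 (two clones reach exactly 0.25
  and fail the strict comparison). The comparison uses a 1e-9 tolerance so
  floating-point noise in the cumulative sum cannot flip a boundary case;
* CPK `= N / (reads/1000)`, using the sample-level TCR-region read count
  when the table provides one and the summed clone reads (with a warning)
  otherwise.

## Compartment overlap

Overlap is directional. The reported defaults take the blood's point of
view: `clone_overlap_pbmc` is the chance a randomly chosen PBMC clone also
occurs in the tumor, `read_overlap_pbmc` the fraction of PBMC reads on
shared clones. Their complements are the PBMC-exclusive fractions — the
part of the peripheral repertoire spent on clones that do not traffic to
the tumor. The read-weighted version is the default "exclusive fraction";
the clone-count variant is also emitted because either reading is
defensible. Both TIL-side fields are computed as well.

Unique-clone counts are strongly depth-dependent, so the PBMC/TIL
diversity ratio is computed after rarefying both repertoires to a common
depth by multivariate hypergeometric subsampling (without replacement) of
the integer-rounded copies. Each compartment is rarefied under the same
seed, which makes the draw reproducible bit for bit and gives a ratio of
exactly 1 for identical clone tables. The mean rarefied clone count is
validated in the tests against the closed-form expectation
`Σ_i (1 - C(T - c_i, d)/C(T, d))`. The alternative to rarefaction —
entering raw counts with depths as regression covariates — is available
simply by fitting `fit_cox()` on the raw ratio with depth adjusters.

The across-patient sharing table averages a public clone's frequency over
the repertoires that *contain* it (not over the whole cohort), matching
the usual presentation of sharing degree versus average frequency.

## Cohort features

* CD4 density is imputed as CD3 − CD8, clamped at 0 with a warning when
  measurement noise puts CD8 above CD3.
* The focus ratio divides unique TIL clones by the raw IHC density
  (lymphocytes/mm²). No hidden area normalization is applied; cohort
  medians of this quantity are medians of per-patient ratios.
* Stage is dichotomized to low (I–IIIB) versus high (IIIC–IV); this
  binary stratum is the stage adjustment everywhere, keeping small
  cohorts estimable where a 6-level factor would not be.
* The infiltration split is a median split of CD3 density within the
  high-stage stratum, with ties and the median point assigned to the low
  group — for an odd cohort of distinct values the low group gets the
  extra patient (39/38 for 77 patients).
* The three-way grouping (high infiltration; low infiltration/low
  diversity; low infiltration/high diversity) uses data-driven
  thresholds chosen for evenly sized groups: the top third by CD3 density
  (remainder first), then a halving of the rest by TIL diversity
  (remainder to the low-diversity group). Ties break by patient id, so
  the partition is invariant to input order.
* Seropositivity is a reciprocal ELISA titer strictly greater than 100;
  exactly 100 is negative. `any_seropositive` is the OR over NY-ESO-1,
  MAGE-A1, MAGE-A3 and p53.
* Covariates enter models scaled to unit standard deviation (optionally
  after a natural-log transform for skewed densities), so hazard ratios
  are per 1 SD and comparable across features.

## Survival models

`fit_cox()` wraps a partial-likelihood proportional-hazards fit with
Efron's tie approximation (the conventional default; the choice matters
little at these tie densities but is fixed and documented). Preconditions
are enforced: at least 10 events, a non-constant feature; non-convergence
or separation aborts with a diagnostic error rather than returning an
unstable estimate. The log-rank test supports two or more groups; the Cox
score test at β = 0 on a binary covariate reproduces it, which the tests
use as a cross-check.

Restricted mean survival (RMS) is the integral of the model survival
curve up to a 60-month cap — the clinically relevant horizon for this
disease. The integrator is trapezoidal; for step functions (Kaplan–Meier
or Cox baselines) step points are doubled so the trapezoids reduce to the
exact rectangle areas, and the curve is extended flat to the cap. On a
densely sampled exponential curve (step 0.005 months) the integrator
matches the closed form `(1 - e^{-λτ})/λ` to better than 1e-6.
`rms_curve()` evaluates the fitted model's baseline survival along a
feature grid with adjusters held at their sample mean (numeric) or modal
level (factor).

The public-clone screen fits one stage-adjusted Cox model per clone
passing the sharing threshold, on the clone's per-patient frequency
scaled to unit SD, and multiplies raw p-values by the number of clones
actually tested, capped at 1 (Bonferroni). The serology-interaction test
is a 1-df likelihood-ratio (deviance) comparison of nested Cox models
with and without the feature × serostatus term. The adjustment set
includes stage and — by default in the pipeline — CD3 infiltration as a
continuous log-density rather than a stratum, since infiltration enters
the models elsewhere on the log scale; a stratum adjustment is available
by passing a factor in `adjust`.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, with defaults chosen to resemble a 99-patient ovarian cohort:

* **Clone frequencies** follow a Zipf law (`p_k ∝ k^{-s}`), more clonal
  at the tumor site (s = 1.0) than in blood (s = 0.85); a symmetric
  Dirichlet law is available. TIL pools of 3,000–16,000 clones against
  peripheral pools of 60,000–100,000.
* **Depths** are log-uniform: TIL 2×10⁴–5×10⁶ reads (within the printed
  coverage range of deep-sequenced tumor samples), PBMC 10⁶–8×10⁶.
  Reads are sampled multinomially from the latent pool, and downstream
  filters apply to the sampled tables exactly as for real data.
* **Sharing**: 30% of TIL clones are seeded into the PBMC pool, placed on
  blood clones selected with probability ∝ frequency^0.5 so shared clones
  tend to be common in blood (making read-level overlap exceed
  clone-level overlap, as observed in real pairs); their TIL frequencies
  are multiplied by a 5-fold tumor-site enrichment and renormalized. A
  pool of 40 cohort-level public clones, each carried with probability
  0.25, supports the sharing table and the public-clone screen.
* **IHC calibration**: CD3 density (log-normal, median 100 lym/mm²) and
  TIL depth are linked by a Gaussian copula with Pearson correlation
  `2 sin(π ρ_s/6)`, which targets the Spearman correlation ρ_s = 0.34
  directly and survives the monotone marginal transforms. CD8 is a
  Beta(2,5) fraction of CD3.
* **Serology**: NY-ESO-1 prevalence 0.25; the three other antigens 0.06
  each, making the any-antigen rate ≈ 0.38. Titers are drawn strictly
  above or at/below the 100 cut-point according to the latent status.
* **Survival** is exponential under proportional hazards (chosen over
  Weibull so the restricted mean has a closed form for oracle tests):
  hazard `λ₀ exp(Σ βx)` on the z-scored focus ratio and clone overlap of
  the *observed* repertoires plus the high-stage indicator
  (β_stage = 0.7), with independent uniform censoring over 72 months.
  Baselines are 0.045/month (PFS) and 0.014/month (OS), giving medians
  near 15 and 49 months. The overlap effect can differ by serostatus
  (`betas_overlap_by_serostatus`) to emulate antigen-dependent sign
  reversal.

Because the generating hazard uses features of the observed, *unfiltered*
repertoires, recovery experiments fit on the same path (filters off);
with the 20-copy filter on, down-scaled fast-mode depths would remove
most clones and attenuate the recovered effects — a measurement-error
phenomenon, not an estimation defect.

What the generator does **not** emulate: V(D)J generation probabilities
and sequence biology (CDR3 strings are random letters with the canonical
C…F frame), antigen-driven clonal dynamics, batch effects in IHC or
serology, correlated censoring, or the real cohort's joint distribution
of diversity and clonality beyond the knobs above (only its marginal
summaries are known). Passing tests therefore validate the *pipeline's
arithmetic and inference* under a faithful proportional-hazards data
structure; they do not certify biological realism.

## Problem sizes and test design

Fast mode (`fast = TRUE`) scales depths down 100-fold and clone pools
20-fold, preserving the structure while keeping end-to-end runs cheap.
The test suite and acceptance script use: 1,000 random repertoires
(N ≤ 1,000) for statistic-oracle equivalence at 1e-9; recovery of per-SD
log hazard ratios ±0.4 on cohorts of n = 300 (three seeds plus a null
cohort, ±25% tolerance); 200 feature-level replicates for null CI
coverage (nominal 95%, accepted in [0.90, 0.98]) and for the interaction
test's type-I error at α = 0.05; and 25 full generator cohorts of
n = 400 for its power under the ∓0.4 sign-reversal alternative
(threshold 0.8). Rarefaction is validated on a 60-clone instance against
the hypergeometric closed form over 100 seeds within 2%.

## Known limitations

* The pipeline consumes CDR3 call tables; assembly, alignment and V/J
  annotation are upstream concerns.
* Hazard ratios from the cohort generator are only recoverable up to
  sampling noise of the feature definitions; no measurement-error
  correction is attempted.
* The public-clone screen uses Bonferroni, which is conservative when
  clone frequencies are correlated across patients.
* T-cell subset composition (Th1/Th2/Th17/Treg) is outside the data
  model, as are nucleotide-level clonotypes.
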