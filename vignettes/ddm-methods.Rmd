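---
title: "Health-status-aware indirect reference intervals: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Health-status-aware indirect reference intervals: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddmr)
```

## The problem

A reference interval (RI) is the central 95% range of an analyte in a
non-diseased population — the band printed next to every laboratory result.
Direct RI studies recruit healthy volunteers; indirect methods instead mine
the laboratory's own routine data, which is abundant but contaminated:
inpatient populations mix healthy-for-this-analyte results with results from
kidney disease, sepsis, diuretic treatment and so on. Classical indirect
estimators attack the contamination purely statistically (by truncation or
mixture modelling). The approach implemented here uses a piece of information
routine data already carries: up to five ICD-10 category codes (three
characters, e.g. `N18` = chronic kidney disease) attached to each result via
its administrative case. Subpopulations whose values deviate from the rest of
the stratum are identified *by their coding* and removed before the interval
is estimated.

## The pipeline

1. **Preprocessing.** One result per administrative case (the first, in file
   or timestamp order); ages restricted to 20–89 whole years; values must be
   positive, present, and inside analyte plausibility bounds (defaults 0.5
   and 12 mmol/L, suitable for plasma potassium — they exceed any survivable
   physiology and only catch unit or entry errors). Codes not matching the
   `letter + two digits` category pattern are dropped from the record; the
   record itself is kept, because its value is still a valid measurement
   (`strict_code_filter = TRUE` removes such records entirely for
   sensitivity analysis). Every removal is tallied in an audit table whose
   counts sum exactly to input minus output.
2. **Stratification.** Two sexes × seven 10-year age bands (20–29 … 80–89);
   each stratum's multiset of values is its *Global Distribution* (GD).
3. **Per-code testing.** Values are grouped by each code mentioned (a result
   with k codes feeds k groups). Groups with more than 5 results are tested
   two-sidedly against the GD: Welch's t-test when both sides pass a
   Shapiro–Wilk normality screen at `normality_alpha = 0.05`, the
   Mann–Whitney U test otherwise. False discovery over the table of codes is
   controlled with Storey–Tibshirani q-values. Rows with `q < alpha`
   (default 0.05) are significant.
4. **Differential Distribution (DD).** Every result carrying at least one
   significant code is removed from the GD (*any-code rule*); uncoded
   results always survive.
5. **Code clustering (optional).** Codes are embedded from their
   co-occurrence on results (skip-gram with negative sampling), pairwise
   cosine similarity is converted to a distance, codes are partitioned by
   bottom-up agglomerative clustering, and steps 3–4 are repeated with
   cluster groups instead of code groups ("DD with Clustering"). Pooling
   related codes lets subpopulations individually below the testing floor
   reach testable size.
6. **RI inference.** The 95% RI of GD, DD and clustered DD is estimated by
   an iterative Gaussian-mode estimator (below), with 90% confidence
   intervals on both limits, and each DD limit is compared against the GD
   limit: `adjusted` when the CIs are disjoint, `not_different` when the DD
   point estimate lies inside the GD CI, `overlap` otherwise.

## Statistical details and numerical choices

### Two-sample tests

The t-test is the unequal-variance (Welch) form: a small diagnosis group
against a whole stratum makes the equal-variance assumption indefensible.
The Mann–Whitney U statistic uses midranks; the p-value is computed by exact
enumeration of all `choose(n, n1)` group assignments whenever the combined
sample has at most 16 values (ties are then handled exactly), and by the
tie-corrected normal approximation, without continuity correction, above
that. The two-sided exact p is `min(1, 2 * min(P(U <= u), P(U >= u)))`.
Degenerate cases are fixed: two identical constant samples give p = 1; two
constant samples with different values (Welch undefined) fall back to the
rank test; a zero-variance group always routes to the rank test because its
normality is untestable. The Shapiro–Wilk screen is undefined above 5000
values, so larger reference samples are screened on a fixed-seed subsample
of 5000 — the choice is therefore deterministic, and in a table all code
groups share the one GD screen.

By default each group is tested against the *full* GD, which contains the
group itself. This self-inclusion is conservative (it drags the reference
toward the group). `compare_to_complement = TRUE` tests against GD minus the
group instead; all codes are always tested against the same reference in a
single pass, never sequentially against partially-cleaned distributions.

### Storey–Tibshirani q-values

`storey_qvalues()` estimates the null proportion pi0 by the smoother method:
`pi0(lambda) = mean(p > lambda) / (1 - lambda)` on the grid 0.05, 0.10, …,
0.90, smoothed by a df = 3 spline and read off at the largest lambda,
clamped to (0, 1]. The q-value of the i-th smallest p is
`min_{j >= i} pi0 * m * p_(j) / j`. With pi0 = 1 this is exactly
Benjamini–Hochberg, which the test suite verifies against `p.adjust()`.
Below 20 p-values the pi0 estimate is too unstable to trust and the function
falls back to pi0 = 1 (pure BH) with a warning — diagnosis tables of small
strata routinely hit this path, erring conservative.

### The iterative Gaussian-mode estimator

Reference limits could be read off the DD's empirical 2.5th/97.5th
percentiles, but any residual contamination sits exactly in those tails. The
parametric estimator instead approaches the central Gaussian mode by
iterative trimming: repeatedly compute mean m and SD s of the current set
and retain values in `[m - trim_z*s, m + trim_z*s]` (default
`trim_z = 1.96`) until both window endpoints move less than `tol = 1e-4` or
`max_iter = 50` passes.

Each pass trims an already-trimmed set, so the iteration does *not* stop at
a window of ±1.96 true SDs: writing `g(a)` for the SD of a standard normal
truncated at ±a, the population fixed point satisfies `a = trim_z * g(a)`
(≈ ±1.34 true SDs for `trim_z = 1.96`, retaining ≈ 82% of a pure Gaussian).
Consequently the converged sample SD must be divided by the
*self-consistent* factor c solving `c = g(trim_z * c)` (≈ 0.684) — this is
the SD of the standard normal truncated at the window the iteration actually
converges to. Correcting with `g(trim_z)` (≈ 0.871), as if a single trim at
±1.96 true SDs had occurred, would underestimate the SD by ~21% on clean
Gaussian data; the test suite pins the corrected estimator to the
closed-form quantiles `mu ± 1.96 sigma` instead. The limits are
`m ± qnorm(0.975) * s_corrected`, and their 90% CIs use the normal-theory
quantile standard error `s_corrected * sqrt(1/n + 1.96^2/(2n))` at the
converged n.

Convergence is declared immediately when a pass removes nothing (the window
is then a deterministic function of an unchanged set), so an already-trimmed
sample converges in one iteration. Inputs below 120 values (the classical
direct-method floor) are refused; below 5000 (the reliability guideline for
mixed patient strata) a warning is emitted. Zero-variance input, or trimming
that collapses to zero variance, is an error.

The `nonparametric` mode estimates the 2.5th/97.5th percentiles of the
supplied distribution directly — the DD already *is* the health-filtered
subpopulation — with the distribution-free binomial order-statistic CI:
ranks `n*p ∓ z*sqrt(n*p*(1-p))` rounded outward. It deliberately does not
take percentiles of the mode-trimmed set: that set is truncated at ≈ ±1.34
SDs, so its own tail percentiles estimate nothing of interest; the trimmer's
metadata (mode mean/SD, iterations) is still reported. Empirical quantiles
use linear interpolation between closest ranks (R type 7) throughout — at
small n different conventions shift percentiles, so one is fixed and
documented.

### Code embeddings and clustering

No pretrained clinical embedding is used: vectors are learned from the data
at hand, so clusters reflect the local population's comorbidity structure.
The trainer is a single-threaded skip-gram with negative sampling (5
negatives, unigram^0.75 sampling, linear learning-rate decay from 0.025)
over "sentences" that are the code lists of individual results. Defaults:
dimension 100, window 5 (≥ 4, so all pairs within a 5-code sentence
co-occur), 20 epochs, `min_count = 6` aligned with the testing floor. A
dedicated deterministic generator makes training exactly reproducible for a
fixed seed, which the suite asserts.

Cosine similarity is turned into a distance as `1 - similarity` (clamped at
0). The similarity matrix could also be *matrix*-inverted, but that is not
generally a metric and fails for singular matrices, so complementation is
the default and `distance_mode = "angular"` (`acos`) is the alternative.
Clustering is bottom-up agglomerative with average linkage — the
conventional choice for similarity-derived distances — cut at
`min(k, N)` clusters with k defaulting to 800; k-means on the raw vectors is
available. The number of clusters is deliberately left to configuration:
choosing it well needs clinical input, not statistics. Codes too rare to be
embedded become singleton pseudo-clusters, so the clustered pipeline
degrades exactly to per-code behaviour for them (with k = N it reproduces
the per-code results verbatim, which the suite checks). Clustering is fit
per stratum, consistent with the slice being tested.

## The synthetic generator

Real routine data cannot ship with the package, so every pipeline stage is
validated on `simulate_lab_data()`, which emulates a mixed inpatient
population with closed-form ground truth. Per stratum: a healthy Gaussian
core (default mean 4.0, SD 0.35 — potassium-like; medians around 4.0–4.1
mmol/L are typical of adult inpatient cohorts, and the uniform SD keeps the
true limits `4.0 ± 1.96*0.35 = 3.314/4.686` identical across strata, which
is what the recovery checks pin against; a per-band SD vector reproduces the
variance-rises-with-age pattern when wanted). Disease components (default:
eight codes, 25% total prevalence, shifts +0.40 to +1.20 mmol/L, doubled
SD, patterned on renal/cardiovascular/acute potassium effects) draw from
shifted Gaussians and carry their code; codes sharing a comorbidity block
are co-assigned with probability 0.5, planting the structure the clustering
must recover; null background codes attach to healthy results at rate 0.05
each. A moment-matched lognormal option makes disease groups right-skewed to
exercise the rank-test path.

What the generator does *not* emulate: longitudinal correlation within
patients, preanalytical artifacts (hemolysis), coding drift over time,
age-continuous physiology within a band, and real coding noise (codes
assigned for billing rather than clinical state). Passing tests therefore
demonstrate the machinery is correct under its stated model, not that any
particular hospital's coding supports the same recovery.

## Problem sizes used in validation

The acceptance-style tests run the full method at the scale the scenario
defines: 20 seeds × 14 strata × 20,000 results for contaminated-recovery
and null-safety checks; 200 null strata of 30 code groups for FDR control;
2,000 replicates at n = 2,000 for CI coverage; 100,000 draws for the
estimator fixed point; 10 seeds of two 500-sentence blocks for cluster
recovery. Unit tests use smaller fixtures chosen so each check's
Monte-Carlo error is well below its asserted tolerance.

## Known limitations

- The method assumes the healthy core is (after trimming) Gaussian;
  analytes with strongly non-Gaussian healthy distributions need a
  transformation step that is out of scope here.
- Removal is only as good as the coding: systematically uncoded disease
  contaminates the DD and biases limits toward the mixed population.
- The self-inclusion of each group in its reference GD makes the default
  tests conservative for large groups (the complement option removes this).
- Small strata fall back to pi0 = 1 and wide CIs rather than refusing to
  run; below 120 values RI estimation refuses outright.
- A fitted embedding reflects one stratum's co-occurrence; clusters are not
  transferable across sites or periods and are not clinically validated.
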