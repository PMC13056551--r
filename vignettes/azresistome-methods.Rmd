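---
title: "Methods: airway microbiome and resistome analysis under azithromycin exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: airway microbiome and resistome analysis under azithromycin exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`azresistome` analyses longitudinal upper-airway metatranscriptomic
cohorts for the footprint of empiric azithromycin: depletion of bacterial
signal, enrichment of macrolide/lincosamide/streptogramin (MLS) resistance
gene expression, shifts in community composition, and the durability of
those shifts after the drug stops. This vignette documents the models, the
tunable parameters, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## Data model

The pipeline consumes three plain-text tables. Taxon reports carry one row
per (sample, taxon, rank) with read counts, NT/NR alignment counts and the
mean nucleotide alignment length; resistance-gene (ARG) reports carry one
row per (sample, gene) with reads, alignments, coverage breadth and mean
per-base depth; the metadata table carries one row per sample with
patient, site, sequencing batch (study phase 1, 2, 3A or 3B), day from
admission, the post-host-removal microbial read total, and a
negative-control flag. Coverage breadth is a fraction in [0, 1]
internally and percent only at I/O; that keeps one unit in all code
paths. Abundance transforms are `compute_rpm()` (reads × 10⁶ /
total reads) and `compute_dpm()` (mean depth × 10⁶ / total reads).
Because mean depth is already averaged over gene length, DPM corrects for
both sequencing effort and gene length. The upstream convention this
mirrors subsamples each library to 2 million microbial reads, so the
generator defaults `total_reads` to 2 × 10⁶ with 5% lognormal noise; the
denominator travels as an explicit metadata column rather than being
assumed, since a pipeline that skips subsampling can supply its own.

## Background decontamination

Water controls processed alongside clinical samples define the
contamination null. For feature $f$ in batch $b$, control counts are
modelled as negative binomial with mean $\mu_{bf}$ and a dispersion
$\theta$ shared across **all** features:

* $\hat\mu_{bf}$ is the arithmetic mean over batch $b$'s controls;
* $\hat\theta$ maximises the pooled profile log-likelihood over all
  control counts with the cell means held at those sample means, by
  bracketed 1-D optimisation of $\log\theta$ over $[10^{-3}, 10^{6}]$.
  Landing on a boundary is reported (`theta_boundary`); the upper bound is
  the Poisson limit that zero-excess-variance control counts drive the
  estimate to. Cells with $\hat\mu_{bf} = 0$ put all null mass at zero and
  are excluded from the optimisation. Fixing the means at their sample
  means biases $\hat\theta$ upward by roughly 20% at 6–7 controls per
  batch (the test suite quantifies this); the retention decisions are
  insensitive to bias of that size, and the shared-dispersion contract is
  kept as stated rather than bias-corrected.

A clinical count $x$ is tested against $P(X \ge x)$ for its batch cell.
Benjamini–Hochberg runs **within each sample, across that sample's
observed features**, and features with $q < 0.1$ are retained. The family
choice was genuinely open (the retention decision is per sample profile,
and per-sample families keep samples exchangeable); a single global family
is available via `family = "global"`. A positive count for a feature never
seen in its batch's controls is infinitely surprising under the null
($p = 0$); such pairs are retained and flagged `unseen_in_controls`
instead of entering the BH family, so degenerate zero p-values cannot
distort the adjustment. Counts are compared on the raw post-subsampling
scale, not depth-normalised, matching the equal-depth convention of the
upstream pipeline. Taxa and ARGs are decontaminated in two separate runs.

## Quality filters

After decontamination, per-sample spurious-hit filters apply verbatim
inequality semantics. A taxon record is retained iff NT alignments ≥ 10
AND NR alignments ≥ 1 AND alignment length ≥ 50 bases. An ARG record is
excluded iff coverage breadth < 5% AND (cohort prevalence ≤ 5% OR
(DPM ≤ 1 AND alignments ≤ 10)); adequate breadth alone rescues a record.
Prevalence is the fraction of ARG-bearing samples in which the gene is
detected, computed once over the whole cohort before filtering — a single
pass, no iterative re-filtering. Both filters are per-record deterministic
and monotone in each metric.

## Diversity

Shannon diversity uses natural log (the convention of the standard
community-ecology implementations; `base` switches it), computed on
genus-level RPM for taxa and gene-level DPM for the resistome. Bray–Curtis
dissimilarity is $\sum_i |u_i - v_i| / \sum_i (u_i + v_i)$; matrices are
validated for symmetry (10⁻¹²), zero diagonal and range. PCoA is classical
scaling of $-\tfrac12 D^2$; negative eigenvalues (expected for
Bray–Curtis) are dropped and reported, and coordinates reproduce the input
distances exactly when the input is Euclidean. The permutational location
test is deliberately **one-factor**: pseudo-F from between/within sums of
squared dissimilarities, $p = (1 + \#\{F^\ast \ge F\}) / (1 + n_{perm})$,
seeded; an exhaustive mode enumerates all distinct relabelings at small n.
Covariate-adjusted multi-term permutational models are out of scope and
the result object says so (`terms = "one-way"`).

## Study design

Patients with any azithromycin exposure are Azithro, otherwise any
antibiotic makes them Other-Abx, otherwise No-Abx; incompletely captured
date ranges exclude the patient. "1 ± 1 days of exposure" is read as
cumulative exposure days ∈ {0, 1, 2} at collection and "5 ± 1" as
{4, 5, 6}, with whole-day resolution; a treated sample with zero exposure
by collection is moved to the No-Abx pool and flagged. No-Abx candidates
require ≤ 40 hospitalisation days (early) or 3–40 (late); samples
qualifying for both windows are split by alternation over sorted sample
ids — a deterministic reading of "split evenly", chosen for
reproducibility since no rule is stated — and the No-Abx pool per window
is rarefied to 50% (discarding ⌊n/2⌋ uniformly at random under a required,
logged seed). Whether exposure days are calendar days or 24-h periods from
first dose is unstated; calendar days are used.

## Resistome summaries

"Detectably expressed" means DPM > 0 after the full retention cascade —
no additional threshold, so richness counts follow the filtered dataset.
Richness counts distinct genes (not allele variants). Class proportions
divide per-class DPM by total DPM and are undefined (flagged, never
silently zero) for an empty resistome. The persistence window selects
samples 7–10 days after the last azithromycin day and is an error for
unexposed patients.

## Statistical models

**Group contrasts** use `lmer` (REML) with a site random intercept and
Satterthwaite p-values, covariates as listed in the README. With no
covariates and no random term the fit reduces exactly to OLS, which the
tests exploit as an oracle. Fold change is the ratio of arithmetic group
means on the linear scale; the ratio-of-medians alternative is a switch,
since the convention is not fixed by the analyses this mirrors.

**Longitudinal trends** use `mgcv::gam` with cubic regression spline
smooths (`bs = "cr"`, k = 4) for azithromycin days and each of the six
co-antibiotics, a smooth for days from admission, linear clinical
covariates, and a patient random intercept as an `s(., bs = "re")` term —
the same penalised additive mixed model the gamm4-style wrappers fit,
expressed directly in its underlying engine. Samples are restricted to the
first 10 hospital days and first 5 exposure days before fitting because
longer courses are rare and would leave the spline tail unsupported.
Columns with fewer unique values than the basis get a shrunk basis (or
enter linearly below 3 unique values) with a warning. A constant response
short-circuits to a flat curve with p = 1.

The azithromycin smooth is tested by a likelihood-ratio comparison of
nested fits. Three numerical choices matter and were validated by the
null-calibration simulations in the test suite:

1. both nested models are refit by ML (REML likelihoods are not
   comparable across fixed-effect structures);
2. nuisance smoothing parameters are held at the full-fit values in the
   null refit, so the deviance difference isolates the exposure term —
   re-estimating them adds noise that inflates the test;
3. the scaled deviance difference is referred to $\chi^2$ with df equal
   to the **basis rank** of the exposure smooth (k − 1 = 3), not its
   effective df. Effective-df references are anti-conservative here
   because the penalised fit searches the full basis; the basis rank
   bounds that search. The resulting test is mildly conservative
   (empirical size ≈ 0.03 at nominal 0.05) with essentially full power at
   the effect sizes of interest.

**Rank tests** use midranks throughout. At combined n ≤ 12 the null is
enumerated exhaustively over all group assignments — valid under ties,
where the classical exact distribution is not — with the two-sided p
defined as the null probability of a rank sum at least as far from its
expectation as observed. Larger samples use the normal approximation with
tie and continuity correction, which matches the standard implementation.

**The correlation network** computes all Spearman pairs between the 30
most abundant genera (by summed RPM) and MLS gene DPM, BH-adjusts across
defined pairs, and draws edges where Rho > 0.2 and q < 0.05 — a one-sided
positive rule, so perfect negative correlation never forms an edge.
Constant vectors have undefined rank correlation; such pairs are flagged
and kept out of the BH family.

## The synthetic cohort generator

The generator emits post-pipeline report tables directly (read-level
simulation is a non-goal). Its defaults are the cohort conditions the
pipeline targets: 1,164 patients, 15 sites, 4 batches, 26 water controls,
sampling at admission and days 4/7/14/21/28 with 15% visit dropout,
total reads 2 × 10⁶ ± 5%, group probabilities 366/1164, 324/1164, 474/1164
(Azithro / Other-Abx / No-Abx), azithromycin courses of 1 + NB(1, 2) days
(median 2, IQR 1–4, capped at 35) starting within the first hospital week,
and ceftriaxone (77%) then vancomycin (19%) as the commonest
co-prescriptions.

Structure the analysis assumes, and the generator provides:

* contaminant features drawn NB($\mu_{bf}$, θ = 2) in controls and
  clinical samples alike, with lognormal per-batch mean profiles; controls
  contain nothing else;
* true taxa with per-genus lognormal abundance, a patient offset, and
  AR(1) dependence (ρ = 0.6) across visits — trajectories are plainly
  autocorrelated in real cohorts but no process is specified anywhere, so
  any positive-dependence choice serves, and this one is documented;
* latent MLS gene expression multiplied by `azithro_effect` (default 1.5)
  per cumulative azithromycin exposure day, with detection as threshold
  crossing (DPM > 0.2) so the effect raises richness and expression
  together; non-MLS classes are untouched. The default produces a clear
  qualitative MLS enrichment at cohort sizes of a few hundred patients
  without claiming numeric equivalence to any real cohort;
* a 5% fraction of records corrupted to fail each quality-control rule.

What it does **not** emulate: taxon–gene coupling (taxa and ARGs are drawn
independently, so the correlation network correctly finds no edges on
synthetic data — its logic is tested on constructed fixtures instead),
secular time trends in abundance, realistic phylogenetic composition,
viral dynamics, and batch effects beyond the contamination profile.
Passing tests therefore demonstrate that the statistical machinery is
correct and calibrated under the assumed structure, not that any specific
biological effect size in real data is recovered.

## Problem sizes

The test suite and acceptance script run at deliberately desk-sized
scales, chosen once: decontamination FDR/power at 26 controls, 200
features, 100 samples (50 replicate datasets); permutational-test size at
n = 12 over 400 replicates; mixed-model recovery at n = 200 across 10
sites (25 seeds) and size at n = 100 (400 fits); trend detection at
n = 300, 60 patients (25 seeds) and size over 200 fits; the end-to-end
contrast at 120 patients. The analysis drivers use 300 patients.

## Known limitations

Headline cohort-scale effect estimates from the motivating setting (e.g.
specific fold changes) are functions of the restricted clinical data and
are not reproduced here. The decontamination dispersion is mildly biased
upward as noted; the trend LRT is mildly conservative by construction; the
pairwise rank tests treat repeated samples from one patient as independent
(the adjusted mixed models are the primary inference). The No-Abx
dual-window split order and the FDR family of the original decontamination
are unstated in the source conventions; both choices here are explicit and
switchable, and neither is claimed to be the original.
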