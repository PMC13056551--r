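# azresistome

Empiric azithromycin is one of the most widely prescribed antibiotics for
acute respiratory infection, yet its collateral effects on the upper-airway
microbiome and its reservoir of expressed antimicrobial resistance genes
(the *resistome*) are poorly quantified. `azresistome` implements, as a
tested and reusable R pipeline, the computational analysis needed to relate
longitudinal azithromycin exposure in a hospitalized cohort to changes in
nasal metatranscriptomic profiles: contamination removal against water
controls, spurious-hit filtering, abundance normalisation, diversity
metrics, exposure-group study design, macrolide/lincosamide/streptogramin
(MLS) resistome summaries, and the longitudinal and correlation statistics.
Everything runs end to end on synthetic data with the statistical structure
the analysis assumes, so every stage is testable without any restricted
clinical download.

It is written for microbiome/resistome analysts working with per-sample
taxon report tables (CZ-ID style), CARD-RGI-style resistance-gene reports
and clinical metadata.

## The statistics at the core

**Negative-binomial background correction.** Water controls sequenced in
each batch carry the contamination background. Counts of feature *f* in
batch *b* controls are modelled as NB with mean μ_bf (the control sample
mean per batch:feature cell) and a single dispersion θ shared across all
features, estimated by 1-D profile maximum likelihood. A count *x* in a
clinical sample is kept only if P(X ≥ x | μ_bf, θ) survives
Benjamini–Hochberg at FDR < 0.1; features never seen in that batch's
controls are kept and flagged. Taxa and resistance genes are corrected
separately.

**Quality filters.** Taxa need ≥ 10 nucleotide-database alignments, ≥ 1
protein-database alignment and ≥ 50 b mean alignment length. A gene is
dropped when its coverage breadth is < 5% *and* it is either rare
(detected in ≤ 5% of ARG-bearing samples) or shallow (DPM ≤ 1 and ≤ 10
alignments).

**Abundance.** Taxa: RPM = reads × 10⁶ / total microbial reads. Genes:
DPM = mean per-base depth × 10⁶ / total reads, comparable across genes of
different lengths.

**Design.** Patients are Azithro (azithromycin ± other drugs), Other-Abx,
or No-Abx. Samples enter an early window at 1 ± 1 cumulative exposure days
and a late window at 5 ± 1; No-Abx controls are matched on hospitalisation
day (≤ 40 d early; 3–40 d late), split evenly when they qualify for both,
and rarefied to 50%.

**Models.** Group contrasts use a linear mixed model (metric ~ group +
age quintile + sex + trajectory group + days from admission + steroids +
six co-antibiotic day counts, random intercept per site). Longitudinal
trends use an additive mixed model with cubic-regression-spline smooths
(k = 4) for azithromycin and each co-antibiotic's exposure days, a smooth
for days from admission and a patient random intercept, restricted to the
first 10 hospital days and 5 exposure days; the azithromycin smooth is
tested by a likelihood-ratio comparison of nested maximum-likelihood
refits. Taxa–gene association uses Spearman correlation between the top-30
genera (RPM) and MLS genes (DPM) with edges at Rho > 0.2 and BH q < 0.05.

## Worked example

The `analysis/` scripts run the whole workflow on a 300-patient synthetic
cohort (`Rscript analysis/01_simulate.R` through `07_correlation_network.R`,
tables under `results/`). Running them prints, among other things:

```
cohort of 296 patients:
  Azithro      93 (31.4%)
  Other-Abx    81 (27.4%)
  No-Abx      122 (41.2%)
taxa: theta = 2.36; 73635/118465 (sample, feature) pairs retained
PERMANOVA (one-way, exposure group): pseudo-F = 3.68, p = 0.001
  late mls_richness  groupAzithro  est 3.60  q = 1.06e-57
mls_richness ~ s(azithro days): LRT p = 1.47e-58, day-0 to day-5 change = +3.698
persistence: MLS richness 5.14 (post-cessation) vs 6.35 (late window)
```

Read: the decontamination null recovered a dispersion near the generating
value (θ = 2); microbiome composition separates by exposure group; after
5 ± 1 days of azithromycin the adjusted model attributes ~3.6 extra
detectably expressed MLS genes to the Azithro group; the smooth exposure
model sees the same rise over 0→5 exposure days; and elevated MLS richness
is still visible 7–10 days after the drug stops. With the effect multiplier
set to 1 the same pipeline reports a flat trend (see the end-to-end test).

A minimal in-R session:

```r
library(azresistome)
out <- run_pipeline(sim_config(n_patients = 120), seed = 1)
out$trend$lrt_p          # likelihood-ratio p for the azithromycin smooth
out$group_results$late   # adjusted late-window group contrasts
```

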