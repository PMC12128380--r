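---
title: "Methods: simulating and analysing MSRE-qPCR methylation biomarkers"
author: "msremeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing MSRE-qPCR methylation biomarkers}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msremeth)
```

## The assay model

A methylation-sensitive restriction enzyme (MSRE) such as HaeIII (recognition
site `GGCC`) cleaves its site only when the internal CpG is unmethylated.
After digestion, only methylated template survives, so a PCR on the digested
aliquot amplifies later than the paired undigested control. Two readouts are
modelled:

* **qPCR.** With cycle thresholds `Ct` for the digested and undigested
  reactions, `dCt = Ct(digested) - Ct(undigested)`. Assuming ~100%
  amplification efficiency, each cycle of delay corresponds to a halving of
  surviving template, so the methylated fraction is recovered as

  `% methylation = 100 * exp(-0.7 * dCt)`

  The coefficient 0.7 is an assay constant (numerically close to `ln 2`,
  making the formula the familiar `2^-dCt` rule expressed in base e). It is
  treated as fixed, not fitted: the package validates it through the standard
  curve rather than re-estimating it.

* **Gel densitometry (MSRE-PCR).** The digested/undigested band-intensity
  ratio (`D/C`) rises with the methylated fraction `m`. The generator uses an
  affine response `E[D/C] = gel_beta + gel_alpha * m`; quantification inverts
  it. The default coefficients (`gel_alpha = 0.82`, `gel_beta = 0.14`) are the
  two-point solution through the two group-level operating points the
  simulated study design targets (mean `D/C` of 0.21 at 8% methylation and
  0.83 at 84.5%).

Hypomethylation, the primary reported quantity for a biomarker that *loses*
methylation in disease, is always the complement `100 - methylation%`.

## What the synthetic cohort emulates

The default configuration represents a large blood-based case-control study:
180 prostate-cancer (PCa) and 180 benign-hyperplasia (BPH) subjects, with a
diagnostic rule that calls a sample cancer-like when its methylation falls
strictly below 55%.

**Group mode.** True methylation per group is a two-component mixture:

* a *core* truncated normal on the correct side of the cutoff (PCa on
  \[0, 50\]%, BPH on \[60, 100\]%). The configuration stores the target
  *group-level* mean (8% for PCa, 84.5% for BPH, i.e. 92% and 15.5% mean
  hypomethylation); the generator solves the underlying normal location by
  root-finding on the closed-form truncated-normal mean so that the realized
  mixture mean matches the target exactly in expectation;
* a *contamination* component of exactly `round(3/180 * n)` subjects per
  group, placed just across the cutoff (PCa contaminants centred at 60%
  methylation, BPH at 48%, sd 5%, truncated to the wrong side of 55%).

This geometry is the only simple one that reproduces 177/180 sensitivity
*and* specificity at the fixed cutoff while keeping the AUC near 1: a single
normal per group either overlaps too much (AUC drops) or too little (no
misclassifications). Because the contaminants sit near the threshold, the
expected trapezoidal AUC of the mixture is ~0.999.

**Stratified mode** serves the association analyses. The 180 PCa subjects are
assigned to five tumor-stage strata (I–V: 7/15/33/70/55 subjects with mean
hypomethylation 10/35/64.5/96/100%) and five ISUP grade strata
(1–5: 15/20/46/20/79 subjects at 5.66/30/55.2/74/100%). Stage and grade are
paired rank-concordantly (higher stages carry higher grades, as they do
clinically), and each subject's true hypomethylation is drawn around a blend
of its two stratum means, `stage_weight * stage_mean + (1 - stage_weight) *
grade_mean`, truncated to \[0, 100\].

Two modes exist because the two published surfaces they reproduce are
mutually inconsistent: a 92% group mean hypomethylation cannot coexist with
stage-stratum means whose count-weighted average is ≈83%. Rather than
silently averaging, each analysis names the mode it uses. A related wrinkle:
the stratum table lists five stage levels (I–V) while stage figures elsewhere
use four (TS1–TS4); the generator follows the five-level table.

**Covariates.** Total PSA is lognormal per group, parameterized by the
published median and sd (PCa: median 12, sd 21.33 ng/mL; BPH: 4.4, 5.4) —
the median far below the mean indicates strong right skew, which a normal
cannot represent. PSA is coupled to the within-group methylation *ranks*
through a Gaussian copula (`psa_meth_rank_corr`, default 0): even with zero
within-group coupling the pooled PSA–methylation Spearman correlation is
negative, because cases have higher PSA and lower methylation.
`calibrate_generator()` can grid-search the copula parameter to hit a pooled
target (e.g. ρ = −0.364) within a stated tolerance, reporting failure if the
target is unreachable. Age (truncated normal on \[40, 100\] years) and
prostate weight (\[1, 200\] g) match the published group moments and are
deliberately uncoupled from methylation, since no association is reported
for them.

## Tunable parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `ct_baseline` | 25 | cycles | typical Ct for abundant undigested input |
| `ct_cap` | 40 | cycles | standard qPCR cycle limit; `m = 0` sits here |
| `ct_noise_sd` | 0.15 | cycles | typical replicate scatter of a well-run assay; with duplicates this keeps the median standard-curve R² ≈ 0.986 |
| `gel_alpha`, `gel_beta` | 0.82, 0.14 | — | two-point affine solve through the group operating points |
| `gel_noise_sd` | 0.105 | ratio | calibrated so qPCR-vs-gel concordance R² ≈ 0.91 on the default cohort |
| `within_stratum_sd` | 1.0 | % | calibrated so the measured stage/grade regressions reach r ≈ 0.95/0.94 (see below) |
| `stage_weight` | 0.65 | — | blend of stage vs grade stratum means; balances the two regression targets |
| `contamination_fraction` | 3/180 | — | yields 177/180 sensitivity and specificity |

Two calibration notes, recorded here because the choices were genuinely open:

* The within-stratum sd was calibrated against the *measured* (quantified)
  hypomethylation, not the latent values: for high-methylation strata the
  multiplicative qPCR noise dominates the stratum spread, so the achievable
  stage regression r saturates near 0.951 — slightly below the 0.9574 a
  latent-value calibration would suggest — while the grade regression lands
  on its 0.9348 target. No single `(sd, weight)` pair can hit both exactly;
  the default is the joint compromise.
* The published per-sample regression correlations (r > 0.93 over 180
  subjects) imply a very tight within-stratum spread; 1 percentage point of
  latent sd plus assay noise is what reproduces them. Real cohorts almost
  certainly vary more — see the limitations below.

## Numerical choices and degenerate inputs

* Replicates are averaged in Ct space (the linear scale of the model) before
  `dCt`; mean and median coincide for duplicates.
* `m = 0` yields no amplification: digested Ct is pinned to `ct_cap` and the
  call is flagged `below_detection`. If *all undigested* replicates are
  capped the sample had no input DNA and quantification errors out.
* Negative `dCt` (possible from noise at full methylation) clamps to 100%
  with a warning rather than erroring.
* The 0% standard has no logarithm; it is excluded from the log-linear
  standard-curve fit and reported separately as a digestion control. On
  noiseless standards the fitted slope is exactly `-ln(10)/0.7 = -3.289`
  cycles per decade.
* The ROC uses thresholds at midpoints between adjacent distinct scores plus
  infinite sentinels; trapezoidal AUC equals pair-counting concordance with
  ties credited ½, and classification is strictly `< cutoff` (boundary
  samples are negative).
* Dunn's post hoc uses Bonferroni adjustment by default (the labelled
  default of the legacy software this workflow mirrors), with a flag to
  disable. All tests are two-sided at α = 0.05. Stage and grade are treated
  as ordinal integers (I→1 … V→5) for regression and correlation.
* Truncated-normal draws use inverse-CDF sampling; the core-location root
  solve is bracketed at ±6 sd (beyond which the truncated mean is
  numerically pinned to the bound) and reports infeasible targets instead of
  iterating.
* One run seed is expanded into fixed per-stage substreams, so adding a
  stage never perturbs earlier stages' draws and every table is reproducible
  bit for bit.

## Problem sizes

The test suite averages the cohort-level checks over 30 seeds of the full
180 + 180 design, uses 200 seeds for the standard-curve fit distribution,
10,000 null replicates for the type-I-error calibration of the rank tests,
and exhaustive enumeration for the small-sample oracles (all label
assignments at n = 5 + 5; all 5,040 permutations at n = 7). The acceptance
script averages over 100 cohort seeds and 1,000 standard-curve seeds. These
sizes make every Monte Carlo band small relative to the tolerance it guards.

## What passing tests do and do not show

The generator reproduces the *reported summary statistics* of a real study:
group means and spreads, stratum means, diagnostic operating points, method
concordance, and the skew and coupling of PSA. It does not emulate raw
fluorescence or melt curves, gel images, bisulfite or array data, batch
effects, incomplete digestion, DNA-quality gradients, or any linkage between
contamination status and clinical covariates (contaminants inherit labels
only through their stratum). Passing the recovery tests therefore shows the
analysis pipeline is correct and well calibrated under the stated
generative model — not that the biomarker itself would perform identically
in new clinical material.

## Known limitations

* The exponential coefficient 0.7 is fixed; assays with different
  efficiencies would need their own constant, and the package intentionally
  provides no way to fit it from cohort data.
* The affine gel response is a convenience surface through two operating
  points; real densitometry saturates at both ends.
* Group-mode and stratified-mode cohorts are internally consistent but not
  with each other (by design, see above), so cross-mode comparisons of
  absolute hypomethylation levels are not meaningful.
* The Kruskal–Wallis p-value uses the chi-square reference; at very small
  group sizes (n ≤ 3 per group) it deviates from the exact permutation
  distribution by up to ~0.1 in p.
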