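# msremeth

Simulation and analysis of MSRE-qPCR DNA methylation biomarker studies.

## The problem

Blood-based DNA methylation biomarkers are commonly assayed with a
methylation-sensitive restriction enzyme (MSRE, e.g. HaeIII at `GGCC`): the
enzyme cuts its site only when the internal CpG is unmethylated, so
methylated template survives digestion and amplifies earlier in a subsequent
PCR. A case-control study of such a marker needs, end to end:
quantification of methylation from paired digested/undigested reactions,
validation against calibration standards, a threshold classification rule
with ROC/AUC diagnostics, and nonparametric association statistics against
clinical covariates (stage, grade, PSA).

`msremeth` implements that whole pipeline for analysts working with this
assay class, together with a synthetic-cohort generator that reproduces the
statistical structure of a large (180 case / 180 control) prostate-cancer
vs. benign-hyperplasia blood study — so every stage is testable without any
clinical data.

## The model

For a sample with methylated fraction *m*, the digested reaction is delayed
by the loss of cleaved template. With ΔCt = Ct(digested) − Ct(undigested)
and ~100% amplification efficiency,

```
% methylation = 100 · e^(−0.7·ΔCt)        (0.7 ≈ ln 2, i.e. the 2^−ΔCt rule)
% hypomethylation = 100 − % methylation
```

A sample is called cancer-like when its methylation is strictly below a 55%
cutoff. The generator draws per-group true methylation from a calibrated
truncated-normal mixture (with a small near-cutoff contamination component
that produces realistic misclassifications), gel band-intensity ratios from
an affine densitometry response, and PSA/age/prostate-weight covariates with
a Gaussian copula coupling PSA to methylation rank. The methods vignette
(`vignettes/msre-qpcr-methods.Rmd`) documents every model assumption,
default and calibration.

## Worked example

```r
library(msremeth)

cfg <- generator_config(seed = 5)          # 180 PCa + 180 BPH, group mode
report <- run_pipeline(cfg, out_dir = "msremeth-out", quiet = TRUE)
print(report)
```

```
MSRE-qPCR pipeline report (seed 5)
  hypomethylation mean: PCa 92.6679%, BPH 16.3740%
  D/C ratio mean: PCa 0.2041, BPH 0.8314
  AUC 0.9979 (SE 0.0024, CI 0.9931-1.0000); sens 0.9889, spec 0.9778 at <55%
  method concordance R^2 0.9049; standard curve R^2 0.9834
```

Reading the output: the cancer group has lost most of its methylation at the
marker CpG (≈93% hypomethylation vs ≈16% in controls); the gel readout
agrees (digested bands retain ~20% vs ~83% of control intensity); the <55%
rule separates the groups almost perfectly (AUC ≈ 0.998, a handful of
near-threshold errors), the two assays agree (R² ≈ 0.90), and the
calibration standards confirm the log-linear ΔCt response (R² ≈ 0.98).

All stage tables (cohort, Ct values, gel intensities, standards, calls, ROC
sweep, associations, summary) are written to `out_dir` as delimited text,
with a JSON manifest recording the config, seed, timings and file digests.
A thin command-line front end with the same stages ships in
`exec/msremeth`:

```sh
Rscript exec/msremeth run --config inst/extdata/default-config.yaml --seed 5 --out out/
Rscript exec/msremeth validate --table out/cohort.csv --schema cohort
```

Individual pieces are exported too, e.g.:

```r
methylation_from_delta_ct(1)        # 49.66
fit_standard_curve(simulate_standards(cfg))   # slope ~ -ln(10)/0.7
find_recognition_sites("AGGCCTGGCC", "GGCC")  # HaeIII sites at 1, 6 (0-based)
```

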