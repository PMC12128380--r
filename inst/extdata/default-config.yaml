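# Default synthetic-cohort configuration for the MSRE-qPCR methylation
# biomarker pipeline. Every key can be overridden; the seed is mandatory
# for pipeline runs. Percentages are on the 0-100 scale, Ct values are
# PCR cycles.

# cohort size and simulation mode ("group" or "stratified")
n_pca: 180
n_bph: 180
mode: group

# target group-level mean of true methylation (%) and the underlying
# core-component sd before truncation; the generator places the core
# component so the realized group mean (contamination included) matches
pca_meth: [8.0, 11.76]
bph_meth: [84.5, 15.12]

# near-cutoff contamination component: fraction per group (3 of 180),
# centers on the wrong side of the 55% cutoff, and its sd
contamination_fraction: 0.0166666666666667
contamination_center: [60.0, 48.0]
contamination_sd: 5.0

# stratified mode: tumor-stage and ISUP-grade strata (counts sum to n_pca)
# with per-stratum mean hypomethylation (%)
stage_table:
- {label: I, 'n': 7, hypometh_mean: 10.0}
- {label: II, 'n': 15, hypometh_mean: 35.0}
- {label: III, 'n': 33, hypometh_mean: 64.5}
- {label: IV, 'n': 70, hypometh_mean: 96.0}
- {label: V, 'n': 55, hypometh_mean: 100.0}
grade_table:
- {label: '1', 'n': 15, hypometh_mean: 5.66}
- {label: '2', 'n': 20, hypometh_mean: 30.0}
- {label: '3', 'n': 46, hypometh_mean: 55.2}
- {label: '4', 'n': 20, hypometh_mean: 74.0}
- {label: '5', 'n': 79, hypometh_mean: 100.0}

# within-stratum sd of true hypomethylation (%) and the weight of the
# stage stratum mean in the blended stage/grade stratum center
within_stratum_sd: 1.0
stage_weight: 0.65

# clinical covariates: PSA lognormal (median ng/mL, sd ng/mL) per group;
# age (mean yr, sd yr) truncated to [40, 100]; prostate weight (mean g,
# sd g) truncated to [1, 200]
psa_params:
  pca: [12.0, 21.33]
  bph: [4.4, 5.4]
age_params:
  pca: [69.5, 17.67]
  bph: [68.65, 15.6]
weight_params:
  pca: [36.83, 38.36]
  bph: [56.26, 27.74]

# within-group Gaussian-copula correlation of PSA with methylation rank
# (0 = independent given group; the pooled correlation is already negative
# because the groups separate on both variables)
psa_meth_rank_corr: 0.0

# qPCR forward model: per-replicate Ct noise sd, undigested baseline Ct,
# and the no-amplification cap
ct_noise_sd: 0.15
ct_baseline: 25.0
ct_cap: 40.0

# gel densitometry: expected D/C ratio = gel_beta + gel_alpha * m, plus
# noise on the ratio scale (calibrated to the observed method concordance)
gel_alpha: 0.82
gel_beta: 0.14
gel_noise_sd: 0.105

seed: 1
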