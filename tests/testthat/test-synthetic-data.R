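test_that("config validation rejects impossible settings", {
  expect_error(generator_config(n_pca = 0), "positive")
  expect_error(generator_config(contamination_fraction = 1.5), "\\[0, 1\\]")
  expect_error(generator_config(ct_baseline = 45, ct_cap = 40), "below ct_cap")
  expect_error(generator_config(ct_noise_sd = -1), "non-negative")
  bad_stage <- default_stage_table()
  bad_stage$n[1] <- 8L
  expect_error(generator_config(mode = "stratified", stage_table = bad_stage),
               "sum to n_pca")
})

test_that("identical config and seed give bit-identical simulations", {
  cfg <- generator_config(seed = 7)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  co <- simulate_cohort(cfg)
  expect_identical(simulate_qpcr(co, cfg), simulate_qpcr(co, cfg))
  expect_identical(simulate_gel(co, cfg), simulate_gel(co, cfg))
  expect_identical(simulate_standards(cfg), simulate_standards(cfg))
  cfg2 <- generator_config(seed = 8)
  expect_false(identical(simulate_cohort(cfg2), co))
})

test_that("core components stay on the correct side of the cutoff without contamination", {
  cfg <- generator_config(n_pca = 5000, n_bph = 5000,
                          contamination_fraction = 0, seed = 3)
  co <- simulate_cohort(cfg)
  expect_true(all(co$true_meth[co$group == "PCa"] < 0.55))
  expect_true(all(co$true_meth[co$group == "BPH"] > 0.55))
  expect_false(any(co$is_contaminant))
})

test_that("contaminant count is exactly round(fraction * n) per group", {
  for (frac in c(0, 3 / 180, 0.05)) {
    cfg <- generator_config(contamination_fraction = frac, seed = 11)
    co <- simulate_cohort(cfg)
    for (g in c("PCa", "BPH"))
      expect_equal(sum(co$is_contaminant[co$group == g]), round(frac * 180))
  }
})

test_that("contaminants sit just across the 55% cutoff", {
  cfg <- generator_config(seed = 5)
  co <- simulate_cohort(cfg)
  expect_true(all(co$true_meth[co$is_contaminant & co$group == "PCa"] >= 0.55))
  expect_true(all(co$true_meth[co$is_contaminant & co$group == "BPH"] < 0.55))
})

test_that("stratified mode reproduces the stage and grade stratum counts", {
  cfg <- generator_config(mode = "stratified", seed = 2)
  co <- simulate_cohort(cfg)
  pca <- co[co$group == "PCa", ]
  expect_equal(as.vector(table(factor(pca$stage,
                                      c("I", "II", "III", "IV", "V")))),
               c(7L, 15L, 33L, 70L, 55L))
  expect_equal(as.vector(table(factor(pca$grade, as.character(1:5)))),
               c(15L, 20L, 46L, 20L, 79L))
  # stage/grade absent outside the stratified PCa arm
  expect_true(all(is.na(co$stage[co$group == "BPH"])))
  co_g <- simulate_cohort(generator_config(seed = 2))
  expect_true(all(is.na(co_g$stage)))
})

test_that("group-level methylation means match the configured targets at scale", {
  cfg <- generator_config(n_pca = 50000, n_bph = 50000, seed = 13)
  co <- simulate_cohort(cfg)
  meth <- 100 * co$true_meth
  expect_equal(mean(meth[co$group == "PCa"]), cfg$pca_meth[1],
               tolerance = 0.02)
  expect_equal(mean(meth[co$group == "BPH"]), cfg$bph_meth[1],
               tolerance = 0.02)
})

test_that("covariate moments match truncation-adjusted configured values at scale", {
  cfg <- generator_config(n_pca = 50000, n_bph = 50000, seed = 17)
  co <- simulate_cohort(cfg)
  for (g in c("PCa", "BPH")) {
    key <- if (g == "PCa") "pca" else "bph"
    sub <- co[co$group == g, ]
    # age: truncated normal on [40, 100]
    ap <- cfg$age_params[[key]]
    expect_equal(mean(sub$age),
                 msremeth:::truncnorm_mean(ap[1], ap[2], 40, 100),
                 tolerance = 0.02)
    expect_equal(sd(sub$age),
                 msremeth:::truncnorm_sd(ap[1], ap[2], 40, 100),
                 tolerance = 0.02)
    # PSA: lognormal with configured median
    pp <- cfg$psa_params[[key]]
    expect_equal(median(sub$tpsa), pp[1], tolerance = 0.03)
    expect_equal(sd(sub$tpsa), pp[2], tolerance = 0.05)
  }
})

test_that("qPCR forward model matches the closed-form delta-Ct when noiseless", {
  cfg <- generator_config(ct_noise_sd = 0, seed = 1)
  cohort <- data.frame(id = c("m1", "m05", "m0"), group = "PCa",
                       true_meth = c(1, 0.5, 0), stage = NA, grade = NA,
                       tpsa = 1, age = 60, prostate_weight = 30,
                       is_contaminant = FALSE, stringsAsFactors = FALSE)
  qp <- simulate_qpcr(cohort, cfg)
  calls <- quantify_qpcr(qp)
  expect_equal(calls$delta_ct[calls$sample_id == "m1"], 0)
  expect_equal(calls$delta_ct[calls$sample_id == "m05"], -log(0.5) / 0.7,
               tolerance = 1e-12)
  # fully unmethylated template never amplifies: digested Ct at the cap
  expect_true(all(qp$ct_digested[qp$sample_id == "m0"] == cfg$ct_cap))
  expect_true(all(calls$below_detection[calls$sample_id == "m0"]))
})

test_that("noiseless forward/inverse round trip recovers 100*m exactly", {
  cfg <- generator_config(ct_noise_sd = 0, seed = 9)
  m <- seq(0.05, 1, by = 0.05)
  cohort <- data.frame(id = sprintf("s%02d", seq_along(m)), group = "PCa",
                       true_meth = m, stage = NA, grade = NA, tpsa = 1,
                       age = 60, prostate_weight = 30, is_contaminant = FALSE,
                       stringsAsFactors = FALSE)
  calls <- quantify_qpcr(simulate_qpcr(cohort, cfg))
  expect_equal(calls$methylation_pct[match(cohort$id, calls$sample_id)],
               100 * m, tolerance = 1e-9)
})

test_that("noiseless gel response follows the affine model with clipping", {
  cfg <- generator_config(gel_noise_sd = 0, seed = 1)
  cohort <- data.frame(id = c("a", "b"), group = "PCa",
                       true_meth = c(0.08, 0.845), stage = NA, grade = NA,
                       tpsa = 1, age = 60, prostate_weight = 30,
                       is_contaminant = FALSE, stringsAsFactors = FALSE)
  gel <- simulate_gel(cohort, cfg)
  dc <- dc_ratio(gel$intensity_digested, gel$intensity_undigested)
  expect_equal(dc, c(0.2056, 0.8329), tolerance = 1e-9)
  expect_true(all(gel$intensity_undigested > 0))

  cfg0 <- generator_config(gel_noise_sd = 0, gel_alpha = 1, gel_beta = 0,
                           seed = 1)
  cohort$true_meth <- c(0, 1)
  gel0 <- simulate_gel(cohort, cfg0)
  expect_equal(dc_ratio(gel0$intensity_digested, gel0$intensity_undigested),
               c(0, 1), tolerance = 1e-12)
})

test_that("standards carry paired Cts at each level with the closed-form delta-Ct", {
  cfg <- generator_config(ct_noise_sd = 0, seed = 1)
  std <- simulate_standards(cfg, replicates = 2)
  expect_equal(nrow(std), 10L)
  expect_setequal(unique(std$nominal_meth), c(0, 25, 50, 75, 100))
  d100 <- compute_delta_ct(std$ct_digested[std$nominal_meth == 100],
                           std$ct_undigested[std$nominal_meth == 100])
  expect_equal(d100$delta_ct, 0)
  d25 <- compute_delta_ct(std$ct_digested[std$nominal_meth == 25],
                          std$ct_undigested[std$nominal_meth == 25])
  expect_equal(d25$delta_ct, -log(0.25) / 0.7, tolerance = 1e-12)
  expect_error(simulate_standards(cfg, levels = c(-5, 50)), "\\[0, 100\\]")
})

test_that("PSA-methylation copula coupling moves the pooled rank correlation", {
  cfg0 <- generator_config(n_pca = 2000, n_bph = 2000, seed = 23,
                           psa_meth_rank_corr = 0)
  cfg_neg <- generator_config(n_pca = 2000, n_bph = 2000, seed = 23,
                              psa_meth_rank_corr = -0.8)
  rho0 <- with(simulate_cohort(cfg0), cor(tpsa, true_meth,
                                          method = "spearman"))
  rho_neg <- with(simulate_cohort(cfg_neg), cor(tpsa, true_meth,
                                                method = "spearman"))
  expect_lt(rho_neg, rho0)   # stronger negative coupling
  expect_lt(rho0, 0)         # group separation alone is already negative
})
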