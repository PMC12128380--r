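#' Simulate a two-group methylation biomarker cohort
#'
#' Draws `n_pca + n_bph` subjects with a latent true methylated fraction
#' (`true_meth`, in \[0, 1\]) and clinical covariates (total PSA, age,
#' prostate weight), reproducibly from `config$seed`.
#'
#' In \emph{group} mode each group's true methylation comes from a
#' two-component mixture: a core truncated normal on the correct side of the
#' 55\% cutoff (PCa core on \[0, 50\]\%, BPH core on \[60, 100\]\%) whose
#' location is solved so that the realized group mean (contamination
#' included) equals the configured target, plus a narrow contamination
#' component just across the cutoff. The number of contaminants per group is
#' exactly `round(contamination_fraction * n)`.
#'
#' In \emph{stratified} mode PCa subjects are assigned to tumor-stage and
#' ISUP-grade strata with the configured counts (stage and grade are paired
#' rank-concordantly, so higher stages carry higher grades), and
#' hypomethylation is drawn around a blend of the two stratum means
#' (`stage_weight` controls the blend) with sd `within_stratum_sd`,
#' truncated to \[0, 100\].
#'
#' PSA is drawn from per-group lognormal marginals (parameterized by the
#' configured median and sd) coupled to the within-group methylation ranks
#' through a Gaussian copula with correlation `psa_meth_rank_corr`. Age and
#' prostate weight are truncated normals, uncoupled from methylation.
#'
#' @param config An [generator_config()] object.
#' @return A data frame (one row per subject) with columns `id`, `group`
#'   (`"PCa"`/`"BPH"`), `true_meth` (fraction), `stage`, `grade` (present
#'   only for PCa in stratified mode, else `NA`), `tpsa` (ng/mL), `age`
#'   (years), `prostate_weight` (g), `is_contaminant` (logical).
#' @export
#' @examples
#' cohort <- simulate_cohort(generator_config(seed = 42))
#' tapply(100 * cohort$true_meth, cohort$group, mean)
simulate_cohort <- function(config) {
  validate_config(config)
  with_seed_(stage_seed_(config$seed, "cohort"), {
    pca <- draw_group_(config, "PCa")
    bph <- draw_group_(config, "BPH")
    cohort <- rbind(pca, bph)
    cohort$id <- sprintf("S%04d", seq_len(nrow(cohort)))
    cohort[, c("id", "group", "true_meth", "stage", "grade", "tpsa", "age",
               "prostate_weight", "is_contaminant")]
  })
}

# solve the underlying core-normal location so that the realized mixture
# group mean equals `target` given the contamination component
core_location_ <- function(target, sd, lo, hi, f, c_mean, c_sd, c_lo, c_hi) {
  m_cont <- if (f > 0) truncnorm_mean(c_mean, c_sd, c_lo, c_hi) else 0
  core_target <- (target - f * m_cont) / (1 - f)
  if (core_target <= lo || core_target >= hi)
    stop("core methylation target ", signif(core_target, 4),
         "% falls outside the truncation bounds [", lo, ", ", hi, "]",
         call. = FALSE)
  # beyond ~6 sd the truncated mean is numerically pinned to the bound
  f <- function(mu) truncnorm_mean(mu, sd, lo, hi) - core_target
  lower <- lo - 6 * sd
  upper <- hi + 6 * sd
  if (f(lower) * f(upper) > 0)
    stop("core methylation target ", signif(core_target, 4),
         "% is not reachable by a truncated normal on [", lo, ", ", hi,
         "] with sd ", sd, call. = FALSE)
  uniroot(f, lower = lower, upper = upper, tol = 1e-10)$root
}

draw_group_ <- function(config, group) {
  n <- if (group == "PCa") config$n_pca else config$n_bph
  stage <- grade <- rep(NA_character_, n)
  is_cont <- rep(FALSE, n)

  if (config$mode == "stratified" && group == "PCa") {
    st <- rep(seq_len(nrow(config$stage_table)), config$stage_table$n)
    gr <- rep(seq_len(nrow(config$grade_table)), config$grade_table$n)
    centre <- config$stage_weight * config$stage_table$hypometh_mean[st] +
      (1 - config$stage_weight) * config$grade_table$hypometh_mean[gr]
    hypo <- rtruncnorm_(n, centre, config$within_stratum_sd, 0, 100)
    meth_pct <- 100 - hypo
    stage <- config$stage_table$label[st]
    grade <- config$grade_table$label[gr]
    ord <- sample.int(n)
    meth_pct <- meth_pct[ord]; stage <- stage[ord]; grade <- grade[ord]
  } else {
    if (group == "PCa") {
      target <- config$pca_meth[1]; sd <- config$pca_meth[2]
      lo <- 0; hi <- 50
      c_mean <- config$contamination_center[1]; c_lo <- 55; c_hi <- 100
    } else {
      target <- config$bph_meth[1]; sd <- config$bph_meth[2]
      lo <- 60; hi <- 100
      c_mean <- config$contamination_center[2]; c_lo <- 0; c_hi <- 55
    }
    n_cont <- round(config$contamination_fraction * n)
    f <- n_cont / n
    mu <- core_location_(target, sd, lo, hi, f, c_mean,
                         config$contamination_sd, c_lo, c_hi)
    core <- rtruncnorm_(n - n_cont, mu, sd, lo, hi)
    cont <- rtruncnorm_(n_cont, c_mean, config$contamination_sd, c_lo, c_hi)
    meth_pct <- c(core, cont)
    is_cont <- c(rep(FALSE, n - n_cont), rep(TRUE, n_cont))
    ord <- sample.int(n)
    meth_pct <- meth_pct[ord]; is_cont <- is_cont[ord]
  }

  key <- tolower(group) %in% "pca"
  pk <- if (key) "pca" else "bph"
  psa <- copula_lognormal_(meth_pct, config$psa_params[[pk]],
                           config$psa_meth_rank_corr)
  age <- rtruncnorm_(n, config$age_params[[pk]][1], config$age_params[[pk]][2],
                     40, 100)
  wt <- rtruncnorm_(n, config$weight_params[[pk]][1],
                    config$weight_params[[pk]][2], 1, 200)

  data.frame(id = NA_character_, group = group, true_meth = meth_pct / 100,
             stage = stage, grade = grade, tpsa = psa, age = age,
             prostate_weight = wt, is_contaminant = is_cont,
             stringsAsFactors = FALSE)
}

# lognormal marginal (parameterized by median and sd) coupled to the ranks of
# `meth` via a Gaussian copula with correlation rho
copula_lognormal_ <- function(meth, params, rho) {
  n <- length(meth)
  med <- params[1]; s <- params[2]
  mu <- log(med)
  # sd/median = sqrt(t^2 - t) with t = exp(sigma^2)
  ratio2 <- (s / med)^2
  t <- (1 + sqrt(1 + 4 * ratio2)) / 2
  sigma <- sqrt(log(t))
  z_m <- qnorm((rank(meth, ties.method = "average") - 0.5) / n)
  z_p <- rho * z_m + sqrt(1 - rho^2) * rnorm(n)
  qlnorm(pnorm(z_p), meanlog = mu, sdlog = sigma)
}

#' Simulate paired digested/undigested qPCR Ct values
#'
#' Forward model for the MSRE-qPCR readout. For a subject with methylated
#' fraction `m`, each undigested (control) replicate is
#' `ct_baseline + N(0, ct_noise_sd)` and each digested replicate is
#' `ct_baseline - ln(m)/0.7 + N(0, ct_noise_sd)`, capped at `ct_cap`. Fully
#' unmethylated template (`m = 0`) never amplifies: its digested Ct sits at
#' the cap. The expected delta-Ct is `-ln(m)/0.7`, the inverse of the
#' exponential quantification formula.
#'
#' @param cohort A cohort data frame from [simulate_cohort()].
#' @param config The same [generator_config()].
#' @param replicates Technical replicates per arm (default 2, i.e. duplicate
#'   wells).
#' @return A long-format data frame with columns `sample_id`, `replicate`,
#'   `ct_digested`, `ct_undigested`, `capped_digested`, `capped_undigested`.
#' @export
simulate_qpcr <- function(cohort, config, replicates = 2L) {
  validate_config(config)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  with_seed_(stage_seed_(config$seed, "qpcr"), {
    n <- nrow(cohort)
    m <- rep(cohort$true_meth, each = replicates)
    id <- rep(cohort$id, each = replicates)
    repl <- rep(seq_len(replicates), times = n)
    und_raw <- config$ct_baseline + rnorm(n * replicates, 0, config$ct_noise_sd)
    dig_raw <- config$ct_baseline - log(m) / 0.7 +
      rnorm(n * replicates, 0, config$ct_noise_sd)
    dig_raw[m == 0] <- Inf  # no template survives digestion
    data.frame(sample_id = id, replicate = repl,
               ct_digested = pmin(dig_raw, config$ct_cap),
               ct_undigested = pmin(und_raw, config$ct_cap),
               capped_digested = dig_raw >= config$ct_cap,
               capped_undigested = und_raw >= config$ct_cap,
               stringsAsFactors = FALSE)
  })
}

#' Simulate gel densitometry band intensities
#'
#' Models the MSRE-PCR gel readout: the expected digested/undigested (D/C)
#' band-intensity ratio responds affinely to the methylated fraction `m` as
#' `gel_beta + gel_alpha * m`, plus densitometry noise, clipped to
#' \[0, 1.2\]. The undigested (control) intensity is drawn from a positive
#' reference distribution (lognormal, arbitrary units) and the digested
#' intensity is `ratio * undigested`.
#'
#' @inheritParams simulate_qpcr
#' @return A data frame with columns `sample_id`, `intensity_digested`,
#'   `intensity_undigested`.
#' @export
simulate_gel <- function(cohort, config) {
  validate_config(config)
  with_seed_(stage_seed_(config$seed, "gel"), {
    n <- nrow(cohort)
    ratio <- config$gel_beta + config$gel_alpha * cohort$true_meth +
      rnorm(n, 0, config$gel_noise_sd)
    ratio <- pmin(pmax(ratio, 0), 1.2)
    undig <- qlnorm(runif(n), meanlog = log(1000), sdlog = 0.25)
    data.frame(sample_id = cohort$id,
               intensity_digested = ratio * undig,
               intensity_undigested = undig,
               stringsAsFactors = FALSE)
  })
}

#' Simulate calibration standards of defined methylation level
#'
#' Generates Ct pairs for control-DNA mixtures of known methylated fraction
#' (default levels 0/25/50/75/100\%) using the same forward model as
#' [simulate_qpcr()] with `m = level / 100`.
#'
#' @param config An [generator_config()].
#' @param levels Nominal methylation percentages in \[0, 100\].
#' @param replicates Ct replicates per standard (default 2).
#' @return A long-format data frame with columns `nominal_meth`,
#'   `replicate`, `ct_digested`, `ct_undigested`, `capped_digested`,
#'   `capped_undigested`.
#' @export
simulate_standards <- function(config, levels = c(0, 25, 50, 75, 100),
                               replicates = 2L) {
  validate_config(config)
  if (any(levels < 0 | levels > 100))
    stop("standard levels must lie in [0, 100]", call. = FALSE)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  with_seed_(stage_seed_(config$seed, "standards"), {
    k <- length(levels)
    m <- rep(levels / 100, each = replicates)
    und_raw <- config$ct_baseline + rnorm(k * replicates, 0, config$ct_noise_sd)
    dig_raw <- config$ct_baseline - log(m) / 0.7 +
      rnorm(k * replicates, 0, config$ct_noise_sd)
    dig_raw[m == 0] <- Inf
    data.frame(nominal_meth = rep(levels, each = replicates),
               replicate = rep(seq_len(replicates), times = k),
               ct_digested = pmin(dig_raw, config$ct_cap),
               ct_undigested = pmin(und_raw, config$ct_cap),
               capped_digested = dig_raw >= config$ct_cap,
               capped_undigested = und_raw >= config$ct_cap,
               stringsAsFactors = FALSE)
  })
}
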