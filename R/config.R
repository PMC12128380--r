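#' Generator configuration for synthetic MSRE-qPCR cohorts
#'
#' Builds and validates the configuration object consumed by
#' [simulate_cohort()], [simulate_qpcr()], [simulate_gel()] and
#' [simulate_standards()]. All methylation quantities are percentages in
#' \[0, 100\]; Ct quantities are PCR cycles.
#'
#' The default configuration encodes a 180 + 180 prostate-cancer (PCa) vs.
#' benign-hyperplasia (BPH) blood cohort:
#' \itemize{
#'   \item \emph{group} mode draws true methylation from a two-component
#'     mixture per group. The core component is a truncated normal on the
#'     correct side of the 55\% diagnostic cutoff (PCa on \[0, 50\], BPH on
#'     \[60, 100\]); a small contamination component sits just across the
#'     cutoff (PCa contaminants near 60\%, BPH contaminants near 48\%) at a
#'     fraction of 3/180 per group, which reproduces 177/180 sensitivity and
#'     specificity while keeping the AUC near 1.
#'   \item \emph{stratified} mode assigns the PCa group to tumor-stage and
#'     ISUP-grade strata with fixed counts and per-stratum hypomethylation
#'     means, for association analyses.
#' }
#' `pca_meth` / `bph_meth` give the target \emph{group-level} mean of true
#' methylation (the generator solves the underlying core-component location
#' so that the realized mixture mean, contamination included, matches) and
#' the spread (underlying normal sd before truncation).
#'
#' @param n_pca,n_bph Group sizes (positive integers).
#' @param mode `"group"` or `"stratified"`.
#' @param pca_meth,bph_meth Numeric `c(mean, sd)` in percent: target group
#'   mean of true methylation and underlying core-component sd.
#' @param contamination_fraction Fraction of each group drawn from the
#'   near-cutoff contamination component (group mode only).
#' @param contamination_center Numeric `c(pca, bph)`: contamination component
#'   centers in percent methylation.
#' @param contamination_sd Contamination component sd (percent).
#' @param stage_table,grade_table Data frames with columns `label`, `n`,
#'   `hypometh_mean` (percent); counts must each sum to `n_pca`.
#' @param within_stratum_sd Within-stratum sd of hypomethylation (percent),
#'   stratified mode.
#' @param stage_weight Weight of the stage stratum mean (vs. grade) in the
#'   blended stratum center, stratified mode.
#' @param psa_params List with `pca` and `bph` elements, each
#'   `c(median, sd)` of total PSA in ng/mL (lognormal marginals).
#' @param age_params,weight_params Lists with `pca`/`bph` elements
#'   `c(mean, sd)`; ages truncated to \[40, 100\] years, prostate weights to
#'   \[1, 200\] g.
#' @param psa_meth_rank_corr Within-group Gaussian-copula correlation
#'   coupling PSA to true methylation (0 = independent given group).
#' @param ct_noise_sd Per-replicate Ct noise sd in cycles.
#' @param ct_baseline Undigested (control) Ct in cycles.
#' @param ct_cap Maximum observable Ct (no-amplification cap), cycles.
#' @param gel_alpha,gel_beta Affine densitometry response: expected
#'   digested/undigested ratio is `gel_beta + gel_alpha * m` for methylated
#'   fraction `m`.
#' @param gel_noise_sd Densitometry noise sd on the ratio scale.
#' @param seed Integer run seed (mandatory in pipeline runs).
#'
#' @return An object of class `msre_config` (a validated named list).
#' @seealso [calibrate_generator()] to tune knobs against target moments,
#'   [read_config()] / [write_config()] for the YAML representation.
#' @export
#' @examples
#' cfg <- generator_config(seed = 1)
#' cohort <- simulate_cohort(cfg)
#' table(cohort$group)
generator_config <- function(n_pca = 180L,
                             n_bph = 180L,
                             mode = c("group", "stratified"),
                             pca_meth = c(mean = 8, sd = 11.76),
                             bph_meth = c(mean = 84.5, sd = 15.12),
                             contamination_fraction = 3 / 180,
                             contamination_center = c(pca = 60, bph = 48),
                             contamination_sd = 5,
                             stage_table = default_stage_table(),
                             grade_table = default_grade_table(),
                             within_stratum_sd = 1.0,
                             stage_weight = 0.65,
                             psa_params = list(pca = c(median = 12, sd = 21.33),
                                               bph = c(median = 4.4, sd = 5.4)),
                             age_params = list(pca = c(mean = 69.5, sd = 17.67),
                                               bph = c(mean = 68.65, sd = 15.6)),
                             weight_params = list(pca = c(mean = 36.83, sd = 38.36),
                                                  bph = c(mean = 56.26, sd = 27.74)),
                             psa_meth_rank_corr = 0,
                             ct_noise_sd = 0.15,
                             ct_baseline = 25,
                             ct_cap = 40,
                             gel_alpha = 0.82,
                             gel_beta = 0.14,
                             gel_noise_sd = 0.105,
                             seed = 1L) {
  mode <- match.arg(mode)
  cfg <- structure(list(
    n_pca = as.integer(n_pca), n_bph = as.integer(n_bph), mode = mode,
    pca_meth = unname(pca_meth), bph_meth = unname(bph_meth),
    contamination_fraction = contamination_fraction,
    contamination_center = unname(contamination_center),
    contamination_sd = contamination_sd,
    stage_table = stage_table, grade_table = grade_table,
    within_stratum_sd = within_stratum_sd, stage_weight = stage_weight,
    psa_params = lapply(psa_params, unname),
    age_params = lapply(age_params, unname),
    weight_params = lapply(weight_params, unname),
    psa_meth_rank_corr = psa_meth_rank_corr,
    ct_noise_sd = ct_noise_sd, ct_baseline = ct_baseline, ct_cap = ct_cap,
    gel_alpha = gel_alpha, gel_beta = gel_beta, gel_noise_sd = gel_noise_sd,
    seed = as.integer(seed)
  ), class = "msre_config")
  validate_config(cfg)
  cfg
}

#' Tumor-stage and ISUP-grade stratum tables
#'
#' Default stratum layouts for stratified-mode simulation: five tumor-stage
#' strata (I-V) and five ISUP grade-group strata (1-5), each with a subject
#' count and a mean hypomethylation percentage. Counts sum to 180.
#'
#' @return A data frame with columns `label`, `n`, `hypometh_mean`.
#' @export
default_stage_table <- function() {
  data.frame(label = c("I", "II", "III", "IV", "V"),
             n = c(7L, 15L, 33L, 70L, 55L),
             hypometh_mean = c(10, 35, 64.5, 96, 100),
             stringsAsFactors = FALSE)
}

#' @rdname default_stage_table
#' @export
default_grade_table <- function() {
  data.frame(label = c("1", "2", "3", "4", "5"),
             n = c(15L, 20L, 46L, 20L, 79L),
             hypometh_mean = c(5.66, 30, 55.2, 74, 100),
             stringsAsFactors = FALSE)
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "msre_config"))
  err <- function(...) stop("invalid generator config: ", ..., call. = FALSE)
  if (cfg$n_pca <= 0L || cfg$n_bph <= 0L) err("group sizes must be positive")
  if (!cfg$mode %in% c("group", "stratified")) err("unknown mode ", cfg$mode)
  pct <- c(cfg$pca_meth[1], cfg$bph_meth[1], cfg$contamination_center,
           cfg$stage_table$hypometh_mean, cfg$grade_table$hypometh_mean)
  if (any(pct < 0 | pct > 100)) err("percentage fields must lie in [0, 100]")
  if (cfg$contamination_fraction < 0 || cfg$contamination_fraction > 1)
    err("contamination_fraction must lie in [0, 1]")
  sds <- c(cfg$pca_meth[2], cfg$bph_meth[2], cfg$contamination_sd,
           cfg$within_stratum_sd, cfg$ct_noise_sd, cfg$gel_noise_sd)
  if (any(sds < 0)) err("standard deviations must be non-negative")
  if (cfg$stage_weight < 0 || cfg$stage_weight > 1)
    err("stage_weight must lie in [0, 1]")
  if (!is.finite(cfg$ct_baseline) || !is.finite(cfg$ct_cap) ||
      cfg$ct_baseline >= cfg$ct_cap)
    err("ct_baseline must be below ct_cap")
  for (tb in list(cfg$stage_table, cfg$grade_table))
    if (!all(c("label", "n", "hypometh_mean") %in% names(tb)))
      err("stratum tables need columns label, n, hypometh_mean")
  if (cfg$mode == "stratified") {
    if (sum(cfg$stage_table$n) != cfg$n_pca)
      err("stage_table counts must sum to n_pca")
    if (sum(cfg$grade_table$n) != cfg$n_pca)
      err("grade_table counts must sum to n_pca")
  }
  if (abs(cfg$psa_meth_rank_corr) > 1) err("psa_meth_rank_corr must lie in [-1, 1]")
  if (is.na(cfg$seed)) err("seed is required")
  invisible(cfg)
}

#' @export
print.msre_config <- function(x, ...) {
  cat("MSRE-qPCR generator config (", x$mode, " mode)\n", sep = "")
  cat("  cohort: ", x$n_pca, " PCa + ", x$n_bph, " BPH, seed ", x$seed, "\n", sep = "")
  cat("  methylation targets (group mean %): PCa ", x$pca_meth[1],
      ", BPH ", x$bph_meth[1], "\n", sep = "")
  cat("  contamination: ", signif(x$contamination_fraction, 3),
      " per group at ", x$contamination_center[1], "% / ",
      x$contamination_center[2], "%\n", sep = "")
  cat("  qPCR: baseline ", x$ct_baseline, ", cap ", x$ct_cap,
      ", noise sd ", x$ct_noise_sd, " cycles\n", sep = "")
  cat("  gel: D/C = ", x$gel_beta, " + ", x$gel_alpha,
      " * m, noise sd ", x$gel_noise_sd, "\n", sep = "")
  invisible(x)
}

#' Read or write a generator configuration as YAML
#'
#' The on-disk representation is a flat YAML mapping mirroring the
#' [generator_config()] arguments; stratum tables are nested lists of
#' `label`/`n`/`hypometh_mean` records. A fully commented default file ships
#' in `system.file("extdata", "default-config.yaml", package = "msremeth")`.
#'
#' @param path File path.
#' @return `read_config()` returns an `msre_config`; `write_config()`
#'   invisibly returns `path`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  tab <- function(x) do.call(rbind, lapply(x, function(r)
    data.frame(label = as.character(r$label), n = as.integer(r$n),
               hypometh_mean = as.numeric(r$hypometh_mean),
               stringsAsFactors = FALSE)))
  args <- raw
  for (nm in c("stage_table", "grade_table"))
    if (!is.null(raw[[nm]])) args[[nm]] <- tab(raw[[nm]])
  for (nm in c("psa_params", "age_params", "weight_params"))
    if (!is.null(raw[[nm]])) args[[nm]] <- lapply(raw[[nm]], unlist)
  do.call(generator_config, args)
}

#' @rdname read_config
#' @param config An `msre_config`.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  out <- unclass(config)
  for (nm in c("stage_table", "grade_table")) {
    tb <- out[[nm]]
    out[[nm]] <- lapply(seq_len(nrow(tb)), function(i)
      list(label = tb$label[i], n = tb$n[i], hypometh_mean = tb$hypometh_mean[i]))
  }
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}
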