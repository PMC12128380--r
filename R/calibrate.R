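#' Calibrate generator knobs against target summary statistics
#'
#' Moment-matching for the synthetic-data generator: adjusts specific
#' configuration knobs so that the large-sample moments of simulated
#' cohorts hit named targets. Supported target names:
#' \describe{
#'   \item{`pca_hypometh_mean`, `bph_hypometh_mean`}{Group mean
#'     hypomethylation \% (group mode). Solved analytically through the
#'     truncated-normal mixture (the generator already places the core
#'     component so the realized mean matches the configured target), after
#'     a feasibility check against the truncation bounds.}
#'   \item{`dc_pca_mean`, `dc_bph_mean`}{Group mean D/C gel ratio; solved
#'     through the affine response at the group methylation mean.}
#'   \item{`psa_meth_rho`}{Pooled (both groups) Spearman correlation of PSA
#'     with methylation; bounded grid search over the within-group
#'     Gaussian-copula correlation, each candidate evaluated by Monte Carlo
#'     at `n_mc` subjects per group.}
#'   \item{`concordance_r2`}{qPCR-vs-gel agreement; monotone bisection on
#'     `gel_noise_sd`, Monte Carlo evaluated.}
#' }
#' The search is bounded and deterministic given `config$seed`; an
#' unreachable target raises a `calibration_failure` error naming the
#' offending target instead of looping.
#'
#' @param config Starting [generator_config()].
#' @param targets Named numeric vector/list of target values (see above).
#' @param tolerance Acceptable absolute deviation for Monte-Carlo-matched
#'   targets (default 0.02).
#' @param n_mc Subjects per group per Monte Carlo evaluation (default
#'   10000).
#' @return The calibrated `msre_config`. Targets already met by the input
#'   configuration leave it unchanged (fixed point).
#' @export
calibrate_generator <- function(config, targets, tolerance = 0.02,
                                n_mc = 10000L) {
  validate_config(config)
  targets <- as.list(targets)
  known <- c("pca_hypometh_mean", "bph_hypometh_mean", "dc_pca_mean",
             "dc_bph_mean", "psa_meth_rho", "concordance_r2")
  bad <- setdiff(names(targets), known)
  if (length(bad))
    stop("unknown calibration target(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  fail <- function(target, why) {
    stop(structure(class = c("calibration_failure", "error", "condition"),
                   list(message = sprintf(
                     "calibration failure for target '%s': %s", target, why),
                     call = NULL, target = target)))
  }

  for (grp in c("pca", "bph")) {
    nm <- paste0(grp, "_hypometh_mean")
    if (is.null(targets[[nm]])) next
    meth_target <- 100 - targets[[nm]]
    bounds <- if (grp == "pca") c(0, 50) else c(60, 100)
    c_bounds <- if (grp == "pca") c(55, 100) else c(0, 55)
    c_mean <- if (grp == "pca") config$contamination_center[1]
              else config$contamination_center[2]
    f <- round(config$contamination_fraction *
                 (if (grp == "pca") config$n_pca else config$n_bph)) /
      (if (grp == "pca") config$n_pca else config$n_bph)
    m_cont <- if (f > 0)
      truncnorm_mean(c_mean, config$contamination_sd, c_bounds[1], c_bounds[2])
      else 0
    core_target <- (meth_target - f * m_cont) / (1 - f)
    if (core_target <= bounds[1] || core_target >= bounds[2])
      fail(nm, sprintf(
        "implied core mean %.2f%% lies outside truncation bounds [%g, %g]",
        core_target, bounds[1], bounds[2]))
    field <- paste0(grp, "_meth")
    config[[field]][1] <- meth_target
  }

  for (grp in c("pca", "bph")) {
    nm <- paste0("dc_", grp, "_mean")
    if (is.null(targets[[nm]])) next
    # expected ratio at the group methylation mean; solve beta holding alpha
    m <- (if (grp == "pca") config$pca_meth[1] else config$bph_meth[1]) / 100
    implied <- targets[[nm]] - config$gel_alpha * m
    if (implied < -0.2 || implied > 1.2)
      fail(nm, sprintf("implied gel intercept %.3f is outside [-0.2, 1.2]",
                       implied))
    other <- setdiff(c("pca", "bph"), grp)
    other_nm <- paste0("dc_", other, "_mean")
    if (!is.null(targets[[other_nm]])) {
      # both group means given: two-point solve for slope and intercept
      m1 <- config$pca_meth[1] / 100; m2 <- config$bph_meth[1] / 100
      y1 <- targets$dc_pca_mean; y2 <- targets$dc_bph_mean
      if (abs(m1 - m2) < 1e-8) fail(nm, "group methylation means coincide")
      config$gel_alpha <- (y2 - y1) / (m2 - m1)
      config$gel_beta <- y1 - config$gel_alpha * m1
      targets[[other_nm]] <- NULL
    } else {
      config$gel_beta <- implied
    }
  }

  if (!is.null(targets$psa_meth_rho)) {
    eval_rho <- function(rho) {
      cfg <- config
      cfg$psa_meth_rank_corr <- rho
      cfg$n_pca <- cfg$n_bph <- as.integer(n_mc)
      co <- simulate_cohort(cfg)
      spearman_corr(co$tpsa, 100 * co$true_meth)$rho
    }
    current <- eval_rho(config$psa_meth_rank_corr)
    if (abs(current - targets$psa_meth_rho) > tolerance) {
      grid <- seq(-0.99, 0.99, by = 0.02)
      vals <- vapply(grid, eval_rho, numeric(1))
      best <- which.min(abs(vals - targets$psa_meth_rho))
      if (abs(vals[best] - targets$psa_meth_rho) > tolerance)
        fail("psa_meth_rho", sprintf(
          "closest achievable pooled rho %.3f (at copula rho %.2f) misses target %.3f",
          vals[best], grid[best], targets$psa_meth_rho))
      config$psa_meth_rank_corr <- grid[best]
    }
  }

  if (!is.null(targets$concordance_r2)) {
    eval_r2 <- function(sg) {
      cfg <- config
      cfg$gel_noise_sd <- sg
      cfg$n_pca <- cfg$n_bph <- as.integer(n_mc)
      co <- simulate_cohort(cfg)
      q <- quantify_qpcr(simulate_qpcr(co, cfg))
      g <- quantify_gel(simulate_gel(co, cfg), cfg$gel_alpha, cfg$gel_beta)
      concordance_r2(q$methylation_pct[match(co$id, q$sample_id)],
                     g$methylation_pct[match(co$id, g$sample_id)])
    }
    current <- eval_r2(config$gel_noise_sd)
    if (abs(current - targets$concordance_r2) > tolerance) {
      lo <- 0.001; hi <- 0.5
      if (eval_r2(lo) < targets$concordance_r2 - tolerance ||
          eval_r2(hi) > targets$concordance_r2 + tolerance)
        fail("concordance_r2", "target outside the achievable range of gel_noise_sd in [0.001, 0.5]")
      for (i in 1:25) {
        mid <- (lo + hi) / 2
        if (eval_r2(mid) > targets$concordance_r2) lo <- mid else hi <- mid
      }
      config$gel_noise_sd <- (lo + hi) / 2
    }
  }

  validate_config(config)
  config
}
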