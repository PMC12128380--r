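#' Delta-Ct from paired digested/undigested replicates
#'
#' Computes `mean(ct_digested) - mean(ct_undigested)` for one sample.
#' Replicates are averaged in Ct space (Ct is the linear scale of the
#' underlying exponential model) before subtraction. A digested replicate at
#' the amplification cap marks the sample as below the detection limit of
#' the assay; if \emph{all undigested} replicates are capped the sample had
#' no amplifiable input DNA and an error is raised.
#'
#' @param ct_digested,ct_undigested Numeric vectors of replicate Ct values
#'   (cycles), at least one each.
#' @param capped_digested,capped_undigested Logical vectors flagging
#'   replicates that hit the no-amplification cap (default: none).
#' @return A list with `delta_ct` (cycles) and `capped` (TRUE if any
#'   digested replicate was capped).
#' @export
#' @examples
#' compute_delta_ct(c(30, 30), c(25, 25))$delta_ct  # 5
compute_delta_ct <- function(ct_digested, ct_undigested,
                             capped_digested = rep(FALSE, length(ct_digested)),
                             capped_undigested = rep(FALSE, length(ct_undigested))) {
  if (length(ct_digested) < 1L || length(ct_undigested) < 1L)
    stop("need at least one replicate per arm", call. = FALSE)
  if (all(capped_undigested))
    stop("all undigested replicates capped: no amplifiable input DNA",
         call. = FALSE)
  list(delta_ct = mean(ct_digested) - mean(ct_undigested),
       capped = any(capped_digested))
}

#' Methylation percentage from delta-Ct
#'
#' The exponential quantification formula `100 * exp(-0.7 * delta_ct)`,
#' clamped to \[0, 100\]. The coefficient -0.7 (approximately `-ln 2`, so the
#' formula is the familiar 2^-dCt rule expressed in base e) assumes ~100\%
#' amplification efficiency: each cycle of delay after digestion halves the
#' surviving (methylated) template. A negative delta-Ct — the digested
#' reaction amplifying \emph{earlier} than its control, which arises from
#' noise at full methylation — clamps to 100\% with a warning.
#'
#' @param delta_ct Numeric vector of delta-Ct values (cycles).
#' @param coefficient Exponential coefficient (fixed assay constant;
#'   default 0.7).
#' @return Methylation percentages in \[0, 100\], non-increasing in
#'   `delta_ct`.
#' @export
#' @examples
#' methylation_from_delta_ct(0)       # 100
#' methylation_from_delta_ct(-log(0.5) / 0.7)  # 50
methylation_from_delta_ct <- function(delta_ct, coefficient = 0.7) {
  if (any(!is.finite(delta_ct) & !is.infinite(delta_ct)))
    stop("delta_ct must not contain NA/NaN", call. = FALSE)
  if (any(delta_ct < 0))
    warning("negative delta-Ct clamped to 100% methylation")
  pmin(pmax(100 * exp(-coefficient * delta_ct), 0), 100)
}

#' Hypomethylation percentage
#'
#' The complement `100 - methylation_pct`: the fraction of template cleaved
#' by the methylation-sensitive enzyme. This is the primary reported
#' quantity for a biomarker that loses methylation in disease.
#'
#' @param methylation_pct Methylation percentages in \[0, 100\].
#' @return `100 - methylation_pct`.
#' @export
hypomethylation <- function(methylation_pct) {
  stopifnot(all(methylation_pct >= 0 & methylation_pct <= 100))
  100 - methylation_pct
}

#' Digested/undigested band-intensity ratio
#'
#' The D/C densitometry ratio: digested-lane intensity divided by the
#' undigested control lane. Scale-invariant (units of the densitometer
#' cancel). A proxy for the methylated, digestion-resistant fraction.
#'
#' @param intensity_digested Non-negative intensities (arbitrary units).
#' @param intensity_undigested Strictly positive control intensities.
#' @return The elementwise ratio.
#' @export
#' @examples
#' dc_ratio(21, 100)  # 0.21
dc_ratio <- function(intensity_digested, intensity_undigested) {
  if (any(intensity_undigested <= 0))
    stop("invalid lane: undigested band intensity must be positive",
         call. = FALSE)
  if (any(intensity_digested < 0))
    stop("band intensities must be non-negative", call. = FALSE)
  intensity_digested / intensity_undigested
}

#' Quantify a qPCR measurement table into methylation calls
#'
#' Reduces replicate Ct values per sample (arithmetic mean in Ct space),
#' applies [compute_delta_ct()] and [methylation_from_delta_ct()], and
#' returns one methylation call per sample. Samples whose digested
#' replicates all hit the amplification cap are flagged `below_detection`
#' (their methylation is reported at the formula value for the capped
#' delta-Ct, effectively ~0).
#'
#' @param qpcr Long-format table from [simulate_qpcr()] (columns
#'   `sample_id`, `ct_digested`, `ct_undigested`, optionally the `capped_*`
#'   flags).
#' @return A data frame of calls: `sample_id`, `method` (`"qPCR"`),
#'   `delta_ct`, `methylation_pct`, `hypomethylation_pct`,
#'   `below_detection`.
#' @export
quantify_qpcr <- function(qpcr) {
  need <- c("sample_id", "ct_digested", "ct_undigested")
  if (!all(need %in% names(qpcr)))
    stop("qpcr table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(qpcr$capped_digested)) qpcr$capped_digested <- FALSE
  if (is.null(qpcr$capped_undigested)) qpcr$capped_undigested <- FALSE
  id <- factor(qpcr$sample_id, levels = unique(qpcr$sample_id))
  und_dead <- tapply(qpcr$capped_undigested, id, all)
  if (any(und_dead))
    stop("all undigested replicates capped for sample(s) ",
         paste(levels(id)[und_dead], collapse = ", "),
         ": no amplifiable input DNA", call. = FALSE)
  delta <- as.numeric(tapply(qpcr$ct_digested, id, mean) -
                        tapply(qpcr$ct_undigested, id, mean))
  capped <- as.logical(tapply(qpcr$capped_digested, id, any))
  meth <- suppressWarnings(methylation_from_delta_ct(delta))
  data.frame(sample_id = levels(id), method = "qPCR", delta_ct = delta,
             methylation_pct = meth, hypomethylation_pct = 100 - meth,
             below_detection = capped, stringsAsFactors = FALSE)
}

#' Quantify gel densitometry into methylation calls
#'
#' Converts D/C band-intensity ratios to methylation percentages by
#' inverting the affine densitometry response
#' `ratio = gel_beta + gel_alpha * m`, clamped to \[0, 100\].
#'
#' @param gel Table from [simulate_gel()] (columns `sample_id`,
#'   `intensity_digested`, `intensity_undigested`).
#' @param gel_alpha,gel_beta Affine response coefficients (defaults match
#'   [generator_config()]).
#' @return A data frame of calls with `method = "MSRE-PCR"`, columns
#'   `sample_id`, `method`, `dc_ratio`, `methylation_pct`,
#'   `hypomethylation_pct`.
#' @export
quantify_gel <- function(gel, gel_alpha = 0.82, gel_beta = 0.14) {
  ratio <- dc_ratio(gel$intensity_digested, gel$intensity_undigested)
  meth <- pmin(pmax(100 * (ratio - gel_beta) / gel_alpha, 0), 100)
  data.frame(sample_id = gel$sample_id, method = "MSRE-PCR",
             dc_ratio = ratio, methylation_pct = meth,
             hypomethylation_pct = 100 - meth, stringsAsFactors = FALSE)
}

#' Fit the qPCR calibration standard curve
#'
#' Ordinary least squares of per-standard delta-Ct against
#' `log10(nominal methylation %)` over standards of known level. Under the
#' exponential model `delta_ct = -ln(m)/0.7` the curve is linear in
#' `log10` with slope `-ln(10)/0.7 = -3.289` cycles per decade. The 0\%
#' standard has no logarithm and is excluded from the fit; it is instead
#' reported as a digestion control (its digested reactions should sit at
#' the amplification cap).
#'
#' @param standards Table from [simulate_standards()] (columns
#'   `nominal_meth`, `ct_digested`, `ct_undigested`, optional `capped_*`).
#' @return An object of class `msre_calibration`: list with `slope`,
#'   `intercept`, `r_squared`, `n_points`, `fit` (the `lm` object) and
#'   `zero_control` (NULL if no 0\% standard; else a list with its mean
#'   delta-Ct and whether all its digested replicates were capped).
#' @export
fit_standard_curve <- function(standards) {
  if (is.null(standards$capped_digested)) standards$capped_digested <- FALSE
  if (is.null(standards$capped_undigested)) standards$capped_undigested <- FALSE
  levels <- unique(standards$nominal_meth)
  pos <- levels[levels > 0]
  if (length(pos) < 3L)
    stop("insufficient standards: need >= 3 distinct positive levels",
         call. = FALSE)
  per_level <- lapply(levels, function(lv) {
    sub <- standards[standards$nominal_meth == lv, ]
    d <- compute_delta_ct(sub$ct_digested, sub$ct_undigested,
                          sub$capped_digested, sub$capped_undigested)
    data.frame(nominal_meth = lv, delta_ct = d$delta_ct, capped = d$capped)
  })
  per_level <- do.call(rbind, per_level)
  dat <- per_level[per_level$nominal_meth > 0, ]
  fit <- lm(delta_ct ~ log10(nominal_meth), data = dat)
  zero <- NULL
  if (any(per_level$nominal_meth == 0)) {
    z <- per_level[per_level$nominal_meth == 0, ]
    zero <- list(delta_ct = z$delta_ct, fully_digested = z$capped)
  }
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n_points = nrow(dat),
                 fit = fit,
                 zero_control = zero),
            class = "msre_calibration")
}

#' @export
print.msre_calibration <- function(x, ...) {
  cat("qPCR standard curve: delta-Ct ~ log10(methylation %)\n")
  cat(sprintf("  slope %.4f cycles/decade, intercept %.4f, R^2 %.4f (%d levels)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  if (!is.null(x$zero_control))
    cat("  0% digestion control:",
        if (isTRUE(x$zero_control$fully_digested)) "complete digestion (capped)"
        else sprintf("delta-Ct %.2f (incomplete digestion?)",
                     x$zero_control$delta_ct), "\n")
  invisible(x)
}
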