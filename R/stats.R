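#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The statistic is the
#' number of (a, b) pairs with `a < b` plus half the ties (ties get average
#' ranks). Small tie-free samples use the exact null distribution; larger
#' or tied samples use the normal approximation with tie correction
#' (delegated to [stats::wilcox.test()]).
#'
#' @param a,b Numeric vectors, both non-empty.
#' @return List with `statistic` (U for sample `a`), `p_value`
#'   (two-sided), `n` (`c(n_a, n_b)`).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$statistic  # 0
mann_whitney_u <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L)
    stop("both samples must be non-empty", call. = FALSE)
  wt <- suppressWarnings(wilcox.test(a, b, exact = NULL, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n = c(length(a), length(b)))
}

as_grouped_ <- function(g) {
  if (is.data.frame(g)) {
    stopifnot(all(c("group", "value") %in% names(g)))
    split(g$value, g$group)
  } else if (is.list(g)) g
  else stop("grouped values must be a list or a group/value data frame",
            call. = FALSE)
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based one-way comparison across two or more groups, with tie
#' correction (delegated to [stats::kruskal.test()]). If every pooled value
#' is identical the statistic is 0 with p = 1.
#'
#' @param g Either a named list of numeric vectors or a data frame with
#'   columns `group` and `value`.
#' @return List with `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(g) {
  vals <- as_grouped_(g)
  if (length(vals) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(vals) == 0L)) stop("every group must be non-empty", call. = FALSE)
  x <- unlist(vals, use.names = FALSE)
  if (length(x) < 5L) stop("need total n >= 5", call. = FALSE)
  if (length(unique(x)) == 1L)
    return(list(statistic = 0, p_value = 1, df = length(vals) - 1L))
  grp <- factor(rep(names(vals) %||% seq_along(vals), lengths(vals)))
  kt <- kruskal.test(x, grp)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dunn's post hoc pairwise comparisons
#'
#' Follows a Kruskal-Wallis omnibus test: for each pair of groups the
#' z statistic is the difference in mean pooled ranks divided by its
#' tie-corrected standard error
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum (t^3 - t)}{12 (N-1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)}}
#' with two-sided normal p-values, Bonferroni-adjusted over all
#' `k(k-1)/2` pairs by default. Singleton groups are included with a
#' warning (their variance term uses n = 1).
#'
#' @param g Grouped values as in [kruskal_wallis()].
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return Data frame with one row per pair: `group1`, `group2`, `z`,
#'   `p_value`, `p_adjusted`.
#' @export
dunn_posthoc <- function(g, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  vals <- as_grouped_(g)
  if (length(vals) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(vals) == 1L))
    warning("singleton group(s) included in Dunn's comparisons")
  labs <- names(vals) %||% as.character(seq_along(vals))
  x <- unlist(vals, use.names = FALSE)
  grp <- rep(labs, lengths(vals))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, grp, mean)[labs]
  n <- lengths(vals)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(seq_along(vals), 2)
  k <- ncol(pairs)
  res <- data.frame(group1 = labs[pairs[1, ]], group2 = labs[pairs[2, ]],
                    z = NA_real_, p_value = NA_real_, p_adjusted = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(v0 * (1 / n[i1] + 1 / n[i2]))
    z <- (rbar[i1] - rbar[i2]) / se
    res$z[j] <- z
    res$p_value[j] <- 2 * pnorm(-abs(z))
  }
  res$p_adjusted <- if (adjust == "bonferroni")
    pmin(res$p_value * k, 1) else res$p_value
  res
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks, i.e. Spearman's rho with the
#' standard tie handling; p-values from [stats::cor.test()] (exact for
#' small tie-free samples, t approximation otherwise).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p_value`, `n`.
#' @export
#' @examples
#' spearman_corr(1:3, 3:1)$rho  # -1
spearman_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance input", call. = FALSE)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  exact = length(x) <= 10))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Simple linear regression with confidence intervals
#'
#' Ordinary least squares of `y` on `x` with the signed correlation
#' coefficient, its square, a t-based 95\% confidence interval for the
#' slope, and the slope's two-sided p-value.
#'
#' @param x,y Numeric vectors of equal length >= 3; `x` must vary.
#' @return List with `slope`, `intercept`, `r`, `r_squared`, `ci95_slope`
#'   (length-2 vector), `p_value`, `n`.
#' @export
#' @examples
#' linear_fit(1:5, 2 * (1:5) + 1)$slope  # 2
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need n >= 3 for regression", call. = FALSE)
  if (sd(x) == 0) stop("degenerate design: x is constant", call. = FALSE)
  fit <- lm(y ~ x)
  sm <- summary(fit)
  r <- if (sd(y) == 0) 0 else cor(x, y)
  ci <- unname(confint(fit, "x", level = 0.95))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r = r, r_squared = r^2, ci95_slope = as.numeric(ci),
       p_value = sm$coefficients["x", "Pr(>|t|)"], n = length(x))
}

#' Concordance between two per-sample methylation estimates
#'
#' Squared Pearson correlation between two methods' estimates on the same
#' samples (e.g. gel densitometry vs. qPCR), the usual agreement summary
#' for paired assay validation.
#'
#' @param a,b Paired numeric vectors of equal length >= 3.
#' @return Squared Pearson correlation in \[0, 1\].
#' @export
concordance_r2 <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L)
    stop("a and b must be paired with length >= 3", call. = FALSE)
  if (sd(a) == 0 || sd(b) == 0)
    stop("undefined correlation: zero variance input", call. = FALSE)
  cor(a, b)^2
}
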