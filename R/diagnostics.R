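#' Classify samples at a methylation cutoff
#'
#' The diagnostic decision rule: a sample is called positive (cancer-like)
#' when its methylation percentage is \emph{strictly below} the cutoff
#' (default 55\%). Boundary samples are negative.
#'
#' @param methylation_pct Methylation percentages in \[0, 100\].
#' @param cutoff Cutoff percentage (default 55).
#' @return Character vector, `"positive"` or `"negative"`.
#' @export
#' @examples
#' classify_methylation(c(54.9, 55, 8))  # positive negative positive
classify_methylation <- function(methylation_pct, cutoff = 55) {
  stopifnot(all(methylation_pct >= 0 & methylation_pct <= 100),
            cutoff >= 0, cutoff <= 100)
  ifelse(methylation_pct < cutoff, "positive", "negative")
}

check_labels_ <- function(labels) {
  if (!all(labels %in% c("positive", "negative")))
    stop("labels must be 'positive'/'negative'", call. = FALSE)
  if (!any(labels == "positive") || !any(labels == "negative"))
    stop("undefined ROC: both classes must be present", call. = FALSE)
}

#' ROC curve for a lower-is-positive methylation score
#'
#' Builds the full receiver operating characteristic of the rule
#' "score < threshold is positive", with thresholds at midpoints between
#' adjacent distinct scores plus `-Inf`/`+Inf` sentinels. The area under
#' the curve is computed by trapezoidal integration over
#' (1 - specificity, sensitivity), which equals the concordance probability
#' `P(score_pos < score_neg) + 0.5 * P(tie)`.
#'
#' @param scores Numeric scores (methylation \%; lower = more positive).
#' @param labels `"positive"`/`"negative"` per sample.
#' @return An object of class `msre_roc`: list with `thresholds`,
#'   `sensitivity`, `specificity`, `auc`, `n_positive`, `n_negative`.
#' @export
#' @examples
#' roc_curve(c(1, 2, 3, 10, 11, 12),
#'           rep(c("positive", "negative"), each = 3))$auc  # 1
roc_curve <- function(scores, labels) {
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  check_labels_(labels)
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  s <- sort(unique(scores))
  thr <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(pos < t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, n_positive = length(pos), n_negative = length(neg)),
            class = "msre_roc")
}

#' @export
print.msre_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d positives vs %d negatives, AUC %.4f (%d thresholds)\n",
              x$n_positive, x$n_negative, x$auc, length(x$thresholds)))
  invisible(x)
}

#' Confusion summary at a fixed cutoff
#'
#' Counts and rates of the strict `< cutoff` rule at a single threshold.
#' Rates are exact ratios of counts.
#'
#' @inheritParams roc_curve
#' @param cutoff Threshold on the score scale (default 55).
#' @return List with counts `tp`, `fp`, `tn`, `fn` and rates `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy`.
#' @export
confusion_at <- function(scores, labels, cutoff = 55) {
  check_labels_(labels)
  call_pos <- scores < cutoff
  is_pos <- labels == "positive"
  tp <- sum(call_pos & is_pos); fn <- sum(!call_pos & is_pos)
  fp <- sum(call_pos & !is_pos); tn <- sum(!call_pos & !is_pos)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       accuracy = (tp + tn) / (tp + fp + tn + fn))
}

#' Standard error and confidence interval for an AUC
#'
#' Either the Hanley-McNeil closed-form standard error with a normal 95\%
#' interval (the convention of legacy ROC software), or a percentile
#' bootstrap resampling within each class.
#'
#' @param roc An `msre_roc`, or for bootstrap the original data via
#'   `scores`/`labels`.
#' @param method `"hanley-mcneil"` or `"bootstrap"`.
#' @param n_boot Bootstrap replicates (required > 0 for bootstrap).
#' @param seed RNG seed (required for bootstrap).
#' @param scores,labels Original data (bootstrap only).
#' @return List with `se`, `ci_low`, `ci_high` (CI clipped to \[0, 1\]).
#' @export
auc_confidence <- function(roc, method = c("hanley-mcneil", "bootstrap"),
                           n_boot = 2000L, seed = NULL,
                           scores = NULL, labels = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(roc, "msre_roc"))
  if (method == "hanley-mcneil") {
    A <- roc$auc
    if (A %in% c(0, 1))
      warning("degenerate AUC: Hanley-McNeil SE is 0")
    q1 <- A / (2 - A)
    q2 <- 2 * A^2 / (1 + A)
    np <- roc$n_positive; nn <- roc$n_negative
    se <- sqrt((A * (1 - A) + (np - 1) * (q1 - A^2) + (nn - 1) * (q2 - A^2)) /
                 (np * nn))
    list(se = se, ci_low = max(0, A - 1.96 * se), ci_high = min(1, A + 1.96 * se))
  } else {
    if (is.null(n_boot) || n_boot < 1L)
      stop("bootstrap requires n_boot >= 1", call. = FALSE)
    if (is.null(seed)) stop("bootstrap requires a seed", call. = FALSE)
    if (is.null(scores) || is.null(labels))
      stop("bootstrap requires the original scores and labels", call. = FALSE)
    check_labels_(labels)
    pos <- scores[labels == "positive"]
    neg <- scores[labels == "negative"]
    with_seed_(seed, {
      aucs <- vapply(seq_len(n_boot), function(i) {
        ps <- sample(pos, replace = TRUE)
        ns <- sample(neg, replace = TRUE)
        roc_curve(c(ps, ns), rep(c("positive", "negative"),
                                 c(length(ps), length(ns))))$auc
      }, numeric(1))
      ci <- unname(quantile(aucs, c(0.025, 0.975)))
      list(se = sd(aucs), ci_low = ci[1], ci_high = ci[2])
    })
  }
}

#' Youden's J optimal cutoff
#'
#' Utility sweep of `sensitivity + specificity - 1` over the ROC
#' thresholds. Provided for exploration; headline diagnostics use the fixed
#' assay cutoff.
#'
#' @param roc An `msre_roc`.
#' @return List with `threshold` and `j` at the maximum.
#' @export
youden_j <- function(roc) {
  stopifnot(inherits(roc, "msre_roc"))
  j <- roc$sensitivity + roc$specificity - 1
  i <- which.max(j)
  list(threshold = roc$thresholds[i], j = j[i])
}
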