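# shared fixtures: everything is generated in code at test time

# one full group-mode run: simulate, quantify both assays, diagnose
group_run <- function(seed, cfg = generator_config(seed = seed)) {
  cfg$seed <- as.integer(seed)
  cohort <- simulate_cohort(cfg)
  calls <- quantify_qpcr(simulate_qpcr(cohort, cfg))
  meth <- calls$methylation_pct[match(cohort$id, calls$sample_id)]
  gel <- quantify_gel(simulate_gel(cohort, cfg), cfg$gel_alpha, cfg$gel_beta)
  gmeth <- gel$methylation_pct[match(cohort$id, gel$sample_id)]
  gdc <- gel$dc_ratio[match(cohort$id, gel$sample_id)]
  labels <- ifelse(cohort$group == "PCa", "positive", "negative")
  list(cfg = cfg, cohort = cohort, meth = meth, gel_meth = gmeth,
       dc = gdc, labels = labels, pca = cohort$group == "PCa")
}

# pair-counting AUC oracle: P(pos < neg) + 0.5 P(tie), brute force
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  (sum(outer(pos, neg, "<")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# all permutations of seq_len(n), for small exhaustive oracles
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}
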