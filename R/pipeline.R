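#' Run the full simulate - quantify - diagnose - associate pipeline
#'
#' Composes every stage into one reproducible run: cohort simulation, qPCR
#' and gel forward models, methylation quantification by both methods,
#' standard-curve validation, ROC/threshold diagnostics, association
#' statistics, and method concordance. All intermediate tables, a summary
#' table and a JSON run manifest (config snapshot, seed, stage timings,
#' file digests, package version) are written to `out_dir` as delimited
#' text. Re-running with the same config and seed reproduces byte-identical
#' result tables; on failure, partially written outputs are removed.
#'
#' @param config An [generator_config()] object or the path to a YAML
#'   config file.
#' @param out_dir Output directory (created if needed).
#' @param cutoff Diagnostic methylation cutoff in percent (default 55).
#' @param format `"csv"` or `"tsv"`.
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, a list of class `msre_report` with elements
#'   `summary` (metric/value data frame), `tables` (the in-memory stage
#'   tables) and `manifest`.
#' @export
#' @examples
#' \donttest{
#' out <- run_pipeline(generator_config(n_pca = 30, n_bph = 30, seed = 1),
#'                     out_dir = tempfile())
#' head(out$summary)
#' }
run_pipeline <- function(config, out_dir, cutoff = 55,
                         format = c("csv", "tsv"), quiet = FALSE) {
  format <- match.arg(format)
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written))
  log_ <- function(...) if (!quiet) message("[msremeth] ", ...)
  timings <- list()
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }

  cohort <- timed("simulate", {
    co <- simulate_cohort(config)
    log_("simulated ", nrow(co), " subjects (", config$mode, " mode)")
    co
  })
  qpcr <- timed("qpcr", simulate_qpcr(cohort, config))
  gel <- timed("gel", simulate_gel(cohort, config))
  standards <- timed("standards", simulate_standards(config))

  calls_qpcr <- timed("quantify_qpcr", quantify_qpcr(qpcr))
  calls_gel <- timed("quantify_gel",
                     quantify_gel(gel, config$gel_alpha, config$gel_beta))
  curve <- timed("standard_curve", fit_standard_curve(standards))
  log_("quantified ", nrow(calls_qpcr), " samples; standard curve R^2 ",
       sprintf("%.4f", curve$r_squared))

  idx <- match(cohort$id, calls_qpcr$sample_id)
  meth <- calls_qpcr$methylation_pct[idx]
  labels <- ifelse(cohort$group == "PCa", "positive", "negative")
  diag <- timed("diagnose", {
    roc <- roc_curve(meth, labels)
    conf <- confusion_at(meth, labels, cutoff)
    ci <- auc_confidence(roc)
    list(roc = roc, conf = conf, ci = ci)
  })
  log_(sprintf("diagnostics: AUC %.4f, sens %.4f, spec %.4f at <%g%%",
               diag$roc$auc, diag$conf$sensitivity, diag$conf$specificity,
               cutoff))

  assoc <- timed("associate", association_table(cohort, calls_qpcr, calls_gel))
  gel_idx <- match(cohort$id, calls_gel$sample_id)
  r2 <- concordance_r2(meth, calls_gel$methylation_pct[gel_idx])

  grp_stat <- function(v, g) c(mean = mean(v[cohort$group == g]),
                               sd = sd(v[cohort$group == g]))
  dc <- calls_gel$dc_ratio[gel_idx]
  summary_df <- rbind(
    met("qpcr_methylation_pca", grp_stat(meth, "PCa")),
    met("qpcr_methylation_bph", grp_stat(meth, "BPH")),
    met("qpcr_hypomethylation_pca", grp_stat(100 - meth, "PCa")),
    met("qpcr_hypomethylation_bph", grp_stat(100 - meth, "BPH")),
    met("gel_dc_ratio_pca", grp_stat(dc, "PCa")),
    met("gel_dc_ratio_bph", grp_stat(dc, "BPH")),
    data.frame(metric = c("auc", "auc_se", "auc_ci_low", "auc_ci_high",
                          "sensitivity", "specificity", "cutoff",
                          "concordance_r2", "curve_slope", "curve_intercept",
                          "curve_r_squared"),
               value = c(diag$roc$auc, diag$ci$se, diag$ci$ci_low,
                         diag$ci$ci_high, diag$conf$sensitivity,
                         diag$conf$specificity, cutoff, r2, curve$slope,
                         curve$intercept, curve$r_squared),
               stringsAsFactors = FALSE)
  )

  roc_sweep <- data.frame(threshold = diag$roc$thresholds,
                          sensitivity = diag$roc$sensitivity,
                          specificity = diag$roc$specificity)

  tables <- list(cohort = cohort, qpcr = qpcr, gel = gel,
                 standards = standards, calls_qpcr = calls_qpcr,
                 calls_gel = calls_gel, roc_sweep = roc_sweep,
                 associations = assoc, summary = summary_df)
  ext <- if (format == "csv") ".csv" else ".tsv"
  for (nm in names(tables)) {
    path <- file.path(out_dir, paste0(nm, ext))
    write_table_(tables[[nm]], path, format)
    written <- c(written, path)
  }

  manifest <- list(
    package = "msremeth",
    version = as.character(packageVersion("msremeth")),
    seed = config$seed,
    cutoff = cutoff,
    format = format,
    config = unclass(config),
    timings_sec = timings,
    files = as.list(tools::md5sum(written))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  written <- c(written, manifest_path)
  ok <- TRUE
  log_("wrote ", length(written), " files to ", out_dir)
  invisible(structure(list(summary = summary_df, tables = tables,
                           manifest = manifest),
                      class = "msre_report"))
}

met <- function(name, ms) {
  data.frame(metric = paste0(name, c("_mean", "_sd")),
             value = unname(ms), stringsAsFactors = FALSE)
}

#' @export
print.msre_report <- function(x, ...) {
  cat("MSRE-qPCR pipeline report (seed ", x$manifest$seed, ")\n", sep = "")
  s <- x$summary
  fmt <- function(m) sprintf("%.4f", s$value[s$metric == m])
  cat("  hypomethylation mean: PCa ", fmt("qpcr_hypomethylation_pca_mean"),
      "%, BPH ", fmt("qpcr_hypomethylation_bph_mean"), "%\n", sep = "")
  cat("  D/C ratio mean: PCa ", fmt("gel_dc_ratio_pca_mean"), ", BPH ",
      fmt("gel_dc_ratio_bph_mean"), "\n", sep = "")
  cat("  AUC ", fmt("auc"), " (SE ", fmt("auc_se"), ", CI ",
      fmt("auc_ci_low"), "-", fmt("auc_ci_high"), "); sens ",
      fmt("sensitivity"), ", spec ", fmt("specificity"), " at <",
      sprintf("%g", s$value[s$metric == "cutoff"]), "%\n", sep = "")
  cat("  method concordance R^2 ", fmt("concordance_r2"),
      "; standard curve R^2 ", fmt("curve_r_squared"), "\n", sep = "")
  invisible(x)
}

# serialize with fixed 4-decimal doubles (locale-independent, reproducible)
write_table_ <- function(df, path, format = "csv") {
  out <- df
  for (nm in names(out)) {
    col <- out[[nm]]
    if (is.double(col)) out[[nm]] <- ifelse(is.finite(col),
                                            sprintf("%.4f", col),
                                            as.character(col))
  }
  sep <- if (format == "csv") "," else "\t"
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE,
                     na = "NA", eol = "\n")
  invisible(path)
}

#' Tidy association statistics for a quantified cohort
#'
#' Builds the association results table: Mann-Whitney comparison of
#' hypomethylation between diagnostic groups; in stratified mode,
#' Kruskal-Wallis omnibus tests (with Dunn's post hoc counts) and linear
#' regressions of hypomethylation on the stage and grade ordinals (I-V and
#' 1-5), plus their Spearman correlations; pooled Spearman correlations of
#' PSA with methylation by both methods; and PCa-only Spearman correlations
#' of age and prostate weight with hypomethylation.
#'
#' @param cohort Cohort table from [simulate_cohort()].
#' @param calls_qpcr qPCR calls from [quantify_qpcr()].
#' @param calls_gel Optional gel calls from [quantify_gel()].
#' @return A tidy data frame with columns `analysis`, `variable`, `method`,
#'   `statistic`, `estimate`, `p_value`.
#' @export
association_table <- function(cohort, calls_qpcr, calls_gel = NULL) {
  meth <- calls_qpcr$methylation_pct[match(cohort$id, calls_qpcr$sample_id)]
  hypo <- 100 - meth
  rows <- list()
  add <- function(analysis, variable, method, statistic, estimate, p_value)
    rows[[length(rows) + 1L]] <<- data.frame(
      analysis = analysis, variable = variable, method = method,
      statistic = statistic, estimate = estimate, p_value = p_value,
      stringsAsFactors = FALSE)

  mw <- mann_whitney_u(hypo[cohort$group == "PCa"],
                       hypo[cohort$group == "BPH"])
  add("group_comparison", "hypomethylation", "mann_whitney",
      mw$statistic, NA_real_, mw$p_value)

  pca <- cohort$group == "PCa"
  for (var in c("stage", "grade")) {
    v <- cohort[[var]][pca]
    if (all(is.na(v))) next
    ord <- as.integer(factor(v, levels = if (var == "stage")
      c("I", "II", "III", "IV", "V") else as.character(1:5)))
    kw <- kruskal_wallis(split(hypo[pca], v))
    add("omnibus", var, "kruskal_wallis", kw$statistic, NA_real_, kw$p_value)
    dn <- dunn_posthoc(split(hypo[pca], v))
    add("posthoc", var, "dunn_bonferroni",
        sum(dn$p_adjusted < 0.05), NA_real_, min(dn$p_adjusted))
    lf <- linear_fit(ord, hypo[pca])
    add("regression", var, "linear", lf$slope, lf$r, lf$p_value)
    sp <- spearman_corr(ord, hypo[pca])
    add("correlation", var, "spearman", NA_real_, sp$rho, sp$p_value)
  }

  sp <- spearman_corr(cohort$tpsa, meth)
  add("correlation", "tpsa", "spearman_qpcr", NA_real_, sp$rho, sp$p_value)
  if (!is.null(calls_gel)) {
    gm <- calls_gel$methylation_pct[match(cohort$id, calls_gel$sample_id)]
    spg <- spearman_corr(cohort$tpsa, gm)
    add("correlation", "tpsa", "spearman_gel", NA_real_, spg$rho, spg$p_value)
  }
  for (var in c("age", "prostate_weight")) {
    sp <- spearman_corr(cohort[[var]][pca], hypo[pca])
    add("correlation", var, "spearman", NA_real_, sp$rho, sp$p_value)
  }
  do.call(rbind, rows)
}

#' Validate a delimited input table against a pipeline schema
#'
#' Checks a user-supplied table against one of the pipeline's input
#' schemas, reporting missing columns, type violations and out-of-range
#' values without mutating the input.
#'
#' @param path Path to a readable CSV/TSV file (delimiter inferred from the
#'   extension).
#' @param schema One of `"cohort"`, `"qpcr"`, `"gel"`, `"standards"`.
#' @return A data frame of violations (zero rows when the table is valid)
#'   with columns `row` (NA for table-level problems), `column`, `problem`.
#' @export
validate_input <- function(path, schema = c("cohort", "qpcr", "gel",
                                            "standards")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  schemas <- list(
    cohort = list(required = c("id", "group", "true_meth"),
                  numeric = c(true_meth = NA, tpsa = NA, age = NA,
                              prostate_weight = NA),
                  range = list(true_meth = c(0, 1), tpsa = c(0, Inf),
                               age = c(0, 150), prostate_weight = c(0, Inf)),
                  levels = list(group = c("PCa", "BPH"))),
    qpcr = list(required = c("sample_id", "ct_digested", "ct_undigested"),
                numeric = c(ct_digested = NA, ct_undigested = NA),
                range = list(ct_digested = c(0, Inf),
                             ct_undigested = c(0, Inf)),
                levels = list()),
    gel = list(required = c("sample_id", "intensity_digested",
                            "intensity_undigested"),
               numeric = c(intensity_digested = NA, intensity_undigested = NA),
               range = list(intensity_digested = c(0, Inf),
                            intensity_undigested = c(1e-12, Inf)),
               levels = list()),
    standards = list(required = c("nominal_meth", "ct_digested",
                                  "ct_undigested"),
                     numeric = c(nominal_meth = NA, ct_digested = NA,
                                 ct_undigested = NA),
                     range = list(nominal_meth = c(0, 100),
                                  ct_digested = c(0, Inf),
                                  ct_undigested = c(0, Inf)),
                     levels = list())
  )
  sc <- schemas[[schema]]
  v <- data.frame(row = integer(0), column = character(0),
                  problem = character(0), stringsAsFactors = FALSE)
  viol <- function(row, column, problem)
    v <<- rbind(v, data.frame(row = row, column = column, problem = problem,
                              stringsAsFactors = FALSE))
  for (col in setdiff(sc$required, names(df)))
    viol(NA_integer_, col, "missing required column")
  for (col in intersect(names(sc$numeric), names(df))) {
    if (!is.numeric(df[[col]])) {
      viol(NA_integer_, col, "column is not numeric")
      next
    }
    rng <- sc$range[[col]]
    bad <- which(!is.na(df[[col]]) &
                   (df[[col]] < rng[1] | df[[col]] > rng[2]))
    for (i in bad)
      viol(i, col, sprintf("value %g outside [%g, %g]",
                           df[[col]][i], rng[1], rng[2]))
  }
  for (col in names(sc$levels)) {
    if (!col %in% names(df)) next
    bad <- which(!df[[col]] %in% sc$levels[[col]])
    for (i in bad)
      viol(i, col, sprintf("value '%s' not one of {%s}", df[[col]][i],
                           paste(sc$levels[[col]], collapse = ", ")))
  }
  v
}
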