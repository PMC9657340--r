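# Top-level pipeline: quantify -> predict -> engraft -> diversity ->
# scfa, driven by a run configuration, with a JSON report and TSV
# tables. Stages gate on the inputs present in the configuration:
# engraftment needs only the qPCR table; diversity needs the feature
# table (tree optional, required for Faith's PD); SCFA statistics need
# the SCFA table (correlations additionally need the feature table).

pipeline_log <- function(lines, level, ...) {
  c(lines, paste0("[", level, "] ", paste0(..., collapse = "")))
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes, in order and as the supplied inputs allow: qPCR
#' quantification with baseline estimation and subtraction, the
#' no-growth washout prediction, engraftment reporting (fold changes,
#' fitted growth multipliers, classifications), alpha diversity with
#' probiotic-ASV exclusion, F/B ratios, and SCFA statistics (stratified
#' pre/post Welch tests and genus-level Pearson correlations). Writes
#' `report.json`, flat TSV tables, and a log recording the resolved
#' defaults; repeated runs with the same inputs and seed are
#' byte-identical.
#'
#' @param config A `run_config` (from [read_run_config()]) or a list with
#'   the same keys.
#' @param outdir Output directory; overrides `config$outdir`.
#'
#' @return Invisibly, the report list (also written as JSON).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- if (!is.null(outdir)) outdir else config$outdir
  if (is.null(outdir)) stop_domain("an output directory is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  report <- list()

  for (key in c("qpcr", "feature_table", "taxonomy", "tree", "scfa",
                "metadata")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      stop_domain("config error: ", key, " file not found: ", config[[key]])
    }
  }
  if (is.null(config$qpcr)) {
    stop_domain("config error: a qPCR input table is required")
  }
  if (!is.null(config$tree) && is.null(config$feature_table)) {
    stop_domain("config error: a tree without a feature table is unusable")
  }

  chain <- config_chain(config)
  schedule <- config_schedule(config)
  dose <- config_dose(config)
  ordering <- if (is.null(config$transit_ordering)) "sequential" else
    config$transit_ordering
  window <- if (is.null(config$window)) 6 else config$window
  factor <- if (is.null(config$factor)) 2 else config$factor
  seed <- if (is.null(config$seed)) 20221026 else config$seed
  log_lines <- pipeline_log(log_lines, "INFO",
    "defaults: ordering=", ordering, " window=", window, " factor=", factor,
    " seed=", seed, " baseline=mean(pre-dose)",
    " shannon_base=", if (is.null(config$shannon_base)) "e" else
      config$shannon_base)

  # --- quantify -------------------------------------------------------
  series <- tryCatch(read_qpcr_csv(config$qpcr),
                     error = function(e) stop_domain("[quantify] ",
                                                     conditionMessage(e)))
  series <- lapply(series, function(s) {
    s <- tryCatch(estimate_baseline(s), error = function(e) {
      s$baseline <- 0
      s
    })
    baseline_subtract(s)
  })
  n_clamped <- sum(vapply(series, function(s) s$n_clamped, integer(1)))
  log_lines <- pipeline_log(log_lines, "INFO", "quantify: ", length(series),
                            " series, ", n_clamped,
                            " below-baseline value(s) clamped to 0")
  report$quantify <- list(n_series = length(series), n_clamped = n_clamped,
    baselines = lapply(series, function(s) s$baseline))

  # --- predict --------------------------------------------------------
  n_cycles <- if (is.null(config$n_cycles)) {
    max(vapply(series, function(s) max(s$cycles), numeric(1)))
  } else config$n_cycles
  traj <- predict_no_growth(chain, schedule, dose, n_cycles,
                            ordering = ordering)
  write_trajectory(traj, file.path(outdir, "predicted_trajectory.tsv"))
  log_lines <- pipeline_log(log_lines, "INFO", "predict: ", n_cycles,
                            " cycle(s), ordering=", ordering)

  # --- engraft --------------------------------------------------------
  engraft <- tryCatch(
    engraftment_report(series, chain, schedule, dose,
                       window = window, factor = factor, seed = seed),
    error = function(e) stop_domain("[engraft] ", conditionMessage(e)))
  utils::write.table(
    within(engraft$summary, {
      fold_change_end_vs_baseline <- format_num(fold_change_end_vs_baseline)
      final_cells_per_ml <- format_num(final_cells_per_ml)
      log10_reduction_over_period <- format_num(log10_reduction_over_period)
      geometric_mean_ratio <- format_num(geometric_mean_ratio)
      fitted_growth_multiplier <- format_num(fitted_growth_multiplier)
    }),
    file.path(outdir, "engraftment.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  report$engraftment <- list(
    summary = engraft$summary,
    growth_multipliers = lapply(engraft$growth_fits, function(br_fits) {
      lapply(br_fits, function(f) f$estimate)
    }))
  log_lines <- pipeline_log(log_lines, "INFO", "engraft: ",
                            nrow(engraft$summary), " series classified")

  # --- diversity ------------------------------------------------------
  if (!is.null(config$feature_table)) {
    counts <- tryCatch(read_feature_table(config$feature_table),
                       error = function(e) stop_domain("[diversity] ",
                                                       conditionMessage(e)))
    taxonomy <- if (!is.null(config$taxonomy)) read_taxonomy(config$taxonomy)
    tree <- if (!is.null(config$tree)) read_newick(config$tree, counts)
    pattern <- if (is.null(config$probiotic_lineage_pattern)) {
      "g__(Lactobacillus|Lacticaseibacillus)"
    } else config$probiotic_lineage_pattern
    excl <- remove_probiotic_asvs(
      counts, target_asvs = as.character(config$probiotic_asvs %||% character()),
      taxonomy = taxonomy, lineage_pattern = pattern)
    log_lines <- pipeline_log(log_lines, "INFO", "diversity: removed ",
                              length(excl$removed),
                              " probiotic ASV(s) before alpha diversity")
    base <- if (is.null(config$shannon_base)) exp(1) else config$shannon_base
    alpha <- alpha_diversity(excl$counts, tree = tree, base = base)
    fmt_alpha <- alpha
    fmt_alpha$shannon <- format_num(fmt_alpha$shannon)
    if ("faith_pd" %in% names(fmt_alpha)) {
      fmt_alpha$faith_pd <- format_num(fmt_alpha$faith_pd)
    }
    utils::write.table(fmt_alpha, file.path(outdir, "alpha_diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$diversity <- list(alpha = alpha, removed_asvs = excl$removed)
    if (!is.null(taxonomy)) {
      fb_warn <- character()
      fb <- withCallingHandlers(
        fb_ratio(counts, taxonomy),
        warning = function(w) {
          fb_warn <<- c(fb_warn, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      for (w in fb_warn) log_lines <- pipeline_log(log_lines, "WARN", w)
      fb_fmt <- fb
      fb_fmt$firmicutes <- format_num(fb_fmt$firmicutes)
      fb_fmt$bacteroidetes <- format_num(fb_fmt$bacteroidetes)
      fb_fmt$fb_ratio <- format_num(fb_fmt$fb_ratio)
      utils::write.table(fb_fmt, file.path(outdir, "fb_ratio.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$diversity$fb_ratio <- fb
    }
  } else {
    log_lines <- pipeline_log(log_lines, "INFO",
                              "diversity: skipped (no feature table)")
  }

  # --- scfa -----------------------------------------------------------
  if (!is.null(config$scfa)) {
    scfa <- read_scfa_csv(config$scfa)
    report$scfa <- list()
    if (!is.null(config$metadata)) {
      meta <- read_metadata(config$metadata)
      long <- data.frame(
        sample = rep(rownames(scfa), times = ncol(scfa)),
        acid = rep(colnames(scfa), each = nrow(scfa)),
        value = as.vector(scfa), stringsAsFactors = FALSE)
      long <- merge(long, meta, by = "sample")
      sub <- long[long$period %in% c("pre", "late-post"), ]
      sub$group <- sub$period
      tests <- suppressWarnings(pairwise_scfa_tests(sub))
      report$scfa$pairwise <- list(n_tested = tests$n_tested,
                                   n_significant = tests$n_significant,
                                   method = tests$method,
                                   alpha = tests$alpha)
      fmt_tests <- tests$tests
      for (cn in c("mean_1", "mean_2", "t", "df", "p")) {
        fmt_tests[[cn]] <- format_num(fmt_tests[[cn]])
      }
      utils::write.table(fmt_tests, file.path(outdir, "scfa_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      log_lines <- pipeline_log(log_lines, "INFO", "scfa: ", tests$n_tested,
                                " stratum tests, ", tests$n_significant,
                                " significant at alpha=", tests$alpha)
    }
    if (!is.null(config$feature_table) && !is.null(config$taxonomy)) {
      genus <- aggregate_by_rank(read_feature_table(config$feature_table),
                                 read_taxonomy(config$taxonomy),
                                 rank = "genus")
      corr <- scfa_taxon_correlation(scfa, t(genus))
      fmt_corr <- corr
      fmt_corr$r <- format_num(fmt_corr$r)
      fmt_corr$p <- format_num(fmt_corr$p)
      utils::write.table(fmt_corr, file.path(outdir, "scfa_correlation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$scfa$n_correlations <- nrow(corr)
      report$scfa$n_significant_correlations <-
        sum(corr$stars != "", na.rm = TRUE)
    }
  } else {
    log_lines <- pipeline_log(log_lines, "INFO",
                              "scfa: skipped (no SCFA table)")
  }

  report$run <- list(package_version = as.character(
                       utils::packageVersion("gutwash")),
                     seed = seed, ordering = ordering,
                     window = window, factor = factor)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE,
                       na = "null")
  writeLines(log_lines, file.path(outdir, "run.log"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
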