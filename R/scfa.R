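# Short-chain fatty acid statistics: taxon correlations and stratified
# pre/post comparisons.

#' Default SCFA panel
#'
#' Linear and branched short-chain fatty acids measured by GC-MS.
#' @return Character vector of acid names.
#' @export
scfa_acids <- function() {
  c("acetic", "propanoic", "butanoic", "pentanoic", "hexanoic",
    "2-methylpropanoic", "3-methylbutanoic", "4-methylpentanoic")
}

#' Pearson correlation between SCFA concentrations and taxon abundances
#'
#' Product-moment correlation of each (taxon, acid) pair across shared
#' samples, with a two-sided p-value from the t distribution on n - 2
#' degrees of freedom and significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param scfa Numeric matrix, samples x acids (ppm).
#' @param taxa Numeric matrix, samples x taxa (relative abundances,
#'   e.g. genus level from [aggregate_by_rank()] transposed).
#' @param min_n Minimum paired samples per pair (default 3).
#'
#' @return Data frame: `taxon`, `acid`, `n`, `r`, `p`, `stars`. Pairs
#'   with zero variance in either variable are reported with `NA` r.
#' @export
scfa_taxon_correlation <- function(scfa, taxa, min_n = 3) {
  scfa <- as.matrix(scfa)
  taxa <- as.matrix(taxa)
  shared <- intersect(rownames(scfa), rownames(taxa))
  if (length(shared) < min_n) {
    stop_domain("need >= ", min_n, " shared samples; found ", length(shared))
  }
  scfa <- scfa[shared, , drop = FALSE]
  taxa <- taxa[shared, , drop = FALSE]
  grid <- expand.grid(taxon = colnames(taxa), acid = colnames(scfa),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- taxa[, grid$taxon[i]]
    y <- scfa[, grid$acid[i]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < min_n || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(data.frame(n = n, r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(n = n, r = unname(ct$estimate), p = ct$p.value)
  })
  out <- cbind(grid, do.call(rbind, res))
  out$stars <- ifelse(is.na(out$p), "",
               ifelse(out$p < 0.001, "***",
               ifelse(out$p < 0.01, "**",
               ifelse(out$p < 0.05, "*", ""))))
  out
}

#' Stratified pre/post comparisons of single SCFA concentrations
#'
#' Compares each stratum (typically bioreplicate x region x acid) between
#' two periods with a Welch unequal-variance two-sample t test, and
#' counts strata significant at `alpha`. No multiplicity correction is
#' applied; the raw significant count is the summary of interest.
#'
#' @param data Data frame with columns `value`, `group` (two levels,
#'   e.g. pre / late-post), and the stratification columns.
#' @param strata Character vector of column names defining strata
#'   (default `c("bioreplicate", "region", "acid")`).
#' @param alpha Significance level (default 0.05).
#'
#' @return A list: `tests` data frame (one row per testable stratum with
#'   group means, t, df, p, significant), `n_significant`, `n_tested`,
#'   `skipped` (strata with < 2 samples in either group), and the test
#'   metadata (`method`, `alpha`).
#' @export
pairwise_scfa_tests <- function(data,
                                strata = c("bioreplicate", "region", "acid"),
                                alpha = 0.05) {
  stopifnot(all(c("value", "group", strata) %in% names(data)))
  grp <- unique(as.character(data$group))
  if (length(grp) != 2) stop_domain("group must have exactly 2 levels")
  key <- interaction(data[strata], drop = TRUE, sep = ":")
  rows <- list()
  skipped <- character()
  for (k in levels(key)) {
    d <- data[key == k, ]
    x <- d$value[d$group == grp[1]]
    y <- d$value[d$group == grp[2]]
    if (length(x) < 2 || length(y) < 2) {
      skipped <- c(skipped, k)
      next
    }
    tt <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      # identical-variance-zero degenerate case: no evidence of difference
      list(statistic = if (mean(x) == mean(y)) 0 else Inf,
           parameter = NA_real_,
           p.value = if (mean(x) == mean(y)) 1 else 0)
    } else {
      stats::t.test(x, y, var.equal = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      stratum = k,
      mean_1 = mean(x), mean_2 = mean(y),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, significant = tt$p.value < alpha,
      stringsAsFactors = FALSE
    )
  }
  if (length(skipped) > 0) {
    warning("skipped ", length(skipped),
            " stratum/strata with < 2 samples per group")
  }
  tests <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(stratum = character(), mean_1 = numeric(),
               mean_2 = numeric(), t = numeric(), df = numeric(),
               p = numeric(), significant = logical())
  list(tests = tests,
       n_significant = sum(tests$significant),
       n_tested = nrow(tests),
       skipped = skipped,
       method = "Welch two-sample t (no multiplicity correction)",
       alpha = alpha)
}
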