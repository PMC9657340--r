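# Feature-table community metrics: probiotic-ASV exclusion, alpha
# diversity (Shannon, richness, Faith's PD), and group testing.
#
# Feature tables are plain integer matrices with ASV ids as row names and
# sample ids as column names, accompanied by a metadata data frame
# (sample, bioreplicate, region, period).

check_feature_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop_domain("feature table must be a numeric matrix (ASVs x samples)")
  }
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts))) {
    stop_domain("feature table must have unique ASV row names")
  }
  if (is.null(colnames(counts)) || anyDuplicated(colnames(counts))) {
    stop_domain("feature table must have unique sample column names")
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop_domain("feature table counts must be finite and >= 0")
  }
  invisible(counts)
}

#' Remove probiotic ASVs from a feature table
#'
#' Because an experimentally dosed organism would inflate diversity
#' metrics, its ASVs are removed from the feature table before alpha
#' diversity is computed. ASVs are selected by exact id and/or by a
#' lineage pattern matched against taxonomy strings (default targets the
#' dosed L. rhamnosus via its Lactobacillus/Lacticaseibacillus lineage).
#'
#' @param counts Feature-table matrix, ASVs x samples.
#' @param target_asvs Character vector of ASV ids to drop (may be empty).
#' @param taxonomy Optional named character vector (ASV id -> lineage
#'   string) used with `lineage_pattern`.
#' @param lineage_pattern Optional regular expression; ASVs whose lineage
#'   matches are also dropped.
#'
#' @return A list: `counts` (table with rows dropped), `removed` (ids
#'   dropped), `removed_reads` (reads removed per sample).
#' @export
remove_probiotic_asvs <- function(counts, target_asvs = character(),
                                  taxonomy = NULL, lineage_pattern = NULL) {
  check_feature_table(counts)
  target_asvs <- as.character(target_asvs)
  unknown <- setdiff(target_asvs, rownames(counts))
  if (length(unknown) > 0) {
    warning("ignoring unknown ASV id(s): ", paste(unknown, collapse = ", "))
  }
  drop <- intersect(target_asvs, rownames(counts))
  if (!is.null(taxonomy) && !is.null(lineage_pattern)) {
    hit <- names(taxonomy)[grepl(lineage_pattern, taxonomy)]
    drop <- union(drop, intersect(hit, rownames(counts)))
  }
  keep <- setdiff(rownames(counts), drop)
  removed_reads <- if (length(drop) > 0) {
    colSums(counts[drop, , drop = FALSE])
  } else {
    stats::setNames(numeric(ncol(counts)), colnames(counts))
  }
  list(counts = counts[keep, , drop = FALSE],
       removed = drop, removed_reads = removed_reads)
}

#' Shannon diversity of a count vector
#'
#' `H = -sum(p_i * log p_i)` over taxa with positive counts, where
#' `p_i = count_i / total`. Natural log (nats) by default.
#'
#' @param counts Non-negative count vector with at least one positive
#'   entry.
#' @param base Logarithm base (default `exp(1)`).
#'
#' @return Shannon index, in `[0, log(richness)]`.
#' @export
shannon <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stop_domain("counts must be >= 0")
  if (sum(counts) <= 0) {
    stop_domain("undefined diversity: count vector has no positive entries")
  }
  as.numeric(vegan::diversity(counts, index = "shannon", base = base))
}

#' Observed richness of a count vector
#'
#' @param counts Non-negative count vector.
#' @return Number of strictly positive entries.
#' @export
richness <- function(counts) {
  if (any(counts < 0)) stop_domain("counts must be >= 0")
  sum(counts > 0)
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree connecting the present
#' tips to the root (root-inclusive: each tip's path to the root is
#' included, the common convention).
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param present Character vector of tip labels present in the sample.
#' @param include_root Include root path (default `TRUE`); `FALSE` sums
#'   only branches within the subtree spanned by the present tips.
#'
#' @return Branch-length sum; 0 (with a warning) for an empty set.
#' @export
faith_pd <- function(tree, present, include_root = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (length(present) == 0) {
    warning("empty tip set: Faith's PD is 0")
    return(0)
  }
  unknown <- setdiff(present, tree$tip.label)
  if (length(unknown) > 0) {
    stop_domain("tip(s) not in tree: ", paste(unknown, collapse = ", "))
  }
  comm <- matrix(as.integer(tree$tip.label %in% present), nrow = 1,
                 dimnames = list("s", tree$tip.label))
  res <- picante::pd(comm, tree, include.root = include_root)
  as.numeric(res$PD)
}

#' Alpha-diversity table for every sample of a feature table
#'
#' @param counts Feature-table matrix, ASVs x samples.
#' @param tree Optional rooted `phylo` tree covering the ASVs; when
#'   supplied, Faith's PD is added.
#' @param base Log base for Shannon (default natural log).
#'
#' @return Data frame with one row per sample: `sample`, `depth` (reads;
#'   no rarefaction is applied, so depth is reported alongside),
#'   `shannon`, `richness`, and `faith_pd` when a tree is given.
#' @export
alpha_diversity <- function(counts, tree = NULL, base = exp(1)) {
  if (is.matrix(counts) && nrow(counts) == 0) {
    stop_domain("feature table has no ASVs")
  }
  check_feature_table(counts)
  empty <- colSums(counts) == 0
  if (any(empty)) {
    stop_domain("sample(s) with zero total counts: ",
                paste(colnames(counts)[empty], collapse = ", "))
  }
  out <- data.frame(
    sample = colnames(counts),
    depth = colSums(counts),
    shannon = apply(counts, 2, shannon, base = base),
    richness = apply(counts, 2, richness),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(tree)) {
    missing_tips <- setdiff(rownames(counts), tree$tip.label)
    if (length(missing_tips) > 0) {
      stop_domain("ASV(s) missing from tree: ",
                  paste(utils::head(missing_tips, 5), collapse = ", "))
    }
    out$faith_pd <- vapply(seq_len(ncol(counts)), function(j) {
      faith_pd(tree, rownames(counts)[counts[, j] > 0])
    }, numeric(1))
  }
  out
}

#' One-way ANOVA with Tukey-Kramer pairwise comparisons
#'
#' Tests whether a per-sample metric differs among groups: one-way
#' analysis of variance for the overall effect, followed by Tukey's
#' honestly-significant-difference pairwise comparisons (studentized
#' range, Tukey-Kramer for unbalanced groups).
#'
#' @param values Numeric per-sample metric.
#' @param groups Group labels, same length.
#'
#' @return A list: `f` statistic, `df` (between, within), `p` overall,
#'   and `pairwise` data frame (comparison, diff, adjusted p).
#' @export
alpha_group_test <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (length(values) != length(groups)) {
    stop_domain("values and groups must have equal length")
  }
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warning("excluding group(s) with < 2 samples: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop_domain("need >= 2 groups with >= 2 samples")
  dat <- data.frame(y = values, g = groups)
  fit <- stats::aov(y ~ g, data = dat)
  # degenerate fits are caught below; muffle base R's perfect-fit warning
  an <- suppressWarnings(stats::anova(fit))
  if (!is.finite(an[["F value"]][1])) {
    stop_domain("degenerate ANOVA: zero within-group variance everywhere")
  }
  tk <- stats::TukeyHSD(fit)$g
  list(
    f = an[["F value"]][1],
    df = c(between = an[["Df"]][1], within = an[["Df"]][2]),
    p = an[["Pr(>F)"]][1],
    pairwise = data.frame(comparison = rownames(tk),
                          diff = tk[, "diff"],
                          p_adj = tk[, "p adj"],
                          row.names = NULL, stringsAsFactors = FALSE)
  )
}
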