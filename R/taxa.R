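# Greengenes-style lineage handling: rank aggregation and the
# Firmicutes/Bacteroidetes ratio.

gg_ranks <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
              family = "f", genus = "g", species = "s")

#' Parse Greengenes-style lineage strings
#'
#' Splits strings like `"k__Bacteria; p__Firmicutes; g__Blautia"` into
#' named rank components. Empty ranks (`"g__"`) and missing ranks are
#' tolerated and reported as `NA`.
#'
#' @param lineages Character vector of lineage strings.
#' @return Data frame with columns kingdom..species (character, `NA`
#'   where unassigned), one row per input.
#' @export
parse_lineage <- function(lineages) {
  out <- matrix(NA_character_, nrow = length(lineages),
                ncol = length(gg_ranks),
                dimnames = list(NULL, names(gg_ranks)))
  for (i in seq_along(lineages)) {
    parts <- trimws(strsplit(lineages[i], ";", fixed = TRUE)[[1]])
    for (p in parts) {
      m <- regmatches(p, regexec("^([kpcofgs])__(.*)$", p))[[1]]
      if (length(m) == 3) {
        rank <- names(gg_ranks)[match(m[2], gg_ranks)]
        if (!is.na(rank) && nzchar(m[3])) out[i, rank] <- m[3]
      }
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Aggregate a feature table to a taxonomic rank
#'
#' Sums ASV counts per lineage at the requested rank (ASVs without an
#' assignment at that rank pool into `"unclassified"`), then normalizes
#' each sample to relative abundances summing to 1.
#'
#' @param counts Feature-table matrix, ASVs x samples.
#' @param taxonomy Named character vector, ASV id -> lineage string.
#' @param rank One of kingdom, phylum, class, order, family, genus,
#'   species.
#' @param relative Normalize columns to proportions (default `TRUE`);
#'   `FALSE` returns summed counts.
#'
#' @return Matrix, taxa at `rank` x samples.
#' @export
aggregate_by_rank <- function(counts, taxonomy, rank = "phylum",
                              relative = TRUE) {
  check_feature_table(counts)
  rank <- match.arg(rank, names(gg_ranks))
  empty <- colSums(counts) == 0
  if (any(empty)) {
    stop_domain("cannot aggregate sample(s) with zero counts: ",
                paste(colnames(counts)[empty], collapse = ", "))
  }
  lin <- parse_lineage(taxonomy[rownames(counts)])
  labels <- lin[[rank]]
  labels[is.na(labels)] <- "unclassified"
  agg <- rowsum(counts, group = labels)
  if (relative) agg <- sweep(agg, 2, colSums(agg), "/")
  agg
}

#' Firmicutes/Bacteroidetes ratio per sample
#'
#' Ratio of the two dominant phyla's relative abundances, a coarse
#' community descriptor. Depth-invariant by construction (ratio of
#' proportions).
#'
#' @inheritParams aggregate_by_rank
#' @param firmicutes,bacteroidetes Phylum labels to use.
#'
#' @return Data frame: `sample`, `firmicutes`, `bacteroidetes`
#'   (proportions), `fb_ratio` (`Inf` flagged when Bacteroidetes is
#'   absent, `NaN` when both are).
#' @export
fb_ratio <- function(counts, taxonomy, firmicutes = "Firmicutes",
                     bacteroidetes = "Bacteroidetes") {
  phyl <- aggregate_by_rank(counts, taxonomy, rank = "phylum")
  f <- if (firmicutes %in% rownames(phyl)) phyl[firmicutes, ] else
    numeric(ncol(phyl))
  b <- if (bacteroidetes %in% rownames(phyl)) phyl[bacteroidetes, ] else
    numeric(ncol(phyl))
  ratio <- ifelse(b > 0, f / b, ifelse(f > 0, Inf, NaN))
  if (any(b == 0)) {
    warning("Bacteroidetes absent in ", sum(b == 0),
            " sample(s): ratio flagged Inf/NaN")
  }
  data.frame(sample = colnames(phyl), firmicutes = as.numeric(f),
             bacteroidetes = as.numeric(b), fb_ratio = as.numeric(ratio),
             stringsAsFactors = FALSE, row.names = NULL)
}
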