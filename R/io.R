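# Readers and writers for the interchange formats: feature-table TSV,
# two-column taxonomy TSV, newick trees, qPCR and SCFA CSVs, sample
# metadata TSV, and YAML run configuration. Writers serialize numbers
# with 12 significant digits so write -> read round-trips are stable.

#' Read an ASV feature table from TSV
#'
#' Expects a header row of sample ids with the first column holding ASV
#' ids, and non-negative integer counts.
#'
#' @param path File path.
#' @return Integer matrix, ASVs x samples.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "")
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    stop_domain("empty or malformed feature table: ", path)
  }
  asv <- raw[[1]]
  if (anyDuplicated(asv)) {
    stop_domain("duplicate ASV id(s): ",
                paste(unique(asv[duplicated(asv)]), collapse = ", "))
  }
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples)) {
    stop_domain("duplicate sample column(s): ",
                paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  mat <- matrix(0L, nrow = length(asv), ncol = length(samples),
                dimnames = list(asv, samples))
  for (j in seq_along(samples)) {
    col <- raw[[j + 1L]]
    val <- suppressWarnings(as.numeric(col))
    bad <- which(!is.finite(val) | val < 0 | val != round(val))
    if (length(bad) > 0) {
      stop_domain("malformed count at row ", bad[1], " (ASV '", asv[bad[1]],
                  "'), column '", samples[j], "': '", col[bad[1]], "'")
    }
    mat[, j] <- as.integer(val)
  }
  mat
}

#' Write an ASV feature table to TSV
#'
#' @param counts Matrix, ASVs x samples.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(counts, path) {
  check_feature_table(counts)
  df <- data.frame(asv_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column taxonomy TSV (ASV id, lineage)
#'
#' @param path File path.
#' @return Named character vector, ASV id -> lineage string.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (ncol(raw) < 2) stop_domain("taxonomy file needs 2 columns: ", path)
  stats::setNames(as.character(raw[[2]]), as.character(raw[[1]]))
}

#' Write a taxonomy map to TSV
#'
#' @param taxonomy Named character vector, ASV id -> lineage.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(
    data.frame(asv_id = names(taxonomy), lineage = unname(taxonomy)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted newick tree
#'
#' Wraps `ape::read.tree` with validation: the tree must parse, be
#' rooted, and have unique tip labels. Missing branch lengths default to
#' 0 with a warning. When a feature table is supplied, tips absent from
#' it are reported.
#'
#' @param path File path.
#' @param counts Optional feature-table matrix for tip validation.
#' @return A `phylo` tree.
#' @export
read_newick <- function(path, counts = NULL) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) NULL)
  if (is.null(tree)) stop_domain("could not parse newick file: ", path)
  if (anyDuplicated(tree$tip.label)) {
    stop_domain("duplicate tip labels in tree: ", path)
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (!ape::is.rooted(tree)) stop_domain("tree is not rooted: ", path)
  if (!is.null(counts)) {
    extra <- setdiff(tree$tip.label, rownames(counts))
    if (length(extra) > 0) {
      warning("tree tip(s) absent from feature table: ",
              paste(utils::head(extra, 10), collapse = ", "))
    }
  }
  tree
}

#' Read a qPCR concentration CSV into a list of series
#'
#' Expects columns `sample_id`, `bioreplicate`, `compartment`, `phase`,
#' `cycle`, and one of `cells_per_ml`, `copies`, or `dna_mass_ng` (the
#' first present is used; mass is converted to copies via
#' [copies_from_mass()], copies are taken as cells one-to-one).
#'
#' @param path File path.
#' @param genome [genome_model()] used for mass conversion.
#' @param dose_cycle Cycle of the dose (default 0).
#' @return Named list of [qpcr_series()], keyed
#'   `bioreplicate.compartment.phase`.
#' @export
read_qpcr_csv <- function(path, genome = genome_model(), dose_cycle = 0) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bioreplicate", "compartment", "phase", "cycle")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_domain("qPCR file missing column(s): ", paste(miss, collapse = ", "))
  }
  if ("cells_per_ml" %in% names(df)) {
    df$value <- df$cells_per_ml
  } else if ("copies" %in% names(df)) {
    df$value <- df$copies
  } else if ("dna_mass_ng" %in% names(df)) {
    df$value <- copies_from_mass(df$dna_mass_ng, genome)
  } else {
    stop_domain("qPCR file needs cells_per_ml, copies or dna_mass_ng")
  }
  key <- interaction(df$bioreplicate, df$compartment, df$phase, drop = TRUE)
  out <- list()
  for (k in levels(key)) {
    d <- df[key == k, ]
    d <- d[order(d$cycle), ]
    out[[k]] <- qpcr_series(d$cycle, d$value,
                            bioreplicate = d$bioreplicate[1],
                            compartment = d$compartment[1],
                            phase = d$phase[1], dose_cycle = dose_cycle)
  }
  out
}

#' Write qPCR series to CSV
#'
#' @param series_list List of [qpcr_series()].
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_qpcr_csv <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    data.frame(
      sample_id = sprintf("%s_%s_%s_c%d", s$bioreplicate, s$compartment,
                          s$phase, s$cycles),
      bioreplicate = s$bioreplicate, compartment = s$compartment,
      phase = s$phase, cycle = s$cycles,
      cells_per_ml = format_num(s$cells_per_ml),
      stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an SCFA concentration CSV
#'
#' Long format: columns `sample`, `acid`, `concentration_ppm`.
#'
#' @param path File path.
#' @return Matrix, samples x acids (ppm).
#' @export
read_scfa_csv <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample", "acid", "concentration_ppm")
  if (!all(need %in% names(df))) {
    stop_domain("SCFA file needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$concentration_ppm < 0)) {
    stop_domain("negative SCFA concentration in ", path)
  }
  samples <- unique(df$sample)
  acids <- unique(df$acid)
  mat <- matrix(NA_real_, length(samples), length(acids),
                dimnames = list(samples, acids))
  mat[cbind(match(df$sample, samples), match(df$acid, acids))] <-
    df$concentration_ppm
  mat
}

#' Write an SCFA concentration matrix to long CSV
#'
#' @param concentrations Matrix, samples x acids.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_scfa_csv <- function(concentrations, path) {
  df <- data.frame(
    sample = rep(rownames(concentrations), times = ncol(concentrations)),
    acid = rep(colnames(concentrations), each = nrow(concentrations)),
    concentration_ppm = format_num(as.vector(concentrations)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata TSV (sample, bioreplicate, region, period)
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("sample", "bioreplicate", "region", "period")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_domain("metadata missing column(s): ", paste(miss, collapse = ", "))
  }
  df
}

#' Write a trajectory to long-format TSV
#'
#' Columns: cycle, compartment, concentration_cells_per_ml,
#' cumulative_waste_cells.
#'
#' @param trajectory A `gw_trajectory`.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  df$concentration_cells_per_ml <- format_num(df$concentration_cells_per_ml)
  df$cumulative_waste_cells <- format_num(df$cumulative_waste_cells)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

run_config_keys <- c("qpcr", "feature_table", "taxonomy", "tree", "scfa",
                     "metadata", "compartments", "transfer_volume_ml",
                     "cycles_per_day", "n_cycles", "dose",
                     "growth_multipliers", "transit_ordering", "window",
                     "factor", "shannon_base", "probiotic_asvs",
                     "probiotic_lineage_pattern", "seed", "outdir")

#' Read a YAML run configuration
#'
#' Recognized keys: input paths (`qpcr`, `feature_table`, `taxonomy`,
#' `tree`, `scfa`, `metadata`), reactor geometry (`compartments` as a
#' list of `name`/`volume_ml`, `transfer_volume_ml`, `cycles_per_day`,
#' `n_cycles`, `dose` with `compartment`/`cycle`/`total_cells`,
#' `growth_multipliers`, `transit_ordering`), analysis options
#' (`window`, `factor`, `shannon_base`, `probiotic_asvs`,
#' `probiotic_lineage_pattern`), `seed`, and `outdir`. Unknown keys are
#' rejected with a message.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_domain("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown) > 0) {
    stop_domain("unknown config key(s): ", paste(unknown, collapse = ", "),
                "; recognized: ", paste(run_config_keys, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

config_chain <- function(cfg) {
  comp <- cfg$compartments
  if (is.null(comp)) {
    return(reactor_chain(c(AC = 500, TC = 800, DC = 600)))
  }
  vols <- vapply(comp, function(x) config_num(x$volume_ml, "volume_ml"),
                 numeric(1))
  names(vols) <- vapply(comp, function(x) as.character(x$name), character(1))
  reactor_chain(vols)
}

config_schedule <- function(cfg) {
  feeding_schedule(
    transfer_volume = if (is.null(cfg$transfer_volume_ml)) 140 else
      config_num(cfg$transfer_volume_ml, "transfer_volume_ml"),
    cycles_per_day = if (is.null(cfg$cycles_per_day)) 3 else
      config_num(cfg$cycles_per_day, "cycles_per_day"))
}

# YAML 1.1 parses exponent notation without a sign ("2.5e10") as a
# string; coerce scalars defensively.
config_num <- function(x, key) {
  v <- suppressWarnings(as.numeric(x))
  if (length(v) != 1L || is.na(v)) {
    stop_domain("config key '", key, "' is not a number: '", x, "'")
  }
  v
}

config_dose <- function(cfg) {
  d <- cfg$dose
  if (is.null(d)) stop_domain("config must supply a dose block")
  dose_event(d$compartment, config_num(d$total_cells, "dose.total_cells"),
             if (is.null(d$cycle)) 0 else config_num(d$cycle, "dose.cycle"))
}
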