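# Seeded synthetic-data generators emulating the data shapes the
# pipeline consumes: tracked-cell qPCR trajectories from the washout
# model plus multiplicative noise, overdispersed ASV feature tables with
# region/bioreplicate structure and a spiked probiotic ASV, random
# rooted trees, and SCFA tables increasing along the chain.

#' Configuration for the synthetic-data generators
#'
#' Defaults describe a paper-like scenario: three bioreplicates, a
#' three-compartment AC/TC/DC chain fed three times daily, a single
#' probiotic dose into the AC giving ~5e7 cells/mL, net growth in the AC
#' (1.2 per cycle) and net loss in TC/DC (0.9), endogenous baselines in
#' the 1.3e3 to 8e4 cells/mL range, multiplicative lognormal qPCR noise
#' (sd 0.1 on the log scale), Dirichlet-multinomial feature tables with a
#' less-even AC community, and SCFA means increasing along AC < TC < DC.
#'
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param volumes Named compartment working volumes, mL.
#' @param transfer_volume Transfer volume per cycle, mL.
#' @param cycles_per_day Feeding cycles per day.
#' @param n_cycles Post-dose feeding cycles simulated.
#' @param n_pre_cycles Pre-dose cycles reported at baseline level.
#' @param dose_compartment,dose_cells Dose target and total cells.
#' @param growth Named per-compartment net per-cycle multipliers.
#' @param qpcr_noise_sd SD of lognormal noise on log concentrations.
#' @param baseline_range Range (cells/mL) endogenous baselines are drawn
#'   from (log-uniform), per bioreplicate x compartment.
#' @param bioreplicates Bioreplicate labels.
#' @param n_taxa Number of ASVs in generated feature tables (>= 5).
#' @param depth Sequencing depth per sample (multinomial total).
#' @param dirichlet_conc Named per-region Dirichlet concentration
#'   parameters (smaller = less even = less diverse).
#' @param spike_weight Relative-abundance weight of the probiotic ASV
#'   spiked into post-dose samples of the dosed compartment.
#' @param phylum_probs Named phylum assignment probabilities.
#' @param samples_per_group Samples per bioreplicate x region x period.
#' @param scfa_region_factor Named per-region multipliers applied to the
#'   per-acid base means (must be non-decreasing along the chain).
#' @param scfa_base_means Named per-acid base concentrations, ppm.
#' @param scfa_noise_sd SD of lognormal noise on SCFA concentrations.
#' @param scfa_postdose_bump Multiplier applied to early-post samples
#'   (1 = none).
#'
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 20221026,
                         volumes = c(AC = 500, TC = 800, DC = 600),
                         transfer_volume = 140,
                         cycles_per_day = 3,
                         n_cycles = 31,
                         n_pre_cycles = 3,
                         dose_compartment = "AC",
                         dose_cells = 2.5e10,
                         growth = c(AC = 1.2, TC = 0.9, DC = 0.9),
                         qpcr_noise_sd = 0.1,
                         baseline_range = c(1.3e3, 8e4),
                         bioreplicates = c("BR1", "BR2", "BR3"),
                         n_taxa = 60,
                         depth = 10000,
                         dirichlet_conc = c(AC = 0.1, TC = 1, DC = 1),
                         spike_weight = 0.05,
                         phylum_probs = c(Firmicutes = 0.45,
                                          Bacteroidetes = 0.35,
                                          Proteobacteria = 0.08,
                                          Actinobacteria = 0.05,
                                          Fusobacteria = 0.04,
                                          Verrucomicrobia = 0.03),
                         samples_per_group = 2,
                         scfa_region_factor = c(AC = 1, TC = 1.35, DC = 1.7),
                         scfa_base_means = c("acetic" = 800,
                                             "propanoic" = 300,
                                             "butanoic" = 250,
                                             "pentanoic" = 60,
                                             "hexanoic" = 20,
                                             "2-methylpropanoic" = 30,
                                             "3-methylbutanoic" = 40,
                                             "4-methylpentanoic" = 10),
                         scfa_noise_sd = 0.15,
                         scfa_postdose_bump = 1) {
  stopifnot(qpcr_noise_sd >= 0, scfa_noise_sd >= 0, depth >= 1,
            n_taxa >= 5, all(scfa_base_means >= 0))
  cfg <- as.list(environment())
  cfg$regions <- names(volumes)
  class(cfg) <- "synth_config"
  cfg
}

synth_chain <- function(cfg) reactor_chain(cfg$volumes)
synth_schedule <- function(cfg) {
  feeding_schedule(cfg$transfer_volume, cfg$cycles_per_day, 0)
}
synth_dose <- function(cfg) dose_event(cfg$dose_compartment, cfg$dose_cells)

#' Generate synthetic qPCR trajectories
#'
#' Truth = growth-extended washout model plus a constant endogenous
#' baseline; observed = truth times `exp(N(0, qpcr_noise_sd))` per point.
#' Pre-dose cycles are included at the baseline level. Both truth and
#' observed are returned so recovery tests can compare against the
#' generating model.
#'
#' @param cfg A [synth_config()].
#' @return List with one element per bioreplicate x compartment:
#'   `series` (a [qpcr_series()] of observed values), `truth` (noise-free
#'   values), `baseline`, and the generating parameters.
#' @export
gen_qpcr_trajectory <- function(cfg = synth_config()) {
  chain <- synth_chain(cfg)
  tr <- simulate_with_growth(chain, synth_schedule(cfg), synth_dose(cfg),
                             cfg$growth[chain$names], cfg$n_cycles)
  cycles <- seq.int(-cfg$n_pre_cycles, cfg$n_cycles)
  with_local_seed(cfg$seed, {
    out <- list()
    for (br in cfg$bioreplicates) {
      for (comp in chain$names) {
        baseline <- if (cfg$baseline_range[2] <= 0) 0 else
          exp(stats::runif(1, log(cfg$baseline_range[1]),
                           log(cfg$baseline_range[2])))
        model <- unname(tr$concentrations[comp, ])
        truth <- c(rep(baseline, cfg$n_pre_cycles), model + baseline)
        noise <- exp(stats::rnorm(length(truth), 0, cfg$qpcr_noise_sd))
        observed <- truth * noise
        key <- paste(br, comp, sep = ".")
        out[[key]] <- list(
          series = qpcr_series(cycles, observed, bioreplicate = br,
                               compartment = comp, phase = "lumen",
                               dose_cycle = 0, baseline = baseline),
          truth = truth, baseline = baseline,
          growth = unname(cfg$growth[comp])
        )
      }
    }
    out
  })
}

# Dirichlet sampler via normalized gammas.
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Generate a synthetic ASV feature table with taxonomy and metadata
#'
#' Per-sample compositions are Dirichlet draws around a
#' bioreplicate-specific mean, with a region-specific concentration
#' parameter (smaller in the AC, making it less even and less diverse);
#' counts are multinomial at the configured depth (Dirichlet-multinomial
#' overdispersion). One designated probiotic ASV is spiked into
#' post-dose samples of the dosed compartment. Lineages are assigned with
#' a Firmicutes + Bacteroidetes majority.
#'
#' @param cfg A [synth_config()].
#' @return List: `counts` (ASV x sample matrix), `taxonomy` (named
#'   lineage vector), `metadata` (sample, bioreplicate, region, period),
#'   `probiotic_asv` (the spiked ASV id).
#' @export
gen_feature_table <- function(cfg = synth_config()) {
  taxa <- sprintf("ASV%03d", seq_len(cfg$n_taxa))
  probiotic <- "ASV_LGG"
  periods <- c("pre", "early-post", "late-post")
  meta <- expand.grid(replicate = seq_len(cfg$samples_per_group),
                      period = periods, region = cfg$regions,
                      bioreplicate = cfg$bioreplicates,
                      stringsAsFactors = FALSE)
  meta$sample <- sprintf("%s_%s_%s_r%d", meta$bioreplicate, meta$region,
                         meta$period, meta$replicate)
  with_local_seed(cfg$seed + 1L, {
    phyla <- sample(names(cfg$phylum_probs), cfg$n_taxa, replace = TRUE,
                    prob = cfg$phylum_probs)
    genera <- sprintf("Genus%03d", seq_len(cfg$n_taxa))
    taxonomy <- stats::setNames(sprintf(
      "k__Bacteria; p__%s; c__; o__; f__; g__%s", phyla, genera), taxa)
    taxonomy[probiotic] <-
      paste0("k__Bacteria; p__Firmicutes; c__Bacilli; o__Lactobacillales; ",
             "f__Lactobacillaceae; g__Lacticaseibacillus; s__rhamnosus")
    base_mean <- lapply(cfg$bioreplicates, function(br) rdirichlet1(rep(2, cfg$n_taxa)))
    names(base_mean) <- cfg$bioreplicates
    counts <- matrix(0L, nrow = cfg$n_taxa + 1L, ncol = nrow(meta),
                     dimnames = list(c(taxa, probiotic), meta$sample))
    for (j in seq_len(nrow(meta))) {
      conc <- cfg$dirichlet_conc[[meta$region[j]]]
      p <- rdirichlet1(conc * cfg$n_taxa * base_mean[[meta$bioreplicate[j]]])
      spike <- if (meta$period[j] != "pre" &&
                   meta$region[j] == cfg$dose_compartment) {
        cfg$spike_weight
      } else 0
      p_full <- c(p * (1 - spike), spike)
      counts[, j] <- stats::rmultinom(1, cfg$depth, p_full)[, 1]
    }
    list(counts = counts, taxonomy = taxonomy,
         metadata = meta[, c("sample", "bioreplicate", "region", "period")],
         probiotic_asv = probiotic)
  })
}

#' Generate a random rooted binary tree over taxon ids
#'
#' Topology is uniform-random (via `ape::rtree`), branch lengths are
#' exponential with the given mean; output is deterministic for a fixed
#' seed.
#'
#' @param taxa Character vector of tip ids (>= 2).
#' @param seed Integer seed.
#' @param mean_branch Mean exponential branch length.
#' @return A rooted binary `phylo` tree with `length(taxa)` tips.
#' @export
gen_tree <- function(taxa, seed = 20221026, mean_branch = 0.1) {
  if (length(taxa) < 2) stop_domain("need >= 2 taxa to build a tree")
  with_local_seed(seed, {
    ape::rtree(length(taxa), rooted = TRUE, tip.label = taxa,
               br = function(n) stats::rexp(n, rate = 1 / mean_branch))
  })
}

#' Generate a synthetic SCFA concentration table
#'
#' Concentration of each acid = per-acid base mean x region factor x
#' lognormal noise, with region factors non-decreasing along the chain so
#' concentrations increase from AC to TC to DC. An optional bump
#' multiplies early-post samples to emulate a transient post-dose rise.
#'
#' @param cfg A [synth_config()].
#' @param metadata Optional sample metadata (as from
#'   [gen_feature_table()]); generated from `cfg` if omitted.
#' @return List: `concentrations` (sample x acid matrix, ppm),
#'   `metadata`.
#' @export
gen_scfa <- function(cfg = synth_config(), metadata = NULL) {
  if (any(diff(cfg$scfa_region_factor[cfg$regions]) < 0)) {
    stop_domain("scfa_region_factor must be non-decreasing along the chain")
  }
  if (is.null(metadata)) metadata <- gen_feature_table(cfg)$metadata
  acids <- names(cfg$scfa_base_means)
  with_local_seed(cfg$seed + 2L, {
    conc <- matrix(0, nrow = nrow(metadata), ncol = length(acids),
                   dimnames = list(metadata$sample, acids))
    for (i in seq_len(nrow(metadata))) {
      mu <- cfg$scfa_base_means * cfg$scfa_region_factor[[metadata$region[i]]]
      if (metadata$period[i] == "early-post") mu <- mu * cfg$scfa_postdose_bump
      conc[i, ] <- mu * exp(stats::rnorm(length(acids), 0, cfg$scfa_noise_sd))
    }
    list(concentrations = conc, metadata = metadata)
  })
}

#' Write a full set of synthetic fixtures to disk
#'
#' Generates qPCR, feature-table, taxonomy, tree, SCFA and metadata files
#' in the interchange formats the readers expect.
#'
#' @param cfg A [synth_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_synth_fixtures <- function(cfg = synth_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(qpcr = file.path(outdir, "qpcr.csv"),
             table = file.path(outdir, "table.tsv"),
             tax = file.path(outdir, "tax.tsv"),
             tree = file.path(outdir, "tree.nwk"),
             scfa = file.path(outdir, "scfa.csv"),
             meta = file.path(outdir, "meta.tsv"))
  qp <- gen_qpcr_trajectory(cfg)
  write_qpcr_csv(lapply(qp, `[[`, "series"), paths["qpcr"])
  ft <- gen_feature_table(cfg)
  write_feature_table(ft$counts, paths["table"])
  write_taxonomy(ft$taxonomy, paths["tax"])
  tree <- gen_tree(rownames(ft$counts), seed = cfg$seed + 3L)
  ape::write.tree(tree, file = paths["tree"])
  sc <- gen_scfa(cfg, ft$metadata)
  write_scfa_csv(sc$concentrations, paths["scfa"])
  utils::write.table(ft$metadata, paths["meta"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
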