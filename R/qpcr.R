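# Absolute quantification of strain-specific qPCR measurements and
# baseline handling for time series of tracked-organism concentrations.

#' Genome model for copy-number conversion
#'
#' Constants used to convert a DNA mass into genome copies. Defaults are
#' for the L. rhamnosus GG chromosome: 3,010,111 bp, a mean molar mass of
#' 660 g/mol per base pair, and Avogadro's number 6.0221e23.
#'
#' @param genome_length_bp Genome length in base pairs.
#' @param mean_bp_mass Mean molar mass per base pair, g/mol.
#' @param avogadro Molecules per mole.
#'
#' @return A `genome_model` object.
#' @export
genome_model <- function(genome_length_bp = 3010111,
                         mean_bp_mass = 660,
                         avogadro = 6.0221e23) {
  check_number(genome_length_bp, "genome_length_bp", 0, allow_zero = FALSE)
  check_number(mean_bp_mass, "mean_bp_mass", 0, allow_zero = FALSE)
  check_number(avogadro, "avogadro", 0, allow_zero = FALSE)
  structure(list(genome_length_bp = genome_length_bp,
                 mean_bp_mass = mean_bp_mass,
                 avogadro = avogadro),
            class = "genome_model")
}

#' Convert DNA mass to genome copies
#'
#' Copies = `mass_ng * avogadro / (genome_length_bp * mean_bp_mass * 1e9)`,
#' i.e. the mass in grams divided by the mass of one genome
#' (about 3.30 fg for the default constants). Linear in `mass_ng`;
#' vectorized.
#'
#' @param mass_ng DNA mass in nanograms (vector allowed), >= 0.
#' @param genome A [genome_model()].
#'
#' @return Genome copy numbers, same length as `mass_ng`. One copy is
#'   interpreted as one cell (single chromosomal qPCR target).
#' @examples
#' copies_from_mass(1) # about 3.031e5 copies per ng
#' @export
copies_from_mass <- function(mass_ng, genome = genome_model()) {
  if (!is.numeric(mass_ng) || any(!is.finite(mass_ng))) {
    stop_domain("mass_ng must be finite numeric")
  }
  if (any(mass_ng < 0)) stop_domain("mass_ng must be >= 0")
  mass_ng * genome$avogadro /
    (genome$genome_length_bp * genome$mean_bp_mass * 1e9)
}

#' Mass of a single genome in femtograms
#'
#' Convenience inverse of [copies_from_mass()]: `genome_length_bp *
#' mean_bp_mass / avogadro`, in fg.
#'
#' @inheritParams copies_from_mass
#' @return Single-genome mass in femtograms.
#' @export
genome_mass_fg <- function(genome = genome_model()) {
  genome$genome_length_bp * genome$mean_bp_mass / genome$avogadro * 1e15
}

#' Construct a qPCR concentration time series
#'
#' One series holds the tracked-organism concentrations for a single
#' (bioreplicate, compartment, phase) combination across feeding cycles.
#' Cycles are integers with the dose at cycle 0; negative cycles are
#' pre-dose.
#'
#' @param cycles Integer feeding-cycle indices, strictly increasing.
#' @param cells_per_ml Concentrations, cells/mL, same length as `cycles`.
#' @param bioreplicate,compartment Labels.
#' @param phase `"lumen"` or `"mucin"`.
#' @param dose_cycle Cycle at which the dose was given (default 0);
#'   samples with `cycle < dose_cycle` are pre-dose.
#' @param baseline Optional endogenous pre-dose level, cells/mL; if `NA`
#'   it can be estimated with [estimate_baseline()].
#'
#' @return A `qpcr_series` object.
#' @export
qpcr_series <- function(cycles, cells_per_ml, bioreplicate = "BR1",
                        compartment = "AC", phase = c("lumen", "mucin"),
                        dose_cycle = 0, baseline = NA_real_) {
  phase <- match.arg(phase)
  cycles <- as.integer(cycles)
  if (length(cycles) != length(cells_per_ml)) {
    stop_domain("cycles and cells_per_ml must have equal length")
  }
  if (is.unsorted(cycles, strictly = TRUE)) {
    stop_domain("cycles must be strictly increasing")
  }
  if (any(!is.finite(cells_per_ml)) || any(cells_per_ml < 0)) {
    stop_domain("cells_per_ml must be finite and >= 0")
  }
  if (!is.na(baseline)) check_number(baseline, "baseline", 0)
  structure(
    list(cycles = cycles, cells_per_ml = as.numeric(cells_per_ml),
         bioreplicate = bioreplicate, compartment = compartment,
         phase = phase, dose_cycle = as.integer(dose_cycle),
         baseline = baseline, n_clamped = 0L, baseline_subtracted = FALSE),
    class = "qpcr_series"
  )
}

#' @export
print.qpcr_series <- function(x, ...) {
  cat("<qpcr_series> ", x$bioreplicate, "/", x$compartment, "/", x$phase,
      ", ", length(x$cycles), " samples, cycles ", min(x$cycles), "..",
      max(x$cycles), sep = "")
  if (!is.na(x$baseline)) cat(", baseline ", signif(x$baseline, 4), " cells/mL",
                              sep = "")
  if (x$baseline_subtracted) cat(" [baseline-subtracted]")
  cat("\n")
  invisible(x)
}

#' Estimate the endogenous pre-dose baseline of a series
#'
#' The endogenous concentration of the tracked organism before dosing is
#' summarized over all pre-dose samples (`cycle < dose_cycle`) and later
#' subtracted from post-dose measurements.
#'
#' @param series A [qpcr_series()].
#' @param method `"mean"` (default) or `"median"` of the pre-dose values.
#'
#' @return The series with its `baseline` field set.
#' @export
estimate_baseline <- function(series, method = c("mean", "median")) {
  method <- match.arg(method)
  stopifnot(inherits(series, "qpcr_series"))
  pre <- series$cells_per_ml[series$cycles < series$dose_cycle]
  if (length(pre) == 0L) {
    stop_domain("baseline unavailable: series has no pre-dose samples ",
                "(supply baseline = 0 explicitly if none exist)")
  }
  series$baseline <- if (method == "mean") mean(pre) else stats::median(pre)
  series
}

#' Subtract the endogenous baseline from post-dose measurements
#'
#' Each post-dose concentration is replaced by
#' `max(0, value - baseline)`; pre-dose samples are untouched. Values
#' clamped at zero (measurement below baseline) are counted in the
#' returned series' `n_clamped` field, since true abundance cannot be
#' negative.
#'
#' @param series A [qpcr_series()] with `baseline` set (possibly via
#'   [estimate_baseline()]).
#'
#' @return The adjusted series.
#' @export
baseline_subtract <- function(series) {
  stopifnot(inherits(series, "qpcr_series"))
  if (is.na(series$baseline)) {
    stop_domain("series baseline is not set; call estimate_baseline() first")
  }
  post <- series$cycles >= series$dose_cycle
  adj <- series$cells_per_ml[post] - series$baseline
  series$n_clamped <- series$n_clamped + sum(adj < 0)
  series$cells_per_ml[post] <- pmax(0, adj)
  series$baseline_subtracted <- TRUE
  series
}
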