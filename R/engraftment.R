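# Engraftment inference: compare measured tracked-cell trajectories to
# the no-growth washout prediction, summarize fold changes, fit net
# growth multipliers, and classify per-compartment outcomes.

#' Fold change of a final concentration over a baseline
#'
#' @param final Final concentration, cells/mL.
#' @param baseline Pre-dose (endogenous) concentration, cells/mL.
#'
#' @return A `fold_change` object: the ratio `final / baseline`, or, when
#'   the baseline is zero (organism absent before dosing), a flagged
#'   "from-zero" result carrying the final value, since a ratio over zero
#'   is undefined but the absolute rise is still meaningful.
#' @examples
#' fold_change(7e3, 1e3)   # 7-fold
#' fold_change(1.28e5, 0)  # from-zero: reported as the final value itself
#' @export
fold_change <- function(final, baseline) {
  check_number(final, "final", 0)
  check_number(baseline, "baseline", 0)
  if (baseline == 0) {
    structure(list(ratio = NA_real_, from_zero = TRUE, final = final,
                   baseline = 0), class = "fold_change")
  } else {
    structure(list(ratio = final / baseline, from_zero = FALSE,
                   final = final, baseline = baseline),
              class = "fold_change")
  }
}

#' @export
print.fold_change <- function(x, ...) {
  if (x$from_zero) {
    cat("fold change: increased from zero to", format(signif(x$final, 4)),
        "cells/mL\n")
  } else {
    cat("fold change:", format(signif(x$ratio, 4)), "\n")
  }
  invisible(x)
}

#' Pair a measured series with its no-growth prediction
#'
#' @param cycles Integer cycle indices shared by both series.
#' @param measured Measured concentrations, cells/mL.
#' @param predicted No-growth model concentrations, cells/mL.
#' @param compartment,phase Labels carried through to reports.
#'
#' @return A `comparison_series` object.
#' @export
comparison_series <- function(cycles, measured, predicted,
                              compartment = "AC", phase = "lumen") {
  if (length(cycles) != length(measured) ||
      length(measured) != length(predicted)) {
    stop_domain("cycles, measured and predicted must have equal length")
  }
  structure(list(cycles = as.integer(cycles),
                 measured = as.numeric(measured),
                 predicted = as.numeric(predicted),
                 compartment = compartment, phase = phase),
            class = "comparison_series")
}

# Pseudo-floor for zeros before a log-ratio: half the smallest positive
# measured value in the series (documented convention).
replace_zeros <- function(x) {
  if (all(x <= 0)) return(x)
  floor_val <- min(x[x > 0]) / 2
  ifelse(x <= 0, floor_val, x)
}

#' Classify a compartment's engraftment outcome
#'
#' Quantifies how far the measured trajectory sits from the no-growth
#' prediction at the end of the experiment: the geometric mean ratio R of
#' measured/predicted over the final `window` cycles. `R > factor` means
#' the organism is persisting above pure washout (`"ABOVE_EXPECTED"`),
#' `R < 1/factor` below it (`"BELOW_EXPECTED"`), otherwise it is tracking
#' the prediction (`"TRACKING"`). The default factor 2 corresponds to
#' about 0.3 log10, a deviation clearly visible on a log-scale trajectory
#' plot.
#'
#' @param series A [comparison_series()].
#' @param window Number of final cycles over which the ratio is averaged
#'   (default 6).
#' @param factor Threshold ratio, > 1 (default 2).
#'
#' @return A `gw_classification`: the call, the geometric mean ratio, and
#'   the per-cycle deviation series.
#' @export
classify_engraftment <- function(series, window = 6, factor = 2) {
  stopifnot(inherits(series, "comparison_series"))
  check_number(window, "window", 1)
  check_number(factor, "factor", 1, allow_zero = FALSE)
  if (factor <= 1) stop_domain("factor must be > 1")
  n <- length(series$cycles)
  if (n < window) {
    stop_domain("series has ", n, " points but window is ", window)
  }
  idx <- seq.int(n - window + 1L, n)
  pred <- series$predicted[idx]
  meas <- series$measured[idx]
  if (all(pred <= 0)) {
    stop_domain("undefined ratio: predicted values are all zero over the window")
  }
  pred <- replace_zeros(pred)
  meas <- replace_zeros(meas)
  keep <- pred > 0 & meas > 0
  ratio <- exp(mean(log(meas[keep] / pred[keep])))
  call <- if (ratio > factor) "ABOVE_EXPECTED"
          else if (ratio < 1 / factor) "BELOW_EXPECTED"
          else "TRACKING"
  structure(list(classification = call, geometric_mean_ratio = ratio,
                 window = window, factor = factor,
                 deviation = series$measured / series$predicted,
                 cycles = series$cycles,
                 compartment = series$compartment, phase = series$phase),
            class = "gw_classification")
}

#' @export
print.gw_classification <- function(x, ...) {
  cat(x$compartment, "/", x$phase, ": ", x$classification,
      " (geometric mean measured/predicted = ",
      format(signif(x$geometric_mean_ratio, 4)),
      " over final ", x$window, " cycles, threshold ", x$factor, ")\n",
      sep = "")
  invisible(x)
}

# Sum of squared log residuals of a measured series against the model
# trajectory for compartment `comp_idx` with multiplier `g` (upstream
# multipliers fixed at `g_fixed`).
growth_objective <- function(g, comp_idx, g_fixed, cycles, log_meas,
                             chain, schedule, dose, n_cycles, ordering) {
  growth <- rep(1, length(chain))
  if (comp_idx > 1L) growth[seq_len(comp_idx - 1L)] <- g_fixed
  growth[comp_idx] <- g
  tr <- simulate_with_growth(chain, schedule, dose, growth, n_cycles,
                             ordering = ordering)
  model <- tr$concentrations[comp_idx, as.character(cycles)]
  ok <- model > 0
  if (sum(ok) < 4L) return(Inf)
  sum((log_meas[ok] - log(model[ok]))^2)
}

#' Fit a per-cycle net growth multiplier for one compartment
#'
#' Least-squares fit on the log scale of measured concentrations against
#' the growth-extended washout model, profiling over the compartment's
#' multiplier g with any upstream compartments fixed at previously fitted
#' values (downstream inflow depends on upstream state, so a chain is
#' fitted in order; see [fit_growth_profile()]). The optional confidence
#' interval resamples log-scale residuals with replacement, refits, and
#' takes percentile bounds.
#'
#' @param cycles Post-dose cycle indices of the measurements (>= 1).
#' @param measured Measured concentrations, cells/mL; at least 4 must be
#'   positive.
#' @param compartment Label of the fitted compartment.
#' @param chain,schedule,dose Model inputs, as [predict_no_growth()].
#' @param growth_upstream Fitted multipliers for compartments upstream of
#'   this one, in chain order (empty for the first compartment).
#' @param interval Search interval for g (default `c(0.05, 5)`).
#' @param n_boot Number of bootstrap resamples for the confidence
#'   interval; 0 (default) skips the interval.
#' @param conf Interval coverage (default 0.95).
#' @param seed Seed for the residual bootstrap (default 20221026).
#' @param ordering Transit ordering, as [predict_no_growth()].
#'
#' @return A `growth_fit`: point estimate, optional percentile interval,
#'   residuals, and the points used.
#' @export
fit_growth_multiplier <- function(cycles, measured, compartment,
                                  chain, schedule, dose,
                                  growth_upstream = numeric(),
                                  interval = c(0.05, 5),
                                  n_boot = 0, conf = 0.95,
                                  seed = 20221026,
                                  ordering = "sequential") {
  comp_idx <- match(compartment, chain$names)
  if (is.na(comp_idx)) stop_domain("unknown compartment '", compartment, "'")
  if (length(growth_upstream) != comp_idx - 1L) {
    stop_domain("growth_upstream must have one value per upstream compartment")
  }
  ok <- is.finite(measured) & measured > 0 & cycles >= 1
  if (sum(ok) < 4L) {
    stop_domain("not estimable: fewer than 4 positive post-dose measurements")
  }
  cyc <- as.integer(cycles[ok])
  log_meas <- log(measured[ok])
  n_cycles <- max(cyc)

  fit_once <- function(lm_vec) {
    stats::optimize(growth_objective, interval = interval,
                    comp_idx = comp_idx, g_fixed = growth_upstream,
                    cycles = cyc, log_meas = lm_vec,
                    chain = chain, schedule = schedule, dose = dose,
                    n_cycles = n_cycles, ordering = ordering,
                    tol = 1e-10)$minimum
  }
  g_hat <- fit_once(log_meas)

  growth <- rep(1, length(chain))
  if (comp_idx > 1L) growth[seq_len(comp_idx - 1L)] <- growth_upstream
  growth[comp_idx] <- g_hat
  tr <- simulate_with_growth(chain, schedule, dose, growth, n_cycles,
                             ordering = ordering)
  fitted_log <- log(tr$concentrations[comp_idx, as.character(cyc)])
  resid <- log_meas - fitted_log

  ci <- c(NA_real_, NA_real_)
  boot <- numeric(0)
  if (n_boot > 0) {
    boot <- with_local_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        fit_once(fitted_log + sample(resid, replace = TRUE))
      }, numeric(1))
    })
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), type = 7))
  }

  structure(list(estimate = g_hat, ci = ci, conf = conf, n_boot = n_boot,
                 compartment = compartment, cycles = cyc,
                 residuals = resid, boot = boot),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("net growth multiplier for ", x$compartment, ": ",
      format(signif(x$estimate, 6)), sep = "")
  if (x$n_boot > 0) {
    cat(" (", x$conf * 100, "% CI ", format(signif(x$ci[1], 4)), "-",
        format(signif(x$ci[2], 4)), ", ", x$n_boot, " bootstrap resamples)",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Fit growth multipliers for every compartment of a chain, in order
#'
#' Fits the first compartment's multiplier first, then each downstream
#' compartment conditional on the upstream fits, since downstream inflow
#' depends on upstream state.
#'
#' @param series_list Named list (by compartment, in chain order) of
#'   lists with elements `cycles` and `measured`.
#' @inheritParams fit_growth_multiplier
#'
#' @return Named list of `growth_fit` objects.
#' @export
fit_growth_profile <- function(series_list, chain, schedule, dose,
                               n_boot = 0, seed = 20221026,
                               ordering = "sequential") {
  fits <- list()
  g_up <- numeric()
  for (comp in chain$names) {
    s <- series_list[[comp]]
    if (is.null(s)) {
      g_up <- c(g_up, 1)
      next
    }
    fit <- fit_growth_multiplier(s$cycles, s$measured, comp,
                                 chain, schedule, dose,
                                 growth_upstream = g_up,
                                 n_boot = n_boot, seed = seed,
                                 ordering = ordering)
    fits[[comp]] <- fit
    g_up <- c(g_up, fit$estimate)
  }
  fits
}

#' Build a full engraftment report for a set of measured series
#'
#' For each measured (compartment, phase) series: end-vs-baseline fold
#' change, log10 reduction over the post-dose period, fitted net growth
#' multiplier (luminal series only; mucosal series are descriptive and
#' never fed to the mass-balance model), and the washout classification.
#'
#' @param series_list List of [qpcr_series()] objects (baselines set).
#' @param chain,schedule,dose Model inputs.
#' @param window,factor Classification parameters, see
#'   [classify_engraftment()].
#' @param n_boot Bootstrap resamples for growth CIs (0 = none).
#' @param seed Bootstrap seed.
#'
#' @return An `engraftment_report`: a data frame of per-series metrics
#'   plus the growth fits, nested by bioreplicate then compartment.
#' @export
engraftment_report <- function(series_list, chain, schedule, dose,
                               window = 6, factor = 2, n_boot = 0,
                               seed = 20221026) {
  pred <- predict_no_growth(chain, schedule, dose,
                            n_cycles = max(vapply(series_list,
                                                  function(s) max(s$cycles),
                                                  numeric(1))))
  lum <- list()
  rows <- list()
  for (s in series_list) {
    post <- s$cycles >= s$dose_cycle
    cyc <- s$cycles[post]
    meas <- s$cells_per_ml[post]
    fc <- fold_change(meas[length(meas)],
                      if (is.na(s$baseline)) 0 else s$baseline)
    pos <- meas > 0
    log10_red <- if (sum(pos) >= 2) {
      log10(meas[which(pos)[1]]) - log10(meas[rev(which(pos))[1]])
    } else NA_real_
    cls <- NA_character_
    gm_ratio <- NA_real_
    if (s$compartment %in% rownames(pred$concentrations) &&
        sum(cyc >= 1) >= max(3, window)) {
      keep <- cyc >= 1
      cs <- comparison_series(cyc[keep], meas[keep],
                              pred$concentrations[s$compartment,
                                                  as.character(cyc[keep])],
                              compartment = s$compartment, phase = s$phase)
      cl <- classify_engraftment(cs, window = window, factor = factor)
      cls <- cl$classification
      gm_ratio <- cl$geometric_mean_ratio
    }
    if (s$phase == "lumen" && s$compartment %in% chain$names) {
      if (is.null(lum[[s$bioreplicate]])) lum[[s$bioreplicate]] <- list()
      lum[[s$bioreplicate]][[s$compartment]] <-
        list(cycles = cyc[cyc >= 1], measured = meas[cyc >= 1])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      bioreplicate = s$bioreplicate, compartment = s$compartment,
      phase = s$phase,
      fold_change_end_vs_baseline = if (fc$from_zero) NA_real_ else fc$ratio,
      from_zero = fc$from_zero,
      final_cells_per_ml = fc$final,
      log10_reduction_over_period = log10_red,
      geometric_mean_ratio = gm_ratio,
      classification = cls,
      stringsAsFactors = FALSE
    )
  }
  fits <- lapply(lum, function(series_list) {
    tryCatch(
      fit_growth_profile(series_list, chain, schedule, dose,
                         n_boot = n_boot, seed = seed),
      error = function(e) list()
    )
  })
  tab <- do.call(rbind, rows)
  tab$fitted_growth_multiplier <- NA_real_
  for (i in seq_len(nrow(tab))) {
    f <- fits[[tab$bioreplicate[i]]][[tab$compartment[i]]]
    if (tab$phase[i] == "lumen" && !is.null(f)) {
      tab$fitted_growth_multiplier[i] <- f$estimate
    }
  }
  structure(list(summary = tab, growth_fits = fits,
                 window = window, factor = factor),
            class = "engraftment_report")
}

#' @export
print.engraftment_report <- function(x, ...) {
  cat("<engraftment_report> ", nrow(x$summary), " series (window=",
      x$window, ", factor=", x$factor, ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
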