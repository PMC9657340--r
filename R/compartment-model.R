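# Mechanistic dilution/washout model for a chain of sequential bioreactors.
#
# The system is a SHIME-style chain of stirred compartments (typically
# ascending, transverse and descending colon vessels) fed in discrete
# cycles. Each feeding cycle moves a fixed transfer volume of medium into
# the first compartment and a plug of equal volume from each compartment
# into the next (the last discharges to waste). Within a compartment the
# incoming plug mixes completely with the resident content:
#
#   r = (M1 * r1 + M2 * r2) / (M1 + M2)
#
# where M1 is the inflow volume at concentration r1 and M2 the resident
# working volume at concentration r2. The compartment returns to its
# working volume by discharging the transfer volume at the mixed
# concentration, so a compartment with zero-concentration inflow retains
# the fraction V / (V + u) of its cells per cycle.

#' Define a chain of sequential bioreactor compartments
#'
#' @param volumes Named numeric vector of working volumes in mL, in chain
#'   order. Feed enters the first compartment; the last discharges to
#'   waste. Names are the compartment labels (e.g. `c(AC = 500, TC = 800,
#'   DC = 600)`).
#'
#' @return A `reactor_chain` object.
#' @examples
#' reactor_chain(c(AC = 500, TC = 800, DC = 600))
#' @export
reactor_chain <- function(volumes) {
  if (!is.numeric(volumes) || length(volumes) < 1L) {
    stop_domain("volumes must be a non-empty numeric vector")
  }
  if (any(!is.finite(volumes)) || any(volumes <= 0)) {
    stop_domain("all working volumes must be finite and > 0")
  }
  nm <- names(volumes)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop_domain("volumes must have unique, non-empty compartment names")
  }
  structure(
    list(names = nm, volumes = unname(as.numeric(volumes))),
    class = "reactor_chain"
  )
}

#' @export
print.reactor_chain <- function(x, ...) {
  cat("<reactor_chain> ", paste0(x$names, " (", x$volumes, " mL)",
                                 collapse = " -> "), " -> waste\n", sep = "")
  invisible(x)
}

#' @export
length.reactor_chain <- function(x) length(x$volumes)

#' Define the feeding cadence of the reactor chain
#'
#' @param transfer_volume Volume in mL moved into each compartment per
#'   feeding cycle.
#' @param cycles_per_day Number of feeding cycles per day (default 3,
#'   i.e. the system is fed three times daily).
#' @param feed_concentration Concentration of the tracked organism in the
#'   fresh feed, cells/mL. Zero for probiotic-free feed.
#'
#' @return A `feeding_schedule` object.
#' @export
feeding_schedule <- function(transfer_volume, cycles_per_day = 3,
                             feed_concentration = 0) {
  check_number(transfer_volume, "transfer_volume", 0, allow_zero = FALSE)
  check_number(cycles_per_day, "cycles_per_day", 1)
  check_number(feed_concentration, "feed_concentration", 0)
  structure(
    list(transfer_volume = transfer_volume,
         cycles_per_day = cycles_per_day,
         feed_concentration = feed_concentration),
    class = "feeding_schedule"
  )
}

#' Define a single bolus dose of tracked cells
#'
#' @param compartment Label of the compartment receiving the dose.
#' @param total_cells Absolute number of cells added.
#' @param cycle Feeding-cycle index at which the dose is added (default 0;
#'   the dose is mixed into the compartment before the next transit).
#'
#' @return A `dose_event` object.
#' @export
dose_event <- function(compartment, total_cells, cycle = 0) {
  stopifnot(is.character(compartment), length(compartment) == 1L)
  check_number(total_cells, "total_cells", 0)
  check_number(cycle, "cycle", 0)
  structure(
    list(compartment = compartment, total_cells = total_cells,
         cycle = as.integer(cycle)),
    class = "dose_event"
  )
}

#' Complete-mixing rule for one transfer event
#'
#' Concentration after an inflow of volume `M1` at concentration `r1`
#' mixes completely with a resident volume `M2` at concentration `r2`:
#' `(M1 * r1 + M2 * r2) / (M1 + M2)`.
#'
#' @param M1 Inflow volume (mL), >= 0.
#' @param r1 Inflow concentration, >= 0.
#' @param M2 Resident volume (mL), >= 0.
#' @param r2 Resident concentration, >= 0.
#'
#' @return The mixed concentration, always between `min(r1, r2)` and
#'   `max(r1, r2)`.
#' @examples
#' mix(140, 0, 500, 6.4e5) # 5e5
#' @export
mix <- function(M1, r1, M2, r2) {
  for (v in list(M1 = M1, r1 = r1, M2 = M2, r2 = r2)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_domain("mix() arguments must be single finite numbers")
    }
  }
  if (M1 < 0 || M2 < 0 || r1 < 0 || r2 < 0) {
    stop_domain("mix() arguments must be non-negative")
  }
  if (M1 + M2 == 0) {
    stop_domain("degenerate mixture: M1 + M2 must be > 0")
  }
  (M1 * r1 + M2 * r2) / (M1 + M2)
}

#' Closed-form washout of a single compartment
#'
#' Analytic solution of the single-compartment recurrence: after `n`
#' feeding cycles with zero-concentration feed, a compartment of working
#' volume `V` receiving `u` mL per cycle holds `c0 * (V / (V + u))^n`.
#' Serves as the analytic oracle for the iterated simulation.
#'
#' @param c0 Initial concentration, cells/mL.
#' @param V Working volume, mL.
#' @param u Transfer volume per cycle, mL.
#' @param n Number of cycles, >= 0 (vector allowed).
#'
#' @return Concentration after `n` cycles.
#' @export
closed_form_single <- function(c0, V, u, n) {
  check_number(c0, "c0", 0)
  check_number(V, "V", 0, allow_zero = FALSE)
  check_number(u, "u", 0, allow_zero = FALSE)
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 0)) {
    stop_domain("n must be finite and >= 0")
  }
  c0 * (V / (V + u))^n
}

# Core cycle iterator shared by predict_no_growth() and
# simulate_with_growth(). Concentrations below `floor` are clamped to 0
# to avoid denormal drift; the clamped mass is tracked so conservation
# checks can account for it.
sim_core <- function(chain, schedule, dose, growth, n_cycles,
                     ordering = c("sequential", "simultaneous"),
                     floor = 1e-30) {
  ordering <- match.arg(ordering)
  check_number(n_cycles, "n_cycles", 0)
  n_cycles <- as.integer(n_cycles)
  V <- chain$volumes
  k <- length(V)
  u <- schedule$transfer_volume
  f <- schedule$feed_concentration
  g <- rep_len(as.numeric(growth), k)
  if (any(!is.finite(g)) || any(g < 0)) {
    stop_domain("growth multipliers must be finite and >= 0")
  }
  dose_idx <- match(dose$compartment, chain$names)
  if (is.na(dose_idx)) {
    stop_domain("unknown dose compartment '", dose$compartment, "'; chain has: ",
                paste(chain$names, collapse = ", "))
  }
  if (dose$cycle > n_cycles) {
    stop_domain("dose cycle (", dose$cycle, ") exceeds n_cycles (", n_cycles, ")")
  }

  conc <- matrix(0, nrow = k, ncol = n_cycles + 1L,
                 dimnames = list(chain$names, 0:n_cycles))
  waste <- numeric(n_cycles + 1L)
  clamped <- 0
  state <- numeric(k)
  if (dose$cycle == 0L) state[dose_idx] <- dose$total_cells / V[dose_idx]
  conc[, 1L] <- state

  for (n in seq_len(n_cycles)) {
    # net growth/death applied to resident cells before the transit event
    state <- state * g
    if (ordering == "sequential") {
      # overflow cascade: feed -> first compartment, each compartment's
      # post-mix overflow feeds the next, last overflows to waste;
      # conserves cells exactly
      inflow <- f
      for (i in seq_len(k)) {
        state[i] <- mix(u, inflow, V[i], state[i])
        inflow <- state[i]
      }
      out <- inflow
    } else {
      # all plugs computed from the pre-cycle state; an approximation
      # that does not conserve mass exactly (see the methods vignette)
      pre <- state
      inflow_conc <- c(f, pre[-k])
      state <- (u * inflow_conc + V * pre) / (u + V)
      out <- state[k]
    }
    low <- state > 0 & state < floor
    if (any(low)) {
      clamped <- clamped + sum(V[low] * state[low])
      state[low] <- 0
    }
    waste[n + 1L] <- waste[n] + u * out
    if (n == dose$cycle) state[dose_idx] <- state[dose_idx] +
        dose$total_cells / V[dose_idx]
    conc[, n + 1L] <- state
  }

  structure(
    list(concentrations = conc,
         cumulative_waste_cells = waste,
         cycle_axis = 0:n_cycles,
         clamped_cells = clamped,
         chain = chain, schedule = schedule, dose = dose,
         growth = g, ordering = ordering),
    class = "gw_trajectory"
  )
}

#' Predict tracked-cell washout under the no-growth assumption
#'
#' Iterates the discrete feeding-cycle model assuming the dosed organism
#' neither replicates nor dies: concentrations change only through
#' dilution by fresh feed and transit down the chain. This is the
#' theoretical curve measured counts are compared against: counts above
#' it indicate net growth, counts below it net loss.
#'
#' @param chain A [reactor_chain()].
#' @param schedule A [feeding_schedule()].
#' @param dose A [dose_event()].
#' @param n_cycles Number of feeding cycles to simulate.
#' @param ordering Transit ordering within a cycle. `"sequential"`
#'   (default) is the overflow cascade: each compartment's post-mix
#'   overflow feeds the next, which conserves cells exactly.
#'   `"simultaneous"` computes every plug from the pre-cycle state and is
#'   kept as an alternative; it does not conserve mass exactly.
#'
#' @return A `gw_trajectory`: concentration matrix (compartments x
#'   cycles 0..n), cumulative waste ledger, and the inputs used.
#' @examples
#' ch <- reactor_chain(c(AC = 500, TC = 800, DC = 600))
#' tr <- predict_no_growth(ch, feeding_schedule(140), dose_event("AC", 2.5e11), 31)
#' tr$concentrations[, c(1, 11, 32)]
#' @export
predict_no_growth <- function(chain, schedule, dose, n_cycles,
                              ordering = c("sequential", "simultaneous")) {
  sim_core(chain, schedule, dose, growth = 1, n_cycles = n_cycles,
           ordering = ordering)
}

#' Simulate washout with per-compartment net growth
#'
#' Extends the no-growth model with a dimensionless net per-cycle factor
#' per compartment: each cycle the resident cells in compartment *i* are
#' multiplied by `growth[i]` before the transit event. `growth = 1`
#' everywhere recovers [predict_no_growth()] exactly; values below 1
#' represent net death, above 1 net proliferation.
#'
#' @inheritParams predict_no_growth
#' @param growth Numeric vector of per-cycle multipliers, recycled to the
#'   number of compartments. All values must be >= 0.
#'
#' @return A `gw_trajectory`, as [predict_no_growth()].
#' @export
simulate_with_growth <- function(chain, schedule, dose, growth, n_cycles,
                                 ordering = c("sequential", "simultaneous")) {
  sim_core(chain, schedule, dose, growth = growth, n_cycles = n_cycles,
           ordering = ordering)
}

#' @export
print.gw_trajectory <- function(x, ...) {
  k <- nrow(x$concentrations)
  n <- ncol(x$concentrations) - 1L
  cat("<gw_trajectory> ", k, " compartment(s) x ", n, " cycle(s), ordering=",
      x$ordering, "\n", sep = "")
  cat("  final concentrations (cells/mL): ",
      paste0(rownames(x$concentrations), "=",
             signif(x$concentrations[, n + 1L], 4), collapse = ", "), "\n")
  cat("  cumulative waste: ", format(signif(x$cumulative_waste_cells[n + 1L], 6)),
      " cells\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.gw_trajectory <- function(x, ...) {
  conc <- x$concentrations
  data.frame(
    cycle = rep(x$cycle_axis, each = nrow(conc)),
    compartment = rep(rownames(conc), times = ncol(conc)),
    concentration_cells_per_ml = as.vector(conc),
    cumulative_waste_cells = rep(x$cumulative_waste_cells, each = nrow(conc)),
    stringsAsFactors = FALSE
  )
}

#' Total cells resident in the system at each cycle
#'
#' @param trajectory A `gw_trajectory`.
#' @return Numeric vector over cycles 0..n of `sum_i V_i * c_i`.
#' @export
system_cells <- function(trajectory) {
  as.vector(trajectory$chain$volumes %*% trajectory$concentrations)
}
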