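#' Capacitance x soil-dryness x strategy sensitivity experiment
#'
#' Runs one-day simulations over the full factorial of storage fractions
#' (storage capacity as a fraction of the daily demand integral), initial
#' soil water potentials and stomatal strategies, and collects the daily
#' summaries. Solver failures are recorded per cell and the grid continues.
#'
#' @param fractions storage capacities as fractions of the daily demand
#'   (the reference experiment uses 0, 0.2, 0.5, 1, 2)
#' @param psi0 initial soil water potentials (MPa)
#' @param strategies named list of [strategy_spec()] objects
#' @param plant a [plant_params()] (default the average-tree preset)
#' @param soil a [soil_params()]
#' @param forcing demand forcing; default one 24-h half-sine day
#' @param solver a [solver_config()]
#' @param V_s accessible soil volume (cm3)
#' @return data frame: one [daily_summary()] row per
#'   (fraction x potential x strategy x day), with scenario columns
#'   `fraction`, `V_max`, `psi0`, `strategy`, and `error` (NA or message)
#' @export
sensitivity_grid <- function(fractions = c(0, 0.2, 0.5, 1, 2),
                             psi0 = seq(0, -2, by = -0.05),
                             strategies = list(
                               fixed = strategy_spec("fixed"),
                               flexible = strategy_spec("flexible")),
                             plant = plant_preset("average"),
                             soil = soil_params(),
                             forcing = sinusoidal_demand(),
                             solver = solver_config(), V_s = 1e6 / 3) {
  daily_demand <- sum(forcing$E0[forcing$t < 86400]) * attr(forcing, "dt")
  if (is.null(names(strategies)))
    names(strategies) <- vapply(strategies, `[[`, "", "mode")
  rows <- list()
  for (f in fractions) {
    storage <- storage_from_fraction(f, daily_demand)
    sys <- hydraulic_system(soil, plant, storage, V_s = V_s)
    for (sname in names(strategies)) {
      for (ps in psi0) {
        res <- tryCatch({
          traj <- run_simulation(forcing, sys, strategies[[sname]], solver,
                                 init_psi_soil = ps)
          cbind(fraction = f, V_max = storage$V_max, psi0 = ps,
                strategy = sname, daily_summary(traj), error = NA_character_)
        }, error = function(e) {
          data.frame(fraction = f, V_max = storage$V_max, psi0 = ps,
                     strategy = sname, day = NA, E_total = NA,
                     Q_soil_total = NA, Q_cap_total = NA, t_peak_E = NA,
                     t_peak_Q_soil = NA, t_peak_Q_cap = NA,
                     lag_E_Q_soil = NA, min_psi_leaf = NA,
                     error = conditionMessage(e))
        })
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Soil potential where two strategies' daily transpiration curves cross
#'
#' With drying soil the flexible (anisohydric) strategy overtakes the fixed
#' threshold (isohydric) strategy: under wet soil it transpires less (early
#' closure), under dry soil more (leaf potential may keep falling). This
#' locates the initial soil water potential at which the two daily
#' transpiration curves intersect, by linear interpolation between the
#' bracketing grid points of the first wet-to-dry sign change. Returns `NA`
#' (with a message) when the curves never cross or are indistinguishable.
#'
#' @param results a [sensitivity_grid()] result (or any data frame with
#'   columns `psi0`, `strategy`, `E_total`) containing the two strategies on
#'   a common potential grid
#' @param flexible,fixed the two strategy labels to compare
#' @param tol relative difference under which the curves are considered
#'   indistinguishable
#' @return crossover soil water potential (MPa), or `NA`
#' @export
crossover_potential <- function(results, flexible = "flexible",
                                fixed = "fixed", tol = 1e-6) {
  a <- results[results$strategy == flexible, c("psi0", "E_total")]
  b <- results[results$strategy == fixed, c("psi0", "E_total")]
  m <- merge(a, b, by = "psi0", suffixes = c("_flex", "_fixed"))
  m <- m[order(m$psi0, decreasing = TRUE), ]  # wet -> dry
  if (nrow(m) < 2) stop("need at least two common potentials")
  d <- m$E_total_flex - m$E_total_fixed
  scale <- max(abs(m$E_total_fixed), na.rm = TRUE)
  if (all(abs(d) <= tol * scale, na.rm = TRUE)) {
    message("curves indistinguishable: no unique crossing")
    return(NA_real_)
  }
  ok <- which(!is.na(d))
  for (j in seq_len(length(ok) - 1)) {
    i1 <- ok[j]; i2 <- ok[j + 1]
    if (d[i1] < 0 && d[i2] >= 0) {
      if (d[i2] == d[i1]) return(m$psi0[i2])
      return(m$psi0[i1] + (0 - d[i1]) * (m$psi0[i2] - m$psi0[i1]) /
               (d[i2] - d[i1]))
    }
  }
  message("no crossing: the flexible strategy never overtakes on this grid")
  NA_real_
}
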