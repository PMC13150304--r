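#' Steady-state supply curve: transpiration vs leaf water potential
#'
#' For a frozen reservoir state (bulk soil potential, storage potential),
#' solves the chain for each transpiration rate on an increasing grid and
#' returns the resulting leaf water potentials. The curve is strictly
#' decreasing in E, and is truncated where the soil or xylem can no longer
#' carry the flux (the supply ceiling) or where the leaf potential falls
#' below `solver$psi_floor`.
#'
#' @param sys a [hydraulic_system()]
#' @param psi_soil bulk soil water potential (MPa)
#' @param psi_cap storage potential (MPa); `NULL` when storage is disabled
#' @param E_grid increasing grid of transpiration rates from 0 (cm3 s-1);
#'   `NULL` builds a `solver$n_grid`-point grid from 0 to the supply ceiling
#' @param solver a [solver_config()]
#' @param psi_x_init optional warm start for the xylem-potential iterate
#' @return data frame with columns `E`, `psi_leaf`, `psi_x`, `Q_soil`, `Q_cap`
#' @export
supply_curve <- function(sys, psi_soil, psi_cap = NULL, E_grid = NULL,
                         solver = solver_config(), psi_x_init = NULL) {
  if (is.null(E_grid)) {
    E_hi <- supply_ceiling(sys, psi_soil, psi_cap, solver)
    E_grid <- seq(0, E_hi, length.out = solver$n_grid)
  }
  stopifnot(E_grid[1] >= 0, !is.unsorted(E_grid))
  sol <- solve_chain(E_grid, psi_soil, sys, psi_cap, solver, psi_x_init,
                     method = "bisection")
  keep <- !sol$limited & sol$psi_leaf >= solver$psi_floor
  # keep the feasible prefix so the curve stays a function of E
  n_keep <- if (all(keep)) length(E_grid) else which.min(keep) - 1L
  n_keep <- max(n_keep, 1L)
  idx <- seq_len(n_keep)
  data.frame(E = E_grid[idx], psi_leaf = sol$psi_leaf[idx],
             psi_x = sol$psi_x[idx], Q_soil = sol$Q_soil[idx],
             Q_cap = sol$Q_cap[idx])
}

# Analytic upper bound for the deliverable transpiration at a frozen state:
# soil supply ceiling plus the largest storage discharge before the xylem
# node reaches the scan floor.
supply_ceiling <- function(sys, psi_soil, psi_cap = NULL,
                           solver = solver_config()) {
  E_hi <- soil_supply_max(psi_soil, sys$domain, sys$soil)
  if (sys$storage$V_max > 0 && !is.null(psi_cap))
    E_hi <- E_hi + max(0, sys$storage$k_exchange * (psi_cap - solver$psi_floor))
  max(E_hi * (1 - 1e-9), 1e-12)
}

#' Flexible (anisohydric) onset of stomatal closure
#'
#' Locates the point on the current supply curve maximizing
#' \eqn{E / (-\Psi_{leaf} + \epsilon)}: stomata stay open in the linear
#' regime of the E--leaf-potential relation and close when limited supply
#' makes it nonlinear. The grid argmax is refined by golden-section search
#' between the neighbouring grid points; ties go to the smaller E. When the
#' ratio is still increasing at the end of the curve (purely linear supply,
#' wet soil) the curve's end point is returned.
#'
#' @inheritParams supply_curve
#' @param epsilon regularizing offset (MPa) in the maximized ratio
#' @param E_max optional cap on the scanned transpiration range (cm3 s-1),
#'   e.g. the maximum imposed demand during calibration
#' @return list with `E_lim`, `psi_leaf_lim`, `at_ceiling` (logical), and
#'   the scanned `curve`
#' @export
flexible_onset <- function(sys, psi_soil, psi_cap = NULL, epsilon = 0.2,
                           solver = solver_config(), E_max = NULL,
                           psi_x_init = NULL) {
  stopifnot(epsilon > 0)
  E_hi <- supply_ceiling(sys, psi_soil, psi_cap, solver)
  if (!is.null(E_max)) E_hi <- min(E_hi, E_max)
  E_grid <- seq(0, E_hi, length.out = solver$n_grid)
  curve <- supply_curve(sys, psi_soil, psi_cap, E_grid, solver, psi_x_init)
  ratio <- curve$E / (-curve$psi_leaf + epsilon)
  i <- which.max(ratio)
  at_ceiling <- i == nrow(curve)
  if (nrow(curve) < 3 || (at_ceiling && i < 2)) {
    warning("degenerate supply curve; returning its end point")
    i <- nrow(curve)
    return(list(E_lim = curve$E[i], psi_leaf_lim = curve$psi_leaf[i],
                at_ceiling = TRUE, curve = curve))
  }
  if (at_ceiling) {
    E_lim <- curve$E[i]; psi_lim <- curve$psi_leaf[i]
  } else {
    # golden-section refinement of the interior argmax
    lo <- curve$E[i - 1L]; hi <- curve$E[i + 1L]
    obj <- function(E) {
      s <- solve_chain(E, psi_soil, sys, psi_cap, solver,
                       psi_x_init = curve$psi_x[i], method = "bisection")
      E / (-s$psi_leaf + epsilon)
    }
    opt <- stats::optimize(obj, lower = lo, upper = hi, maximum = TRUE,
                           tol = (hi - lo) * 1e-2)
    E_lim <- opt$maximum
    psi_lim <- solve_chain(E_lim, psi_soil, sys, psi_cap, solver,
                           psi_x_init = curve$psi_x[i],
                           method = "bisection")$psi_leaf
    if (opt$objective < ratio[i]) {  # guard: keep the grid point on ties
      E_lim <- curve$E[i]; psi_lim <- curve$psi_leaf[i]
    }
  }
  list(E_lim = E_lim, psi_leaf_lim = psi_lim, at_ceiling = at_ceiling,
       curve = curve)
}

#' Limit transpiration according to the stomatal strategy
#'
#' Mode `"none"` returns the demand unchanged; `"fixed"` returns the largest
#' transpiration not exceeding the demand for which the leaf water potential
#' stays at or above `psi_lim` (bisection on the supply relation, tolerance
#' 1e-6 cm3 s-1); `"flexible"` caps the demand at the current flexible onset.
#'
#' @param E_demand imposed evaporative demand (cm3 s-1)
#' @inheritParams supply_curve
#' @param spec a [strategy_spec()]
#' @param onset optionally, a precomputed [flexible_onset()] result to reuse
#' @return list with `E` (the actual transpiration, in `[0, E_demand]`) and
#'   `onset` (the flexible onset used, or `NULL`)
#' @export
regulate <- function(E_demand, sys, psi_soil, psi_cap = NULL,
                     spec = strategy_spec(), solver = solver_config(),
                     psi_x_init = NULL, onset = NULL) {
  stopifnot(E_demand >= 0)
  if (spec$mode == "none" || E_demand == 0)
    return(list(E = E_demand, onset = NULL))
  if (spec$mode == "flexible") {
    if (is.null(onset))
      onset <- flexible_onset(sys, psi_soil, psi_cap, spec$epsilon, solver,
                              psi_x_init = psi_x_init)
    return(list(E = min(E_demand, onset$E_lim), onset = onset))
  }
  # fixed threshold: the cap is the E at which psi_leaf == psi_lim
  if (identical(sys$topology, "lumped")) {
    E_lim <- E_at_leaf_target(spec$psi_lim, psi_soil, sys, psi_cap, solver)
    return(list(E = min(E_demand, max(E_lim, 0)), onset = NULL))
  }
  # branched topology: bisection on the supply relation
  leaf_at <- function(E) {
    s <- solve_chain(E, psi_soil, sys, psi_cap, solver, psi_x_init,
                     method = "bisection")
    if (s$limited) -Inf else s$psi_leaf
  }
  if (leaf_at(E_demand) >= spec$psi_lim)
    return(list(E = E_demand, onset = NULL))
  if (leaf_at(0) < spec$psi_lim)
    return(list(E = 0, onset = NULL))
  lo <- 0; hi <- E_demand
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (leaf_at(mid) >= spec$psi_lim) lo <- mid else hi <- mid
  }
  list(E = lo, onset = NULL)
}

# Largest transpiration keeping the leaf at `psi_target` for the lumped
# topology, where the leaf sits at the xylem node: the storage flux is then
# known outright, and the matching root uptake solves
# phi_x(psi_sri(Q_soil)) - Q_soil = phi_x(psi_target), a strictly
# decreasing residual bisected to high flux precision. Negative roots
# (reverse flow into a soil drier than the target) are allowed, so storage
# can sustain transpiration at the threshold even when the soil cannot.
E_at_leaf_target <- function(psi_target, psi_soil, sys, psi_cap = NULL,
                             solver = solver_config()) {
  p <- sys$plant; soil <- sys$soil
  G <- sys$domain$G
  has_storage <- sys$storage$V_max > 0 && !is.null(psi_cap)
  Q_cap <- if (has_storage) sys$storage$k_exchange * (psi_cap - psi_target)
           else 0
  Ks <- soil$K_s; psie <- soil$psi_e; Ns <- soil$N
  A_s <- Ks * abs(psie)^Ns / (Ns - 1)
  phi_es <- Ks * abs(psie) / (Ns - 1)
  K0 <- p$K_x0; h0 <- p$h_x0; bx <- p$b_x
  A_x <- K0 * abs(h0)^bx / (bx - 1)
  phi_hx <- K0 * abs(h0) / (bx - 1)
  phi_b <- if (psi_soil <= psie) A_s * (-psi_soil)^(1 - Ns)
           else phi_es + Ks * (psi_soil - psie)
  phi_s0 <- phi_es + Ks * (0 - psie)
  phix_target <- if (psi_target <= h0) A_x * (-psi_target)^(1 - bx)
                 else phi_hx + K0 * (psi_target - h0)
  resid <- function(Q) {
    phi_t <- phi_b - Q * G
    if (phi_t <= 0) return(-Inf)
    ps <- if (phi_t < phi_es) -(A_s / phi_t)^(1 / (Ns - 1))
          else min(psie + (phi_t - phi_es) / Ks, 0)
    phix <- if (ps <= h0) A_x * (-ps)^(1 - bx) else phi_hx + K0 * (ps - h0)
    phix - Q - phix_target
  }
  lo <- min(0, -(phi_s0 - phi_b) / G) - 1   # reverse flow: interface at 0
  hi <- phi_b / G                           # soil supply ceiling
  if (resid(lo) <= 0) return(Q_cap + lo)    # degenerate; caller clamps
  for (i in 1:80) {
    mid <- (lo + hi) / 2
    if (resid(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-9) break
  }
  (lo + hi) / 2 + Q_cap
}
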