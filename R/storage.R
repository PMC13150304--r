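#' Storage water potential from stored volume
#'
#' Linear pressure-volume relation: 0 MPa when full, `psi_empty` when empty,
#' `psi = psi_empty (1 - V/V_max)` in between.
#'
#' @param V stored water volume (cm3), in `[0, V_max]`; vectorized
#' @param s a [storage_params()] object with `V_max > 0`
#' @return storage water potential (MPa)
#' @export
storage_potential <- function(V, s) {
  if (s$V_max <= 0) stop("storage is disabled (V_max = 0)")
  if (any(V < -1e-9 * s$V_max) || any(V > s$V_max * (1 + 1e-9)))
    stop("stored volume outside [0, V_max]")
  s$psi_empty * (1 - pmin(pmax(V, 0), s$V_max) / s$V_max)
}

#' Stored volume in equilibrium with a water potential
#'
#' Exact inverse of [storage_potential()].
#'
#' @param psi water potential (MPa), in `[psi_empty, 0]`; vectorized
#' @param s a [storage_params()] object with `V_max > 0`
#' @return stored volume (cm3)
#' @export
equilibrium_volume <- function(psi, s) {
  if (s$V_max <= 0) stop("storage is disabled (V_max = 0)")
  if (any(psi < s$psi_empty) || any(psi > 0))
    stop("potential outside [psi_empty, 0]")
  s$V_max * (1 - psi / s$psi_empty)
}

#' Storage discharge/recharge flux
#'
#' Flux across the storage-xylem branch,
#' `Q_cap = k_exchange (psi_cap - psi_x)`: positive when storage discharges
#' into the transpiration stream, negative during (typically nocturnal)
#' refilling.
#'
#' @param psi_cap storage potential (MPa)
#' @param psi_x xylem potential (MPa)
#' @param s a [storage_params()] object (with `k_exchange` set)
#' @return flux (cm3 s-1)
#' @export
storage_flux <- function(psi_cap, psi_x, s) {
  if (is.null(s$k_exchange)) stop("k_exchange is not set on this storage")
  s$k_exchange * (psi_cap - psi_x)
}

#' Estimate capacitance from a root-segment drydown
#'
#' Ordinary-least-squares slope of relative storage,
#' `(wet mass - dry mass) / dry mass`, against xylem water potential,
#' restricted to the potential window in which the pressure-volume relation
#' is observed to be linear (default -1 to -2.25 MPa, the range plants
#' operate in during daytime transpiration down to the observed minimum).
#' The slope is reported positive: relative water mass lost per MPa of
#' potential drop, in kg MPa-1 kg-1.
#'
#' @param d a data frame with columns `psi_MPa` and `mass_g` (wet mass)
#' @param dry_mass_g segment dry mass (g)
#' @param psi_window length-2 numeric window of potentials (MPa) used for
#'   the regression
#' @return a list with `slope` (kg MPa-1 kg-1), `intercept`, `n`, `r_squared`
#' @export
capacitance_from_drydown <- function(d, dry_mass_g,
                                     psi_window = c(-2.25, -1)) {
  stopifnot(is.data.frame(d), all(c("psi_MPa", "mass_g") %in% names(d)),
            dry_mass_g > 0)
  lo <- min(psi_window); hi <- max(psi_window)
  keep <- d$psi_MPa >= lo & d$psi_MPa <= hi
  if (sum(keep) < 3)
    stop("insufficient data: fewer than 3 records inside the potential window")
  rel <- (d$mass_g[keep] - dry_mass_g) / dry_mass_g
  fit <- stats::lm(rel ~ d$psi_MPa[keep])
  list(slope = abs(unname(stats::coef(fit)[2])),
       intercept = unname(stats::coef(fit)[1]),
       n = sum(keep),
       r_squared = summary(fit)$r.squared)
}
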