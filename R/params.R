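#' Brooks-Corey soil parameters
#'
#' Container for the soil water retention and conductivity constants used
#' throughout the package. The retention curve is Brooks-Corey,
#' \deqn{\theta(\psi) = \theta_r + (\theta_s - \theta_r)(\psi_e/\psi)^\lambda,
#' \quad \psi < \psi_e,}
#' with the Burdine conductivity exponent \eqn{N = 2 + 3\lambda}. When
#' `lambda_bc` is `NULL` it is solved from the wilting-point anchor so that
#' `water_content(wilting_anchor[1]) == wilting_anchor[2]`, which with the
#' defaults (saturation 0.533, residual 0.03, 0.21 at -1.5 MPa) gives
#' \eqn{\lambda \approx 0.1405}.
#'
#' Units: potentials in MPa (negative), contents as volume fractions,
#' conductivity `K_s` in cm2 MPa-1 s-1 (water flux density per unit potential
#' gradient). The default `K_s = 1` corresponds to roughly 1e-4 cm s-1
#' (about 8.5 cm d-1) of saturated conductivity, a typical forest loam.
#'
#' @param theta_s saturated volumetric water content (fraction)
#' @param theta_r residual volumetric water content (fraction)
#' @param psi_e air-entry potential (MPa, negative)
#' @param lambda_bc Brooks-Corey pore-size index; `NULL` to solve from the
#'   wilting anchor
#' @param K_s saturated hydraulic conductivity (cm2 MPa-1 s-1)
#' @param wilting_anchor length-2 numeric `c(psi, theta)` anchor used when
#'   `lambda_bc` is `NULL`
#' @return an object of class `soil_params`
#' @examples
#' p <- soil_params()
#' water_content(-1.5, p) # ~0.21
#' @export
soil_params <- function(theta_s = 0.533, theta_r = 0.03, psi_e = -0.001,
                        lambda_bc = NULL, K_s = 1.0,
                        wilting_anchor = c(-1.5, 0.21)) {
  stopifnot(theta_r > 0, theta_r < theta_s, theta_s <= 1,
            psi_e < 0, K_s > 0)
  if (is.null(lambda_bc)) {
    # (psi_e/psi_w)^lambda = (theta_w - theta_r)/(theta_s - theta_r)
    s_eff <- (wilting_anchor[2] - theta_r) / (theta_s - theta_r)
    stopifnot(s_eff > 0, s_eff < 1, wilting_anchor[1] < psi_e)
    lambda_bc <- log(s_eff) / log(psi_e / wilting_anchor[1])
  }
  stopifnot(lambda_bc > 0)
  N <- 2 + 3 * lambda_bc
  if (N <= 1) stop("conductivity exponent N = 2 + 3*lambda must exceed 1")
  structure(list(theta_s = theta_s, theta_r = theta_r, psi_e = psi_e,
                 lambda_bc = lambda_bc, K_s = K_s, N = N),
            class = "soil_params")
}

#' Root-accessible soil domain geometry
#'
#' The soil accessible to the root system is represented as a cylinder of
#' soil around one long root: volume `V_s`, root radius `r_root`, root
#' length `L`, and the derived bulk-soil radius
#' `r_b = sqrt(V_s / (pi * L))`. Lengths in cm, volumes in cm3.
#'
#' @param V_s root-accessible soil volume (cm3); default 1/3 m3
#' @param r_root root radius (cm); default 0.05 cm (0.5 mm)
#' @param L total root length (cm)
#' @return an object of class `soil_domain`
#' @export
soil_domain <- function(V_s = 1e6 / 3, r_root = 0.05, L) {
  stopifnot(V_s > 0, r_root > 0, L > 0)
  r_b <- sqrt(V_s / (pi * L))
  if (r_b <= r_root)
    stop("bulk-soil radius r_b = ", signif(r_b, 4),
         " cm does not exceed the root radius; root length too large for V_s")
  structure(list(V_s = V_s, r_root = r_root, L = L, r_b = r_b,
                 G = log(r_b / r_root) / (2 * pi * L)),
            class = "soil_domain")
}

#' Whole-plant hydraulic parameters
#'
#' `K_x0` is the maximum soil-plant hydraulic conductance
#' (cm3 MPa-1 s-1), `L_m` the root length in metres (converted to cm for the
#' radial-flow geometry), `h_x0` the xylem water potential at the onset of
#' conductivity loss (MPa), `b_x` the vulnerability exponent of the power-law
#' decline below `h_x0`, and `r_root_mm` the root radius in mm.
#' `leaf_sapwood_factor` scales simulated transpiration into sap-flux-density
#' units for comparison with stem sensors; it is applied only on export,
#' never inside the solver.
#'
#' @param K_x0 maximum soil-plant conductance (cm3 MPa-1 s-1)
#' @param L_m root length (m)
#' @param h_x0 xylem potential at onset of conductivity loss (MPa, negative)
#' @param b_x vulnerability exponent (> 1)
#' @param r_root_mm root radius (mm)
#' @param leaf_sapwood_factor dimensionless export scaling
#' @return an object of class `plant_params`
#' @seealso [plant_preset()] for the calibrated species profiles
#' @export
plant_params <- function(K_x0, L_m, h_x0, b_x = 2, r_root_mm = 0.5,
                         leaf_sapwood_factor = 1) {
  stopifnot(K_x0 > 0, L_m > 0, h_x0 < 0, b_x > 1, r_root_mm > 0,
            leaf_sapwood_factor > 0)
  structure(list(K_x0 = K_x0, L_m = L_m, L_cm = L_m * 100, h_x0 = h_x0,
                 b_x = b_x, r_root_cm = r_root_mm / 10,
                 leaf_sapwood_factor = leaf_sapwood_factor),
            class = "plant_params")
}

#' Calibrated species presets
#'
#' Species-averaged calibrations of the three fitted parameters
#' (`K_x0`, `L`, `h_x0`): beech (0.71 cm3 MPa-1 s-1, 27375 m, -1.7 MPa),
#' spruce (0.35, 10125, -2.8), and their arithmetic mean as the generic
#' "average" tree used in the sensitivity experiments. The leaf-to-sapwood
#' export factors are 1000 (beech) and 500 (spruce).
#'
#' @param species one of `"beech"`, `"spruce"`, `"average"`
#' @param ... overrides passed on to [plant_params()]
#' @return a `plant_params` object
#' @export
plant_preset <- function(species = c("beech", "spruce", "average"), ...) {
  species <- match.arg(species)
  base <- switch(species,
    beech   = list(K_x0 = 0.71, L_m = 27375, h_x0 = -1.7,
                   leaf_sapwood_factor = 1000),
    spruce  = list(K_x0 = 0.35, L_m = 10125, h_x0 = -2.8,
                   leaf_sapwood_factor = 500),
    average = list(K_x0 = (0.71 + 0.35) / 2, L_m = (27375 + 10125) / 2,
                   h_x0 = (-1.7 + -2.8) / 2, leaf_sapwood_factor = 750))
  args <- utils::modifyList(base, list(...))
  do.call(plant_params, args)
}

#' Linear pressure-volume storage parameters
#'
#' Plant water storage follows a linear pressure-volume relation: full
#' (`V = V_max`) at 0 MPa and empty at `psi_empty` (default -4.5 MPa, twice
#' the most negative leaf water potential observed in the field), so the
#' capacitance is the constant `C = V_max / |psi_empty|`. `k_exchange` is the
#' conductance of the branch connecting the storage compartment to the xylem;
#' it defaults to the whole-plant conductance when the storage object is
#' attached to a [hydraulic_system()].
#'
#' @param V_max storage capacity (cm3); 0 disables storage
#' @param psi_empty potential at which storage is empty (MPa, negative)
#' @param k_exchange storage-xylem conductance (cm3 MPa-1 s-1), or `NULL`
#'   to inherit `K_x0`
#' @return an object of class `storage_params` with derived capacitance `C`
#' @export
storage_params <- function(V_max, psi_empty = -4.5, k_exchange = NULL) {
  stopifnot(V_max >= 0, psi_empty < 0)
  if (!is.null(k_exchange)) stopifnot(k_exchange > 0)
  structure(list(V_max = V_max, psi_empty = psi_empty,
                 C = V_max / abs(psi_empty), k_exchange = k_exchange),
            class = "storage_params")
}

#' Storage capacity as a fraction of daily transpiration demand
#'
#' The sensitivity experiments size plant water storage by multiplying the
#' daily integral of the evaporative demand by a factor
#' (0, 20, 50, 100, 200 percent).
#'
#' @param fraction storage capacity as a fraction of `daily_demand`
#' @param daily_demand daily demand integral (cm3); the default is the
#'   integral of the default half-sine day, `2 * 0.3 * 43200 / pi`
#' @param ... passed to [storage_params()]
#' @return a `storage_params` object
#' @export
storage_from_fraction <- function(fraction,
                                  daily_demand = 2 * 0.3 * 43200 / pi, ...) {
  stopifnot(fraction >= 0, daily_demand > 0)
  storage_params(V_max = fraction * daily_demand, ...)
}

#' Stomatal regulation strategy
#'
#' `mode = "fixed"` closes stomata so leaf water potential never falls below
#' `psi_lim` (isohydric; -1.7 MPa as observed for spruce).
#' `mode = "flexible"` closes at the onset point maximizing
#' \eqn{E / (-\Psi_{leaf} + \epsilon)} along the current supply curve
#' (anisohydric; \eqn{\epsilon} = 0.2 MPa, as observed for beech).
#' `mode = "none"` imposes the demand unchanged.
#'
#' @param mode `"fixed"`, `"flexible"` or `"none"`
#' @param psi_lim leaf water potential floor (MPa) for the fixed mode
#' @param epsilon regularizing offset (MPa) for the flexible mode
#' @return an object of class `strategy_spec`
#' @export
strategy_spec <- function(mode = c("none", "fixed", "flexible"),
                          psi_lim = -1.7, epsilon = 0.2) {
  mode <- match.arg(mode)
  stopifnot(psi_lim < 0, epsilon > 0)
  structure(list(mode = mode, psi_lim = psi_lim, epsilon = epsilon),
            class = "strategy_spec")
}

#' Numerical solver configuration
#'
#' The xylem-potential fixed point is damped by averaging each new iterate
#' with the previous one (`damping = 0.5` is the arithmetic mean) and stops
#' once subsequent iterates are less than `tol` (default 5e-5 MPa) apart.
#'
#' @param tol convergence tolerance on the xylem potential iterate (MPa)
#' @param damping weight of the new iterate in the damped update (0, 1]
#' @param max_iter iteration guard
#' @param dt time-step length (s)
#' @param psi_floor most negative leaf water potential scanned when locating
#'   the flexible onset (MPa)
#' @param n_grid number of points on the supply-curve grid
#' @return an object of class `solver_config`
#' @export
solver_config <- function(tol = 5e-5, damping = 0.5, max_iter = 500,
                          dt = 60, psi_floor = -4.5, n_grid = 400) {
  stopifnot(tol > 0, damping > 0, damping <= 1, max_iter >= 1, dt > 0,
            psi_floor < 0, n_grid >= 10)
  structure(list(tol = tol, damping = damping, max_iter = max_iter, dt = dt,
                 psi_floor = psi_floor, n_grid = n_grid),
            class = "solver_config")
}

#' Assemble a soil-plant hydraulic system
#'
#' Bundles soil, plant and storage parameters with the derived soil-domain
#' geometry (bulk-soil radius from the accessible volume, root length and
#' root radius) and the resistor topology. In the default `"lumped"`
#' topology the plant pathway carries one overall soil-plant resistance
#' from the root-soil interface to the xylem node, the leaf sits at that
#' node, and the storage branch (conductance `k_exchange`) feeds it: the
#' total plant resistance equals the calibrated 1/K_x0, consistent with how
#' K_x0 is estimated from leaf measurements. The `"branched"` topology adds
#' a further full 1/K_x0 segment from the xylem node to the leaf.
#'
#' @param soil a [soil_params()] object
#' @param plant a [plant_params()] object
#' @param storage a [storage_params()] object or `NULL` for no storage
#' @param V_s root-accessible soil volume (cm3)
#' @param topology `"lumped"` (default) or `"branched"`
#' @return an object of class `hydraulic_system`
#' @export
hydraulic_system <- function(soil = soil_params(), plant = plant_preset(),
                             storage = NULL, V_s = 1e6 / 3,
                             topology = c("lumped", "branched")) {
  topology <- match.arg(topology)
  stopifnot(inherits(soil, "soil_params"), inherits(plant, "plant_params"))
  if (is.null(storage)) storage <- storage_params(V_max = 0)
  stopifnot(inherits(storage, "storage_params"))
  if (is.null(storage$k_exchange)) storage$k_exchange <- plant$K_x0
  domain <- soil_domain(V_s = V_s, r_root = plant$r_root_cm, L = plant$L_cm)
  structure(list(soil = soil, plant = plant, storage = storage,
                 domain = domain, topology = topology),
            class = "hydraulic_system")
}

#' @export
print.hydraulic_system <- function(x, ...) {
  cat("<hydraulic_system>\n")
  cat(sprintf("  plant: K_x0 = %.3g cm3/MPa/s, L = %.5g m, h_x0 = %.3g MPa, b_x = %.3g\n",
              x$plant$K_x0, x$plant$L_m, x$plant$h_x0, x$plant$b_x))
  cat(sprintf("  soil:  theta_s/r = %.3g/%.3g, lambda = %.4g, psi_e = %.3g MPa, K_s = %.3g\n",
              x$soil$theta_s, x$soil$theta_r, x$soil$lambda_bc, x$soil$psi_e,
              x$soil$K_s))
  cat(sprintf("  storage: V_max = %.5g cm3 (C = %.4g cm3/MPa, empty at %.3g MPa), k = %.3g\n",
              x$storage$V_max, x$storage$C, x$storage$psi_empty,
              x$storage$k_exchange))
  cat(sprintf("  domain: V_s = %.5g cm3, r_root = %.3g cm, r_b = %.4g cm; topology %s\n",
              x$domain$V_s, x$domain$r_root, x$domain$r_b, x$topology))
  invisible(x)
}
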