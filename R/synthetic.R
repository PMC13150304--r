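#' Specification for the synthetic-data generators
#'
#' Bundles the ground truth, noise levels and design of the three synthetic
#' observation kinds (leaf campaigns, diel sensor series, root-segment
#' drydowns). Identical specs produce identical output.
#'
#' Noise defaults (10 percent relative on stomatal conductance, 0.1 MPa on
#' leaf water potential) emulate the scatter of midday porometer/pressure-
#' chamber campaigns; high-frequency sensor noise on water content is
#' small (2e-4).
#'
#' @param seed integer RNG seed
#' @param K_x0,L_m,h_x0,b_x true plant parameters (see [plant_params()])
#' @param C_true true capacitance slope for drydowns (kg MPa-1 kg-1)
#' @param lag_h imposed sap-flow to root-water-uptake lag (h)
#' @param gs_rel_sd relative noise sd on stomatal conductance
#' @param psi_sd absolute noise sd on leaf/xylem potential (MPa)
#' @param theta_sd absolute noise sd on water content (fraction)
#' @param mass_rel_sd relative noise sd on segment mass (laboratory
#'   balances resolve far below a percent of a root segment's weight)
#' @param n_records campaign records per tree (the field study collected
#'   217 beech and 189 spruce records over two trees per species)
#' @param n_readings instrument readings averaged into each record (the
#'   field protocol took at least two readings per tree and averaged them),
#'   so record-level noise is the per-reading sd over `sqrt(n_readings)`
#' @param n_trees trees per species in the campaign
#' @param psi_soil_range campaign range of true soil potentials (MPa)
#' @param wet_frac fraction of records measured under near-saturated soil
#'   (post-rain campaigns, soil potential -0.05 to -0.01 MPa); these make
#'   the near-zero-soil-potential assumption behind the conductance
#'   estimator realistic, as in the field
#' @param demand_range campaign range of evaporative demand (cm3 s-1)
#' @param n_days diel series length (d)
#' @param dt_min diel sampling interval (min)
#' @param bimodal_sap add the second (morning) sap-flow peak
#' @param wet_day_prob probability a day carries precipitation
#' @return a list of class `generator_spec`
#' @export
generator_spec <- function(seed = 1, K_x0 = 0.71, L_m = 27375, h_x0 = -1.7,
                           b_x = 2, C_true = 0.136, lag_h = 2,
                           gs_rel_sd = 0.1, psi_sd = 0.1, theta_sd = 2e-4,
                           mass_rel_sd = 0.002,
                           n_records = 108, n_readings = 2, n_trees = 2,
                           psi_soil_range = c(-2, -0.01), wet_frac = 0.15,
                           demand_range = c(0.3, 0.9),
                           n_days = 30, dt_min = 10,
                           bimodal_sap = FALSE, wet_day_prob = 0.2) {
  stopifnot(gs_rel_sd >= 0, psi_sd >= 0, theta_sd >= 0, mass_rel_sd >= 0,
            n_records >= 1, n_trees >= 1, n_days >= 1, dt_min > 0,
            C_true >= 0)
  structure(as.list(environment()), class = "generator_spec")
}

#' Generate a synthetic leaf campaign with known truth
#'
#' Forward-simulates the storage-free, lumped-resistance chain with the
#' spec's true plant parameters under the flexible stomatal strategy:
#' per record a true soil potential and an evaporative demand are drawn,
#' transpiration is the demand capped at the current onset, the leaf water
#' potential follows from the chain, and the transpiration is back-converted
#' to stomatal conductance through a drawn leaf VPD and atmospheric
#' pressure. Gaussian noise is then added per the generator settings.
#'
#' @param spec a [generator_spec()]
#' @param soil a [soil_params()]
#' @param species species label written to the table
#' @return data frame with columns `tree_id`, `species`, `datetime`,
#'   `gs_mmol_m2_s`, `psi_leaf_MPa`, `vpd_leaf_kPa`, `p_atm_kPa`, and the
#'   ground-truth helpers `psi_soil_MPa`, `E_true`
#' @export
gen_campaign <- function(spec = generator_spec(), soil = soil_params(),
                         species = "beech") {
  set.seed(spec$seed)
  sys <- hydraulic_system(
    soil, plant_params(spec$K_x0, spec$L_m, spec$h_x0, spec$b_x),
    topology = "lumped")
  solver <- solver_config(n_grid = 200)
  rows <- list()
  for (tree in seq_len(spec$n_trees)) {
    psi_soil <- stats::runif(spec$n_records, min(spec$psi_soil_range),
                             max(spec$psi_soil_range))
    n_wet <- round(spec$wet_frac * spec$n_records)
    # the season's peak-demand days fall within wet spells: non-wet records
    # keep a small demand headroom below the campaign maximum, so the
    # maximum-transpiration measurement occurs under near-saturated soil --
    # the condition the conductance estimator requires and that the field
    # campaign verified for its own maximum
    demand <- stats::runif(spec$n_records, min(spec$demand_range),
                           0.95 * max(spec$demand_range))
    if (n_wet > 0) {
      psi_soil[seq_len(n_wet)] <- stats::runif(
        n_wet, max(-0.05, min(spec$psi_soil_range)),
        max(spec$psi_soil_range))
      demand[seq_len(n_wet)] <-
        if (n_wet == 1) max(spec$demand_range)
        else seq(min(spec$demand_range), max(spec$demand_range),
                 length.out = n_wet)
    }
    vpd <- stats::runif(spec$n_records, 0.8, 2.5)
    p_atm <- 96
    E <- psi_leaf <- numeric(spec$n_records)
    for (i in seq_len(spec$n_records)) {
      on <- suppressWarnings(
        flexible_onset(sys, psi_soil[i], NULL, 0.2, solver,
                       E_max = max(spec$demand_range)))
      E[i] <- min(demand[i], on$E_lim)
      psi_leaf[i] <- solve_chain(E[i], psi_soil[i], sys,
                                 solver = solver)$psi_leaf
    }
    gs <- transpiration_to_conductance(E, vpd, p_atm)
    # each record averages n_readings noisy instrument readings
    gs_noise <- rowMeans(matrix(stats::rnorm(spec$n_records * spec$n_readings,
                                             0, spec$gs_rel_sd),
                                spec$n_records))
    psi_noise <- rowMeans(matrix(stats::rnorm(spec$n_records * spec$n_readings,
                                              0, spec$psi_sd),
                                 spec$n_records))
    gs <- gs * (1 + gs_noise)
    psi_obs <- psi_leaf + psi_noise
    rows[[tree]] <- data.frame(
      tree_id = sprintf("%s_%02d", species, tree), species = species,
      datetime = sprintf("2022-06-%02d 11:00", (seq_len(spec$n_records) %% 28) + 1),
      gs_mmol_m2_s = pmax(gs, 0), psi_leaf_MPa = pmin(psi_obs, 0),
      vpd_leaf_kPa = vpd, p_atm_kPa = p_atm,
      psi_soil_MPa = psi_soil, E_true = E)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic diel sensor series with an imposed lag
#'
#' Sap-flux density follows a half-sine day cycle (optionally with a second
#' morning peak); root water uptake is the same cycle shifted by the
#' imposed lag, balanced by a flat nocturnal recharge so the soil-moisture
#' drawdown is periodic. Water content is the cumulative drawdown plus
#' sensor noise, so the smoothed uptake peak recovered from it lags the
#' sap-flow peak by exactly `lag_h`. Days flagged wet carry 1 mm of
#' precipitation.
#'
#' @param spec a [generator_spec()]
#' @param sap_peak_hour clock hour of the (afternoon) sap-flow peak
#' @param theta0 initial water content (fraction)
#' @param drawdown daily uptake drawdown amplitude (fraction of content)
#' @return data frame with columns `t` (s), `day`, `qs`, `theta`,
#'   `precip_mm_day`; attribute `wet_days` marks the precipitation days
#' @export
gen_diel <- function(spec = generator_spec(), sap_peak_hour = 12.5,
                     theta0 = 0.35, drawdown = 0.015) {
  set.seed(spec$seed + 1L)
  dt <- spec$dt_min * 60
  t <- seq(0, spec$n_days * 86400 - dt, by = dt)
  hour <- (t %% 86400) / 3600
  half_sine <- function(h, center, width = 12) {
    x <- (h - (center - width / 2)) / width
    ifelse(x > 0 & x < 1, sin(pi * x), 0)
  }
  qs <- half_sine(hour, sap_peak_hour)
  if (spec$bimodal_sap)
    qs <- qs + 1.2 * exp(-((hour - 9) / 1.2)^2 / 2)
  day_amp <- 1 + 0.1 * stats::rnorm(spec$n_days)
  qs <- qs * day_amp[t %/% 86400 + 1]
  qs <- pmax(qs + stats::rnorm(length(t), 0, 0.02), 0)

  rwu_center <- sap_peak_hour + spec$lag_h
  rwu <- half_sine(hour, rwu_center)
  # flat nocturnal recharge balancing each day's uptake
  active <- rwu > 0
  rwu[!active] <- -sum(rwu[t < 86400]) / sum(!active[t < 86400])
  rate <- drawdown / (sum(half_sine(hour[t < 86400], rwu_center)) * dt)
  # trapezoidal cumulative drawdown: theta samples are instantaneous
  # states of the integrated rate, keeping the central-difference
  # derivative unbiased in time
  dtheta <- -rwu * rate * dt
  theta <- theta0 + cumsum(dtheta) - dtheta / 2
  theta <- theta + stats::rnorm(length(t), 0, spec$theta_sd)

  wet <- stats::runif(spec$n_days) < spec$wet_day_prob
  precip <- ifelse(wet, 1, 0)
  out <- data.frame(t = t, day = t %/% 86400, qs = qs, theta = theta,
                    precip_mm_day = precip[t %/% 86400 + 1])
  attr(out, "wet_days") <- wet
  attr(out, "dt") <- dt
  out
}

#' Generate a synthetic root-segment drydown
#'
#' Xylem potential declines monotonically while the segment dries on the
#' balance; relative storage `(wet - dry)/dry` is coupled linearly to the
#' potential with slope `C_true` inside the regression window and with
#' optional quadratic curvature outside it, emulating the saturated shoulder
#' of a pressure-volume curve.
#'
#' @param spec a [generator_spec()]
#' @param dry_mass_g segment dry mass (g)
#' @param psi_range potential span of the drydown (MPa)
#' @param n_obs number of records
#' @param curvature quadratic coefficient outside `psi_window`
#' @param psi_window linear window (MPa)
#' @return list with `series` (data frame `t`, `mass_g`, `psi_MPa`) and
#'   `dry_mass_g`
#' @export
gen_drydown <- function(spec = generator_spec(), dry_mass_g = 20,
                        psi_range = c(-3, -0.3), n_obs = 80,
                        curvature = 0.05, psi_window = c(-2.25, -1)) {
  stopifnot(spec$C_true > 0)
  set.seed(spec$seed + 2L)
  psi <- seq(max(psi_range), min(psi_range), length.out = n_obs)
  s0 <- 1
  rel <- s0 + spec$C_true * psi
  outside_hi <- psi > max(psi_window)
  rel[outside_hi] <- rel[outside_hi] +
    curvature * (psi[outside_hi] - max(psi_window))^2
  outside_lo <- psi < min(psi_window)
  rel[outside_lo] <- rel[outside_lo] -
    curvature * (psi[outside_lo] - min(psi_window))^2
  mass <- dry_mass_g * (1 + rel)
  mass <- mass * (1 + stats::rnorm(n_obs, 0, spec$mass_rel_sd))
  list(series = data.frame(t = seq(0, by = 1800, length.out = n_obs),
                           mass_g = mass, psi_MPa = psi),
       dry_mass_g = dry_mass_g)
}
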