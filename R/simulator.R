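#' Half-sine evaporative-demand forcing
#'
#' Builds the sinusoidal potential-transpiration boundary condition: a
#' half-sine over the daylight window of each 24-h cycle
#' (`E0 = peak * sin(pi * t / day_length)`), zero at night. The analytic
#' daily integral is `2 * peak * day_length_seconds / pi` (8250.8 cm3 for
#' the defaults).
#'
#' @param peak maximum demand (cm3 s-1)
#' @param day_length daylight duration (h)
#' @param total_length total forcing duration (h); multi-day when > 24
#' @param dt time step (s)
#' @return data frame with columns `t` (s) and `E0` (cm3 s-1); attribute
#'   `dt` holds the step
#' @export
sinusoidal_demand <- function(peak = 0.3, day_length = 12,
                              total_length = 24, dt = 60) {
  stopifnot(peak >= 0, day_length <= 24, day_length * 3600 >= dt,
            total_length >= day_length, dt > 0)
  t <- seq(0, total_length * 3600 - dt, by = dt)
  t_day <- t %% 86400
  E0 <- ifelse(t_day < day_length * 3600,
               peak * sin(pi * t_day / (day_length * 3600)), 0)
  out <- data.frame(t = t, E0 = pmax(E0, 0))
  attr(out, "dt") <- dt
  out
}

#' Run the capacitance-extended soil-plant hydraulic simulation
#'
#' Time-stepping engine. The plant (including the storage compartment)
#' starts in equilibrium with the soil at `init_psi_soil`. Each step the
#' imposed demand is limited by the stomatal strategy, the xylem potential
#' partitioning the actual transpiration into root uptake `Q_soil` and
#' storage discharge `Q_cap` is solved by the damped fixed point, and the
#' two reservoirs are updated: `V_cap <- V_cap - Q_cap dt` (clamped to
#' `[0, V_max]`), `V_soil <- V_soil - Q_soil dt`, with the potentials
#' refreshed from the retention curve and the linear pressure-volume
#' relation.
#'
#' @param forcing a forcing table from [sinusoidal_demand()] (columns `t`,
#'   `E0`, constant step)
#' @param sys a [hydraulic_system()]
#' @param strategy a [strategy_spec()]
#' @param solver a [solver_config()]
#' @param init_psi_soil initial soil water potential (MPa, <= 0)
#' @return data frame trajectory with one row per step: `t`, `E_demand`,
#'   `E`, `Q_soil`, `Q_cap`, `psi_soil`, `psi_sri`, `psi_x`, `psi_leaf`,
#'   `V_cap`, `V_soil_water` (volumes at the end of the step, potentials
#'   and fluxes during it)
#' @export
run_simulation <- function(forcing, sys, strategy = strategy_spec(),
                           solver = solver_config(), init_psi_soil = -0.01) {
  stopifnot(init_psi_soil <= 0, is.data.frame(forcing),
            all(c("t", "E0") %in% names(forcing)))
  dt <- attr(forcing, "dt")
  if (is.null(dt)) {
    dts <- diff(forcing$t)
    if (length(dts) && max(abs(dts - dts[1])) > 1e-9)
      stop("forcing grid must be uniform")
    dt <- if (length(dts)) dts[1] else solver$dt
  }
  n <- nrow(forcing)
  has_storage <- sys$storage$V_max > 0
  if (has_storage && init_psi_soil < sys$storage$psi_empty)
    stop("initial soil potential below the storage empty point")

  psi_soil <- init_psi_soil
  V_soil <- water_content(init_psi_soil, sys$soil) * sys$domain$V_s
  V_cap <- if (has_storage) equilibrium_volume(init_psi_soil, sys$storage) else 0
  psi_cap <- if (has_storage) init_psi_soil else NULL
  psi_x_prev <- init_psi_soil

  out <- data.frame(t = forcing$t, E_demand = forcing$E0, E = NA_real_,
                    Q_soil = NA_real_, Q_cap = NA_real_,
                    psi_soil = NA_real_, psi_sri = NA_real_,
                    psi_x = NA_real_, psi_leaf = NA_real_,
                    V_cap = NA_real_, V_soil_water = NA_real_)
  # flexible-strategy day state: the onset is located on the daily
  # E--psi_leaf trajectory (closure when the ratio E/(-psi_leaf+epsilon)
  # first decreases while demand still rises); after onset, leaf water
  # potential is held at its onset value
  closed <- FALSE; r_max <- 0; psi_at_rmax <- init_psi_soil
  E_dem_prev <- 0
  day_prev <- -1L

  for (k in seq_len(n)) {
    E_dem <- forcing$E0[k]
    day_k <- forcing$t[k] %/% 86400
    if (day_k != day_prev) {
      closed <- FALSE; r_max <- 0; E_dem_prev <- 0
      day_prev <- day_k
    }

    if (strategy$mode == "flexible" && E_dem > 0) {
      if (!closed) {
        tent <- solve_chain(E_dem, psi_soil, sys, psi_cap, solver,
                            psi_x_init = psi_x_prev)
        if (tent$limited) {
          closed <- TRUE
        } else {
          r_t <- E_dem / (-tent$psi_leaf + strategy$epsilon)
          if (E_dem > E_dem_prev && r_t < r_max) {
            closed <- TRUE
          } else if (r_t >= r_max) {
            r_max <- r_t; psi_at_rmax <- tent$psi_leaf
          }
        }
      }
      if (closed) {
        reg <- regulate(E_dem, sys, psi_soil, psi_cap,
                        strategy_spec("fixed", psi_lim = min(psi_at_rmax,
                                                             -1e-6)),
                        solver, psi_x_init = psi_x_prev)
      } else {
        reg <- list(E = E_dem)
      }
    } else {
      reg <- regulate(E_dem, sys, psi_soil, psi_cap, strategy, solver,
                      psi_x_init = psi_x_prev)
    }
    E_dem_prev <- E_dem

    sol <- solve_chain(reg$E, psi_soil, sys, psi_cap, solver,
                       psi_x_init = psi_x_prev)
    if (sol$limited)
      stop(sprintf(paste0("hydraulic limitation at t = %.0f s ",
                          "(E = %.4g, psi_soil = %.4g MPa): ",
                          "the stomatal strategy must reduce transpiration"),
                   forcing$t[k], reg$E, psi_soil))
    if (!all(sol$converged))
      stop(sprintf("solver failed to converge at t = %.0f s", forcing$t[k]))

    # reservoir updates
    if (has_storage) {
      V_cap_new <- min(max(V_cap - sol$Q_cap * dt, 0), sys$storage$V_max)
      Q_cap_eff <- (V_cap - V_cap_new) / dt  # truncated at the clamp
    } else {
      V_cap_new <- 0; Q_cap_eff <- 0
    }
    V_soil <- V_soil - sol$Q_soil * dt
    theta <- V_soil / sys$domain$V_s
    if (theta <= sys$soil$theta_r) {
      warning("soil dry-out during simulation; water content clamped")
      theta <- sys$soil$theta_r + 1e-6
      V_soil <- theta * sys$domain$V_s
    }
    psi_soil_new <- potential_from_content(min(theta, sys$soil$theta_s),
                                           sys$soil)

    out$E[k] <- reg$E
    out$Q_soil[k] <- sol$Q_soil
    out$Q_cap[k] <- Q_cap_eff
    out$psi_soil[k] <- psi_soil
    out$psi_sri[k] <- sol$psi_sri
    out$psi_x[k] <- sol$psi_x
    out$psi_leaf[k] <- sol$psi_leaf
    out$V_cap[k] <- V_cap_new
    out$V_soil_water[k] <- V_soil

    psi_soil <- psi_soil_new
    V_cap <- V_cap_new
    if (has_storage) psi_cap <- storage_potential(V_cap, sys$storage)
    psi_x_prev <- sol$psi_x
  }
  attr(out, "dt") <- dt
  attr(out, "init_psi_soil") <- init_psi_soil
  out
}

#' Per-day totals and peak timings of a simulated trajectory
#'
#' Trapezoidal daily integrals of transpiration, root water uptake and
#' storage discharge, the clock times of each flux's maximum (ties to the
#' earliest sample), the daily minimum leaf water potential, and the lag of
#' peak root water uptake behind peak transpiration.
#'
#' @param traj a trajectory from [run_simulation()]
#' @return data frame with one row per simulated day: `day`, `E_total`,
#'   `Q_soil_total`, `Q_cap_total` (cm3), `t_peak_E`, `t_peak_Q_soil`,
#'   `t_peak_Q_cap` (clock h), `lag_E_Q_soil` (h), `min_psi_leaf` (MPa)
#' @export
daily_summary <- function(traj) {
  if (!is.data.frame(traj) || nrow(traj) == 0) stop("empty trajectory")
  dt <- attr(traj, "dt")
  day <- traj$t %/% 86400
  trap <- function(t, y) {
    if (length(t) < 2) return(y * dt)
    sum(diff(t) * (head2(y) + tail2(y)) / 2)
  }
  rows <- lapply(split(seq_len(nrow(traj)), day), function(idx) {
    tr <- traj[idx, ]
    hour <- (tr$t %% 86400) / 3600
    peak_h <- function(y) hour[which.max(y)]
    data.frame(day = tr$t[1] %/% 86400,
               E_total = trap(tr$t, tr$E),
               Q_soil_total = trap(tr$t, tr$Q_soil),
               Q_cap_total = trap(tr$t, tr$Q_cap),
               t_peak_E = peak_h(tr$E),
               t_peak_Q_soil = peak_h(tr$Q_soil),
               t_peak_Q_cap = peak_h(tr$Q_cap),
               lag_E_Q_soil = peak_h(tr$Q_soil) - peak_h(tr$E),
               min_psi_leaf = min(tr$psi_leaf))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

head2 <- function(x) x[-length(x)]
tail2 <- function(x) x[-1]
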