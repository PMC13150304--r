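# Shared fixtures: default parameter sets and small helpers used across the
# suite. Everything is built in code; no data files.

default_soil <- soil_params()

avg_sys <- function(fraction = 0, ...) {
  storage <- if (fraction > 0) storage_from_fraction(fraction) else NULL
  hydraulic_system(default_soil, plant_preset("average"), storage, ...)
}

beech_sys <- function(...) {
  hydraulic_system(default_soil, plant_preset("beech"), ...)
}

# daily demand integral of the default half-sine day (analytic)
DAILY_DEMAND <- 2 * 0.3 * 43200 / pi

# independent radial-flow oracle: steady Darcy flow to a cylindrical root,
# marching dpsi/dr = Q / (2 pi r L K(psi)) across `shells` log-spaced shells
# from the root surface to the bulk radius, with the flux Q found so the
# outer boundary matches psi_bulk (no matric-flux-potential shortcut)
radial_flux_oracle <- function(psi_bulk, psi_sri, d, p, shells = 200) {
  du <- log(d$r_b / d$r_root) / shells   # march in u = log r
  outer_psi <- function(Q) {
    psi <- psi_sri
    for (i in seq_len(shells)) {         # RK2 midpoint on dpsi/du
      k1 <- conductivity(min(psi, 0), p)
      psi_half <- psi + Q / (2 * pi * d$L * k1) * du / 2
      k2 <- conductivity(min(psi_half, 0), p)
      psi <- min(psi + Q / (2 * pi * d$L * k2) * du, 0)
    }
    psi
  }
  hi <- soil_supply_max(psi_bulk, d, p)
  stats::uniroot(function(Q) outer_psi(Q) - psi_bulk,
                 lower = 0, upper = hi * 0.999999, tol = 1e-13)$root
}
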