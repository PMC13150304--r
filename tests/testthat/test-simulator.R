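test_that("half-sine forcing has the analytic daily volume", {
  f <- sinusoidal_demand(peak = 0.3, day_length = 12, total_length = 24,
                         dt = 60)
  expect_equal(max(f$E0), 0.3, tolerance = 1e-6)
  expect_equal(f$E0[f$t == 6 * 3600], 0.3)      # mid-day value = peak
  expect_equal(sum(f$E0) * 60, DAILY_DEMAND, tolerance = 1e-4)
  expect_true(all(f$E0[f$t >= 12 * 3600] == 0)) # night
  f0 <- sinusoidal_demand(peak = 0)
  expect_true(all(f0$E0 == 0))
})

test_that("zero-capacitance step matches an independent quadrature chain", {
  sys <- avg_sys()
  # oracle: invert the radial relation and the xylem segment by quadrature
  # root-finding, no Kirchhoff closed forms
  oracle_leaf <- function(E, psi_b) {
    d <- sys$domain; sp <- sys$soil; pp <- sys$plant
    flux_between <- function(ps) 2 * pi * d$L *
      stats::integrate(function(u) conductivity(u, sp), ps, psi_b,
                       rel.tol = 1e-12)$value / log(d$r_b / d$r_root)
    psi_sri <- stats::uniroot(function(ps) flux_between(ps) - E,
                              lower = -40, upper = psi_b,
                              tol = 1e-12)$root
    stats::uniroot(function(pl) stats::integrate(
      function(u) xylem_conductance(u, pp), pl, psi_sri,
      rel.tol = 1e-12)$value - E,
      lower = -40, upper = psi_sri, tol = 1e-12)$root
  }
  for (case in list(c(0.25, -0.3), c(0.1, -1.0), c(0.45, -0.1))) {
    f <- sinusoidal_demand(peak = case[1], total_length = 1, day_length = 1,
                           dt = 60)
    f$E0[] <- case[1]                           # constant demand, one hour
    tr <- run_simulation(f, sys, strategy_spec("none"),
                         init_psi_soil = case[2])
    expect_equal(tr$psi_leaf[1], oracle_leaf(case[1], case[2]),
                 tolerance = 1e-6)
  }
})

test_that("zero demand at equilibrium is a fixed point of the step", {
  sys <- avg_sys(fraction = 0.5)
  f <- sinusoidal_demand(peak = 0.3, total_length = 2, day_length = 2)
  f$E0[] <- 0
  tr <- run_simulation(f, sys, strategy_spec("none"), init_psi_soil = -0.4)
  expect_true(all(abs(tr$Q_soil) < 1e-12))
  expect_true(all(abs(tr$Q_cap) < 1e-12))
  expect_true(all(abs(tr$psi_leaf + 0.4) < 1e-9))
  expect_true(all(abs(tr$V_cap - tr$V_cap[1]) < 1e-9))
})

test_that("storage refills from the soil at night", {
  sys <- avg_sys(fraction = 0.5)
  tr <- run_simulation(sinusoidal_demand(), sys, strategy_spec("none"),
                       init_psi_soil = -0.2)
  night <- tr$t > 13 * 3600 & tr$t < 20 * 3600
  expect_true(all(tr$Q_cap[night] < 0))   # refilling
  expect_true(all(tr$Q_soil[night] > 0))  # sustained nocturnal uptake
  expect_gt(tr$V_cap[max(which(night))], tr$V_cap[min(which(night))])
})

test_that("water is conserved per step and over the run", {
  sys <- avg_sys(fraction = 0.5)
  tr <- run_simulation(sinusoidal_demand(), sys, strategy_spec("flexible"),
                       init_psi_soil = -0.6)
  dt <- attr(tr, "dt")
  # per-step partition: E = Q_soil + Q_cap
  expect_lt(max(abs(tr$E - tr$Q_soil - tr$Q_cap)), 1e-10)
  # cumulative closure against both reservoirs
  V_soil0 <- water_content(-0.6, sys$soil) * sys$domain$V_s
  V_cap0 <- equilibrium_volume(-0.6, sys$storage)
  lhs <- sum(tr$E) * dt
  rhs <- (V_soil0 - tr$V_soil_water[nrow(tr)]) +
         (V_cap0 - tr$V_cap[nrow(tr)])
  expect_equal(lhs, rhs, tolerance = 1e-3)
  # solver converged everywhere (run errors otherwise); iterate tolerance
  s <- hydrocap:::solve_chain(0.2, -0.6, sys, psi_cap = -0.8,
                              solver = solver_config())
  expect_true(all(s$converged))
})

test_that("unregulated wet-soil transpiration meets the demand", {
  sys <- avg_sys(fraction = 0.2)
  f <- sinusoidal_demand()
  tr <- run_simulation(f, sys, strategy_spec("none"), init_psi_soil = -0.01)
  expect_equal(tr$E, f$E0)
})

test_that("storage capacity lengthens the uptake lag and buffers the leaf", {
  f <- sinusoidal_demand()
  lags <- mins <- numeric(0)
  for (fr in c(0, 0.5, 2)) {
    ds <- daily_summary(run_simulation(f, avg_sys(fr), strategy_spec("none"),
                                       init_psi_soil = -0.1))
    lags <- c(lags, ds$lag_E_Q_soil)
    mins <- c(mins, ds$min_psi_leaf)
  }
  expect_equal(lags[1], 0)                 # no storage: peaks coincide
  expect_true(all(diff(lags) > 0))         # lag grows with capacity
  expect_true(all(diff(mins) > 0))         # leaf potential buffered
})

test_that("halving the time step barely changes daily transpiration", {
  sys <- avg_sys(fraction = 0.2)
  E_tot <- vapply(c(60, 30), function(dt) {
    tr <- run_simulation(sinusoidal_demand(dt = dt), sys,
                         strategy_spec("fixed"), init_psi_soil = -0.5)
    sum(tr$E) * dt
  }, numeric(1))
  expect_lt(abs(E_tot[2] - E_tot[1]) / E_tot[1], 1e-3)
})

test_that("daily summary integrals match a trapezoid oracle", {
  sys <- avg_sys(fraction = 0.2)
  tr <- run_simulation(sinusoidal_demand(), sys, strategy_spec("none"),
                       init_psi_soil = -0.1)
  ds <- daily_summary(tr)
  trap <- function(y) sum(diff(tr$t) * (y[-length(y)] + y[-1]) / 2)
  expect_equal(ds$E_total, trap(tr$E), tolerance = 1e-12)
  expect_equal(ds$Q_soil_total, trap(tr$Q_soil), tolerance = 1e-12)
  # near-complete overnight refill on a wet day: storage cycle closes
  expect_lt(abs(ds$Q_cap_total), 0.02 * ds$E_total)
  expect_error(daily_summary(tr[0, ]), "empty")
})

test_that("nocturnal uptake grows with capacity and shrinks as soil dries", {
  f <- sinusoidal_demand()
  night_uptake <- function(fr, ps, strat = "none") {
    tr <- run_simulation(f, avg_sys(fr), strategy_spec(strat),
                         init_psi_soil = ps)
    sum(tr$Q_soil[tr$t >= 12 * 3600]) * attr(tr, "dt")
  }
  u <- vapply(c(0.2, 0.5, 2), night_uptake, numeric(1), ps = -0.1)
  expect_true(all(u > 0))
  expect_true(all(diff(u) > 0))
  # gradient-limited regime: drier soil refills less overnight
  u_dry <- vapply(c(-0.8, -1.2, -1.6), function(ps)
    night_uptake(0.5, ps, "fixed"), numeric(1))
  expect_true(all(diff(u_dry) < 0))
})
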