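test_that("retention curve reproduces its anchors and limits", {
  p <- default_soil
  expect_equal(water_content(-1.5, p), 0.21, tolerance = 1e-10)
  expect_equal(water_content(p$psi_e, p), 0.533)
  expect_equal(water_content(-1e30, p), 0.03, tolerance = 1e-2)
  expect_equal(water_content(-1e-5, p), 0.533)  # above air entry: saturated
  expect_error(water_content(0.5, p), "<= 0")
  # strictly increasing in psi below air entry
  psis <- seq(-5, -0.01, length.out = 50)
  expect_true(all(diff(water_content(psis, p)) > 0))
})

test_that("retention inversion is exact and flags dry-out", {
  p <- default_soil
  set.seed(42)
  psis <- -exp(runif(100, log(0.002), log(5)))
  back <- potential_from_content(water_content(psis, p), p)
  expect_lt(max(abs(back - psis)), 1e-9)
  expect_equal(potential_from_content(0.533, p), p$psi_e)
  expect_equal(potential_from_content(0.21, p), -1.5, tolerance = 1e-9)
  expect_error(potential_from_content(0.6, p), "saturation")
  expect_warning(potential_from_content(0.02, p), "dry-out")
  expect_error(potential_from_content(0.02, p, clamp = FALSE), "dry-out")
})

test_that("conductivity follows the Brooks-Corey power law", {
  p <- default_soil
  expect_equal(conductivity(p$psi_e, p), p$K_s)
  expect_equal(conductivity(2 * p$psi_e, p), p$K_s * 0.5^p$N)
  psis <- seq(-3, -0.001, length.out = 200)
  K <- conductivity(psis, p)
  expect_true(all(K <= p$K_s + 1e-15))
  expect_true(all(diff(K) >= 0))
})

test_that("matric flux potential matches quadrature and differentiates to K", {
  p <- default_soil
  set.seed(7)
  for (i in 1:6) {
    ab <- sort(-exp(runif(2, log(0.005), log(4))))
    quad <- stats::integrate(function(u) conductivity(u, p), ab[1], ab[2],
                             rel.tol = 1e-10)$value
    closed <- matric_flux_potential(ab[2], p) - matric_flux_potential(ab[1], p)
    expect_equal(closed, quad, tolerance = 1e-3)
  }
  # a pair straddling the air-entry potential
  quad <- stats::integrate(function(u) conductivity(u, p), -0.01, -1e-4,
                           rel.tol = 1e-10)$value
  expect_equal(matric_flux_potential(-1e-4, p) -
                 matric_flux_potential(-0.01, p), quad, tolerance = 1e-3)
  # derivative by central differences
  for (psi in c(-2, -0.5, -0.05)) {
    h <- abs(psi) * 1e-6
    fd <- (matric_flux_potential(psi + h, p) -
             matric_flux_potential(psi - h, p)) / (2 * h)
    expect_equal(fd, conductivity(psi, p), tolerance = 1e-3)
  }
  expect_equal(matric_flux_potential(-1e6, p), 0, tolerance = 1e-12)
  # diverging integral is a configuration error
  bad <- soil_params(lambda_bc = 0.01)
  bad$N <- 0.9
  expect_error(matric_flux_potential(-1, bad), "diverges")
})

test_that("radial soil-to-root flow matches a 200-shell marching oracle", {
  set.seed(11)
  for (i in 1:5) {
    p <- soil_params(K_s = exp(runif(1, log(0.3), log(3))),
                     lambda_bc = runif(1, 0.1, 0.5))
    L <- exp(runif(1, log(5e5), log(3e6)))
    d <- soil_domain(V_s = 1e6 / 3, r_root = 0.05, L = L)
    psi_bulk <- -exp(runif(1, log(0.05), log(1.5)))
    psi_sri <- psi_bulk * exp(runif(1, log(1.2), log(3)))
    Q <- soil_to_root_flux(psi_bulk, psi_sri, d, p)
    Q_oracle <- radial_flux_oracle(psi_bulk, psi_sri, d, p)
    expect_equal(Q, Q_oracle, tolerance = 5e-3)
  }
})

test_that("flux vanishes at equal potentials and follows their ordering", {
  p <- default_soil
  d <- avg_sys()$domain
  expect_equal(soil_to_root_flux(-0.5, -0.5, d, p), 0)
  expect_gt(soil_to_root_flux(-0.3, -0.8, d, p), 0)
  expect_lt(soil_to_root_flux(-0.8, -0.3, d, p), 0)
})

test_that("interface potential inverts the radial flux", {
  p <- default_soil
  d <- avg_sys()$domain
  expect_equal(interface_potential(0, -0.4, d, p), -0.4)
  Qmax <- soil_supply_max(-0.4, d, p)
  Qs <- seq(0.05, 0.95, by = 0.1) * Qmax
  psi_sri <- vapply(Qs, interface_potential, numeric(1),
                    psi_bulk = -0.4, d = d, p = p)
  # strictly decreasing interface potential as uptake grows
  expect_true(all(diff(psi_sri) < 0))
  back <- vapply(psi_sri, function(ps) soil_to_root_flux(-0.4, ps, d, p),
                 numeric(1))
  expect_equal(back, Qs, tolerance = 1e-10)
  expect_error(interface_potential(Qmax * 1.01, -0.4, d, p), "limitation")
  # ceiling shrinks as the soil dries
  expect_lt(soil_supply_max(-1, d, p), soil_supply_max(-0.5, d, p))
})
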