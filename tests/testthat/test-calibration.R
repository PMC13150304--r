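test_that("conductance-transpiration conversion round-trips", {
  expect_equal(leaf_transpiration(0, 1.5, 96), 0)
  expect_equal(leaf_transpiration(200, 2.0, 100), 4.0)
  E <- leaf_transpiration(180, 1.4, 97)
  expect_equal(transpiration_to_conductance(E, 1.4, 97), 180)
})

test_that("whole-plant conductance estimator uses the max-flux record", {
  one <- data.frame(gs_mmol_m2_s = 60, psi_leaf_MPa = -1.2,
                    vpd_leaf_kPa = 1, p_atm_kPa = 100)
  expect_equal(estimate_Kx0(one), 0.6 / 100 / 1.2 * 100)  # = 0.5 scaled
  two <- data.frame(gs_mmol_m2_s = c(60, 60, 30),
                    psi_leaf_MPa = c(-1.2, -1.2, -2),
                    vpd_leaf_kPa = 1, p_atm_kPa = 100)
  expect_equal(estimate_Kx0(two), estimate_Kx0(one))  # duplicate max: tie-safe
  zero <- data.frame(gs_mmol_m2_s = 0, psi_leaf_MPa = -1,
                     vpd_leaf_kPa = 1, p_atm_kPa = 100)
  expect_error(estimate_Kx0(zero), "zero")
  dry <- data.frame(gs_mmol_m2_s = 60, psi_leaf_MPa = -1.2,
                    vpd_leaf_kPa = 1, p_atm_kPa = 100, psi_soil_MPa = -0.9)
  expect_warning(estimate_Kx0(dry), "assumption")
})

test_that("noise-free synthetic campaign recovers the true conductance", {
  spec <- generator_spec(seed = 11, gs_rel_sd = 0, psi_sd = 0,
                         n_records = 20, n_trees = 1,
                         psi_soil_range = c(-0.005, -0.002), wet_frac = 0.5)
  camp <- gen_campaign(spec)
  expect_equal(suppressWarnings(estimate_Kx0(camp)), 0.71, tolerance = 0.01)
})

test_that("envelope selection matches a per-bin enumeration oracle", {
  set.seed(21)
  n <- 40
  rec <- data.frame(gs_mmol_m2_s = runif(n, 10, 90),
                    psi_leaf_MPa = runif(n, -2.6, -1.0),
                    vpd_leaf_kPa = 1, p_atm_kPa = 100)
  env <- select_envelope(rec, n_bins = 8, psi_cutoff = -1.5)
  # oracle: enumerate bins over the filtered records
  E <- rec$gs_mmol_m2_s * 1 / 100
  keep <- rec$psi_leaf_MPa <= -1.5
  Ek <- E[keep]; Pk <- rec$psi_leaf_MPa[keep]
  edges <- seq(min(Ek), max(Ek), length.out = 9)
  expected <- c()
  for (b in 1:8) {
    lo <- edges[b]; hi <- edges[b + 1]
    inb <- which(if (b == 8) Ek >= lo & Ek <= hi else Ek >= lo & Ek < hi)
    if (length(inb)) expected <- c(expected, inb[which.min(Pk[inb])])
  }
  expect_setequal(round(env$E_leaf, 12), round(Ek[expected], 12))
  expect_lte(nrow(env), 8)
  # cutoff rule: nothing below the cutoff means no envelope
  wetrec <- rec; wetrec$psi_leaf_MPa <- wetrec$psi_leaf_MPa + 2
  expect_error(select_envelope(wetrec), "insufficient")
})

test_that("grid fit recovers parameters from an on-curve envelope", {
  soil <- default_soil
  sys <- hydraulic_system(soil, plant_preset("beech"), topology = "lumped")
  slv <- solver_config(n_grid = 100)
  curve <- onset_curve(sys, seq(-0.4, -2, by = -0.1), solver = slv)
  env <- data.frame(E_leaf = curve$E_lim, psi_leaf_MPa = curve$psi_leaf_lim)
  env <- env[env$psi_leaf_MPa <= -1.5, ]
  fit <- fit_L_hx0(env, soil, 0.71,
                   grid_L = c(18000, 27375, 40000),
                   grid_h = c(-2.1, -1.7, -1.3),
                   psi_soil_grid = seq(0, -2, by = -0.1), solver = slv)
  expect_equal(fit$L_m, 27375)
  expect_equal(fit$h_x0, -1.7)
  # refining the grid can only improve the achieved minimum
  fit2 <- fit_L_hx0(env, soil, 0.71,
                    grid_L = c(18000, 22000, 27375, 33000, 40000),
                    grid_h = c(-2.1, -1.9, -1.7, -1.5, -1.3),
                    psi_soil_grid = seq(0, -2, by = -0.1), solver = slv)
  expect_lte(fit2$sse, fit$sse)
})

test_that("species parameters are per-tree means", {
  spec <- generator_spec(seed = 31, gs_rel_sd = 0, psi_sd = 0,
                         n_records = 40, n_trees = 2)
  camp <- gen_campaign(spec)
  cal <- suppressWarnings(calibrate_campaign(
    camp, default_soil,
    grid_L = c(20000, 27375, 36000), grid_h = c(-2.0, -1.7, -1.4),
    psi_soil_grid = seq(0, -2, by = -0.2),
    solver = solver_config(n_grid = 80)))
  expect_equal(nrow(cal$per_tree), 2)
  expect_equal(cal$species$K_x0, mean(cal$per_tree$K_x0))
  expect_equal(cal$species$L_m, mean(cal$per_tree$L_m))
  expect_equal(cal$species$h_x0, mean(cal$per_tree$h_x0))
})

test_that("VPD correction rescales to the station mean and keeps order", {
  v <- c(1.2, 2.5, 1.8, 3.1)
  expect_equal(vpd_correct(v, v), v)
  expect_equal(vpd_correct(2 * v, v), v)
  corr <- vpd_correct(v, c(1.0, 1.9, 1.4, 2.2))
  expect_equal(order(corr), order(v))
  expect_error(vpd_correct(numeric(0), v), "empty")
})
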