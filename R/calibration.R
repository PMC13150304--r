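#' Leaf transpiration from stomatal conductance
#'
#' Converts porometer stomatal conductance to leaf-level transpiration by
#' multiplying with the leaf vapour pressure deficit over atmospheric
#' pressure, `E_leaf = g_s * vpd / p_atm`. The result is treated numerically
#' in the model's flux units for calibration.
#'
#' @param gs stomatal conductance (mmol m-2 s-1)
#' @param vpd leaf-level vapour pressure deficit (kPa)
#' @param p_atm atmospheric pressure (kPa)
#' @return leaf transpiration (model flux units)
#' @export
leaf_transpiration <- function(gs, vpd, p_atm) {
  stopifnot(all(gs >= 0), all(vpd > 0), all(p_atm > vpd))
  gs * vpd / p_atm
}

#' Back-convert transpiration to conductance units
#'
#' Inverse of [leaf_transpiration()] for plotting simulated onset curves in
#' conductance space: multiplies by the ratio of campaign-mean atmospheric
#' pressure to campaign-mean VPD.
#'
#' @param E transpiration (model flux units)
#' @param mean_vpd campaign-mean leaf VPD (kPa)
#' @param mean_p_atm campaign-mean atmospheric pressure (kPa)
#' @return stomatal conductance (mmol m-2 s-1)
#' @export
transpiration_to_conductance <- function(E, mean_vpd, mean_p_atm) {
  stopifnot(mean_vpd > 0, mean_p_atm > 0)
  E * mean_p_atm / mean_vpd
}

#' Estimate whole-plant conductance from a leaf campaign
#'
#' `K_x0 = max(E_leaf) / |psi_leaf|` at the record with the largest leaf
#' transpiration, assuming near-zero soil water potential and an intact
#' xylem at that measurement. If a `psi_soil_MPa` column is present and the
#' max-E record was taken under soil drier than -0.1 MPa, a warning flags
#' the violated assumption.
#'
#' @param records data frame for one tree with columns `gs_mmol_m2_s`,
#'   `psi_leaf_MPa`, `vpd_leaf_kPa`, `p_atm_kPa`
#' @return estimated maximum soil-plant conductance (cm3 MPa-1 s-1)
#' @export
estimate_Kx0 <- function(records) {
  E <- leaf_transpiration(records$gs_mmol_m2_s, records$vpd_leaf_kPa,
                          records$p_atm_kPa)
  if (all(E <= 0)) stop("all stomatal conductances are zero")
  i <- which.max(E)
  if (!is.null(records$psi_soil_MPa) && records$psi_soil_MPa[i] < -0.1)
    warning("max-E record taken under soil drier than -0.1 MPa; ",
            "the near-saturated-soil assumption behind K_x0 is violated")
  E[i] / abs(records$psi_leaf_MPa[i])
}

#' Select the stomatal-onset envelope of a leaf campaign
#'
#' Records assumed to lie near the onset of stomatal closure: the
#' measurements are binned into `n_bins` equal-width bins of leaf
#' transpiration and, per bin, the record with the most negative leaf water
#' potential is kept; leaf water potentials less negative than `psi_cutoff`
#' are discarded first. Empty bins are skipped; ties keep the first
#' occurrence.
#'
#' @inheritParams estimate_Kx0
#' @param n_bins number of equal-width transpiration bins
#' @param psi_cutoff discard records with `psi_leaf > psi_cutoff` (MPa)
#' @return the selected subset of `records` with an added `E_leaf` column
#' @export
select_envelope <- function(records, n_bins = 8, psi_cutoff = -1.5) {
  records$E_leaf <- leaf_transpiration(records$gs_mmol_m2_s,
                                       records$vpd_leaf_kPa,
                                       records$p_atm_kPa)
  keep <- records$psi_leaf_MPa <= psi_cutoff
  if (!any(keep))
    stop("insufficient data: no records at or below the potential cutoff")
  rec <- records[keep, , drop = FALSE]
  edges <- seq(min(rec$E_leaf), max(rec$E_leaf), length.out = n_bins + 1)
  if (edges[1] == edges[n_bins + 1]) {
    bin <- rep(1L, nrow(rec))
  } else {
    bin <- findInterval(rec$E_leaf, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
  }
  idx <- unlist(lapply(split(seq_len(nrow(rec)), bin),
                       function(i) i[which.min(rec$psi_leaf_MPa[i])]))
  out <- rec[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulated onset-of-closure curve across soil water potentials
#'
#' For each soil water potential on the grid, computes the flexible onset
#' point (maximum of `E / (-psi_leaf + epsilon)`) of the storage-free,
#' lumped-resistance chain with the soil potential held fixed -- the
#' configuration used for model calibration, where soil drying and
#' capacitance are neglected.
#'
#' @param sys a [hydraulic_system()]; storage is ignored
#' @param psi_soil_grid soil water potentials (MPa)
#' @param E_max maximum scanned transpiration (cm3 s-1); the calibration
#'   forcing raises demand linearly from 0 to 0.9
#' @param epsilon flexible-onset offset (MPa)
#' @param solver a [solver_config()]
#' @return data frame with columns `psi_soil`, `E_lim`, `psi_leaf_lim`
#' @export
onset_curve <- function(sys, psi_soil_grid = seq(0, -2, by = -0.05),
                        E_max = 0.9, epsilon = 0.2,
                        solver = solver_config()) {
  sys$storage <- storage_params(V_max = 0)
  sys$topology <- "lumped"
  rows <- lapply(psi_soil_grid, function(ps) {
    on <- suppressWarnings(
      flexible_onset(sys, ps, NULL, epsilon, solver, E_max = E_max))
    data.frame(psi_soil = ps, E_lim = on$E_lim,
               psi_leaf_lim = on$psi_leaf_lim)
  })
  do.call(rbind, rows)
}

#' Grid-search calibration of root length and vulnerability onset
#'
#' For every combination on the (L, h_x0) grid, simulates the onset-of-
#' closure curve (storage disabled, soil potential fixed per grid value,
#' demand 0 to `E_max`) and scores it against the envelope records: each
#' envelope point is matched to its nearest curve point in the
#' doubly-normalized plane and the summed squared error in both directions
#' -- transpiration normalized by the observed maximum, potential by the
#' observed minimum -- is minimized; the curve is treated as piecewise
#' linear between simulated soil potentials. Ties go to the smaller root
#' length.
#'
#' @param envelope output of [select_envelope()] (columns `E_leaf`,
#'   `psi_leaf_MPa`)
#' @param soil a [soil_params()]
#' @param K_x0 whole-plant conductance (from [estimate_Kx0()])
#' @param grid_L root-length grid (m)
#' @param grid_h vulnerability-onset grid (MPa)
#' @param psi_soil_grid soil potentials spanned by the simulated curve (MPa)
#' @param E_max top of the demand ramp (cm3 s-1)
#' @param epsilon flexible-onset offset (MPa)
#' @param b_x vulnerability exponent
#' @param V_s accessible soil volume (cm3)
#' @param solver a [solver_config()]
#' @return list with `L_m`, `h_x0`, `sse` (normalized), and the full `grid`
#'   of scores
#' @export
fit_L_hx0 <- function(envelope, soil, K_x0,
                      grid_L = exp(seq(log(1000), log(50000), length.out = 60)),
                      grid_h = seq(-4, -0.5, length.out = 71),
                      psi_soil_grid = seq(0, -2, by = -0.05),
                      E_max = 0.9, epsilon = 0.2, b_x = 2, V_s = 1e6 / 3,
                      solver = solver_config()) {
  stopifnot(nrow(envelope) > 0, length(grid_L) > 0, length(grid_h) > 0)
  E_obs <- envelope$E_leaf
  psi_obs <- envelope$psi_leaf_MPa
  sE <- max(E_obs); sP <- abs(min(psi_obs))
  if (sE <= 0 || sP <= 0) stop("degenerate envelope")
  # squared distance from each envelope point to the piecewise-linear
  # onset curve (nearest point on any segment) in the normalized plane
  score <- function(curve) {
    cx <- curve$E_lim / sE; cy <- curve$psi_leaf_lim / sP
    ax <- cx[-length(cx)]; ay <- cy[-length(cy)]
    dx <- diff(cx); dy <- diff(cy)
    len2 <- pmax(dx^2 + dy^2, 1e-300)
    sum(vapply(seq_along(E_obs), function(i) {
      px <- E_obs[i] / sE; py <- psi_obs[i] / sP
      tt <- pmin(pmax(((px - ax) * dx + (py - ay) * dy) / len2, 0), 1)
      min((px - (ax + tt * dx))^2 + (py - (ay + tt * dy))^2)
    }, numeric(1)))
  }
  grid <- expand.grid(L_m = grid_L, h_x0 = grid_h)
  grid$sse <- NA_real_
  best <- list(sse = Inf)
  for (j in seq_len(nrow(grid))) {
    sys <- hydraulic_system(
      soil, plant_params(K_x0 = K_x0, L_m = grid$L_m[j],
                         h_x0 = grid$h_x0[j], b_x = b_x),
      V_s = V_s, topology = "lumped")
    curve <- onset_curve(sys, psi_soil_grid, E_max, epsilon, solver)
    grid$sse[j] <- score(curve)
    if (grid$sse[j] < best$sse)   # strict: ties keep the earlier, smaller L
      best <- list(L_m = grid$L_m[j], h_x0 = grid$h_x0[j], sse = grid$sse[j])
  }
  best$grid <- grid
  best
}

#' Full calibration pipeline for a leaf campaign
#'
#' Per tree: estimates `K_x0`, selects the onset envelope, and grid-fits
#' `(L, h_x0)`; species parameters are the arithmetic means of the per-tree
#' values.
#'
#' @param campaign data frame with columns `tree_id`, `species`,
#'   `gs_mmol_m2_s`, `psi_leaf_MPa`, `vpd_leaf_kPa`, `p_atm_kPa`
#' @param soil a [soil_params()]
#' @param ... passed on to [fit_L_hx0()] (grids, solver, ...)
#' @return list with `per_tree` and `species` parameter tables
#' @export
calibrate_campaign <- function(campaign, soil = soil_params(), ...) {
  trees <- split(campaign, campaign$tree_id)
  per_tree <- do.call(rbind, lapply(names(trees), function(id) {
    rec <- trees[[id]]
    K <- estimate_Kx0(rec)
    env <- select_envelope(rec)
    fit <- fit_L_hx0(env, soil, K, ...)
    data.frame(tree_id = id, species = rec$species[1], K_x0 = K,
               L_m = fit$L_m, h_x0 = fit$h_x0, sse = fit$sse,
               n_envelope = nrow(env))
  }))
  species <- do.call(rbind, lapply(split(per_tree, per_tree$species),
    function(d) data.frame(species = d$species[1], K_x0 = mean(d$K_x0),
                           L_m = mean(d$L_m), h_x0 = mean(d$h_x0),
                           n_trees = nrow(d))))
  rownames(per_tree) <- rownames(species) <- NULL
  list(per_tree = per_tree, species = species)
}

#' Rescale leaf-level VPD against a reference station series
#'
#' Manual leaf VPD readings are prone to sensor overheating; the default
#' correction rescales them multiplicatively so the campaign-mean leaf VPD
#' equals the campaign-mean station VPD. Monotone, so within-day rank order
#' is preserved.
#'
#' @param vpd_leaf raw leaf-level VPD series (kPa)
#' @param vpd_station paired weather-station VPD series (kPa)
#' @return corrected leaf VPD (kPa)
#' @export
vpd_correct <- function(vpd_leaf, vpd_station) {
  if (length(vpd_leaf) == 0 || length(vpd_station) == 0)
    stop("empty VPD series")
  vpd_leaf * mean(vpd_station) / mean(vpd_leaf)
}
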