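# Core solver for the resistor-capacitor chain at one frozen reservoir state.
#
# Unknown: the xylem-node potential psi_x that makes the node flux balance
# close, E = Q_soil + Q_cap, with
#   Q_cap  = k_exchange (psi_cap - psi_x)                  (storage branch)
#   Q_soil = E - Q_cap
#   psi_sri from the radial soil solution at Q_soil
#   psi_x  from the interface->node xylem segment at Q_soil.
# Two solution methods share one chain sweep:
#   fixed_point - the damped iteration the simulator prescribes (average the
#     new iterate with the previous one, stop when successive iterates are
#     less than tol apart), with a guarded scalar bisection fallback for
#     states where the map is not a contraction (dry soil, strong storage
#     coupling);
#   bisection - a vectorized bracketed solve of the strictly decreasing
#     node-balance residual, used for whole supply-curve grids where points
#     at the supply ceiling make the fixed point cycle on the clamp.
# Without storage the chain is feed-forward and solved in one sweep.
#
# Vectorized over E (psi_soil and psi_cap are scalars). Fluxes that exceed
# the soil supply ceiling or the xylem carrying capacity are clamped to a
# tiny residual flux potential and flagged in `limited`; callers decide
# whether limitation is an error (unregulated runs) or a truncation point
# (supply curves).

solve_chain <- function(E, psi_soil, sys, psi_cap = NULL,
                        solver = solver_config(), psi_x_init = NULL,
                        method = c("fixed_point", "bisection")) {
  method <- if (identical(method, "bisection")) "bisection"
            else if (length(method) > 1) method[1] else method
  p <- sys$plant; soil <- sys$soil
  has_storage <- sys$storage$V_max > 0 && !is.null(psi_cap)
  k_ex <- sys$storage$k_exchange
  lumped <- identical(sys$topology, "lumped")
  nE <- length(E)

  # local copies of constants (hot loops; avoid repeated list access)
  G <- sys$domain$G
  Ks <- soil$K_s; psie <- soil$psi_e; Ns <- soil$N
  A_s <- Ks * abs(psie)^Ns / (Ns - 1)                  # phi = A_s |psi|^(1-Ns)
  phi_es <- Ks * abs(psie) / (Ns - 1)
  K0 <- p$K_x0; h0 <- p$h_x0; bx <- p$b_x
  A_x <- K0 * abs(h0)^bx / (bx - 1)                    # phi = A_x |psi|^(1-bx)
  phi_hx <- K0 * abs(h0) / (bx - 1)
  phix0 <- phi_hx + K0 * abs(h0)
  inv_Ns <- 1 / (Ns - 1); inv_bx <- 1 / (bx - 1)

  phi_s <- function(psi) {                              # soil Kirchhoff
    out <- phi_es + Ks * (psi - psie)
    low <- psi <= psie
    out[low] <- A_s * (-psi[low])^(1 - Ns)
    out
  }
  phi_s_inv <- function(phi) {
    out <- psie + (phi - phi_es) / Ks
    out[out > 0] <- 0
    low <- phi < phi_es
    out[low] <- -(A_s / phi[low])^inv_Ns
    out
  }
  phi_x <- function(psi) {
    out <- phi_hx + K0 * (psi - h0)
    low <- psi <= h0
    out[low] <- A_x * (-psi[low])^(1 - bx)
    out
  }
  phi_x_inv <- function(phi) {
    out <- h0 + (phi - phi_hx) / K0
    out[out > 0] <- 0
    low <- phi < phi_hx
    out[low] <- -(A_x / phi[low])^inv_bx
    out
  }

  phi_b <- phi_s(psi_soil)
  phi_soil_min <- phi_b * 1e-9
  phix_min <- phix0 * 1e-12

  # one sweep of the chain: psi_x -> implied new psi_x
  sweep_chain <- function(psi_x) {
    Q_cap <- if (has_storage) k_ex * (psi_cap - psi_x) else numeric(nE)
    Q_soil <- E - Q_cap
    phi_t <- phi_b - Q_soil * G
    lim <- phi_t <= phi_soil_min
    phi_t[lim] <- phi_soil_min
    psi_sri <- phi_s_inv(phi_t)
    phixt <- phi_x(psi_sri) - Q_soil
    limx <- phixt <= phix_min
    phixt[limx] <- phix_min
    list(psi_x = phi_x_inv(phixt), psi_sri = psi_sri,
         Q_cap = Q_cap, Q_soil = Q_soil, limited = lim | limx)
  }

  if (!has_storage) {
    sw <- sweep_chain(numeric(nE))  # Q_cap = 0: single direct sweep
    psi_x <- sw$psi_x
    iterations <- 1L
    converged <- rep(TRUE, nE)
  } else if (method == "bisection") {
    lo_def <- min(2 * solver$psi_floor, psi_soil - 1, -10)
    lo <- rep(lo_def, nE)
    hi <- rep(0, nE)
    if (!is.null(psi_x_init)) {
      # warm bracket around the previous solution, widened where invalid
      lo_w <- pmax(rep_len(psi_x_init, nE) - 0.6, lo_def)
      hi_w <- pmin(rep_len(psi_x_init, nE) + 0.6, 0)
      ok <- (sweep_chain(lo_w)$psi_x - lo_w > 0) &
            (sweep_chain(hi_w)$psi_x - hi_w <= 0)
      lo[ok] <- lo_w[ok]; hi[ok] <- hi_w[ok]
    }
    iterations <- 0L
    while (max(hi - lo) > solver$tol / 2) {
      mid <- (lo + hi) / 2
      up <- sweep_chain(mid)$psi_x - mid > 0
      lo[up] <- mid[up]
      hi[!up] <- mid[!up]
      iterations <- iterations + 1L
    }
    psi_x <- (lo + hi) / 2
    converged <- rep(TRUE, nE)
    sw <- sweep_chain(psi_x)
  } else {
    psi_x <- if (is.null(psi_x_init)) rep(psi_soil, nE)
             else rep_len(psi_x_init, nE)
    converged <- rep(FALSE, nE)
    iterations <- 0L
    repeat {
      sw <- sweep_chain(psi_x)
      psi_next <- solver$damping * sw$psi_x + (1 - solver$damping) * psi_x
      delta <- abs(psi_next - psi_x)
      psi_x <- psi_next
      iterations <- iterations + 1L
      converged <- delta < solver$tol
      if (all(converged) || iterations >= solver$max_iter) break
    }
    if (!all(converged)) {
      # bisection fallback on the strictly decreasing residual
      for (i in which(!converged)) {
        Ei <- E[i]
        f <- function(px) {
          Qc <- k_ex * (psi_cap - px)
          Qs <- Ei - Qc
          ps <- phi_s_inv(max(phi_b - Qs * G, phi_soil_min))
          phi_x_inv(max(phi_x(ps) - Qs, phix_min)) - px
        }
        psi_x[i] <- stats::uniroot(f, lower = -50, upper = 0,
                                   tol = solver$tol / 10)$root
        converged[i] <- TRUE
      }
    }
    # refresh fluxes and the interface potential at the solved node potential
    sw <- sweep_chain(psi_x)
  }

  limited <- sw$limited
  if (lumped) {
    psi_leaf <- psi_x
  } else {
    phil_t <- phi_x(psi_x) - E
    limited <- limited | phil_t <= phix_min
    phil_t[phil_t <= phix_min] <- phix_min
    psi_leaf <- phi_x_inv(phil_t)
  }
  list(psi_sri = sw$psi_sri, psi_x = psi_x, psi_leaf = psi_leaf,
       Q_soil = sw$Q_soil, Q_cap = sw$Q_cap,
       limited = limited, converged = converged, iterations = iterations)
}
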