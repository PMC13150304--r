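#' Soil water content from matric potential
#'
#' Brooks-Corey retention: saturated at and above the air-entry potential,
#' power-law desaturation below it.
#'
#' @param psi matric potential (MPa, <= 0); vectorized
#' @param p a [soil_params()] object
#' @return volumetric water content (fraction)
#' @export
water_content <- function(psi, p) {
  if (any(psi > 0)) stop("matric potential must be <= 0 MPa")
  theta <- ifelse(psi >= p$psi_e, p$theta_s,
                  p$theta_r + (p$theta_s - p$theta_r) *
                    (p$psi_e / psi)^p$lambda_bc)
  theta
}

#' Matric potential from soil water content
#'
#' Exact inverse of [water_content()] on `(theta_r, theta_s]`. Contents at or
#' below the residual signal soil dry-out: by default the content is clamped
#' just above residual with a warning so long sensitivity sweeps can finish;
#' set `clamp = FALSE` to make dry-out an error.
#'
#' @param theta volumetric water content (fraction); vectorized
#' @param p a [soil_params()] object
#' @param clamp clamp dry-out at `theta_r + 1e-6` (warning) instead of erroring
#' @return matric potential (MPa)
#' @export
potential_from_content <- function(theta, p, clamp = TRUE) {
  if (any(theta > p$theta_s + 1e-12)) stop("water content above saturation")
  dry <- theta <= p$theta_r
  if (any(dry)) {
    if (!clamp) stop("soil dry-out: water content at or below residual")
    warning("soil dry-out: clamping water content just above residual")
    theta[dry] <- p$theta_r + 1e-6
  }
  s_eff <- (theta - p$theta_r) / (p$theta_s - p$theta_r)
  p$psi_e / s_eff^(1 / p$lambda_bc)
}

#' Unsaturated hydraulic conductivity
#'
#' Brooks-Corey/Burdine power law `K = K_s (psi_e/psi)^N` below air entry
#' with `N = 2 + 3 lambda`, saturated value above.
#'
#' @inheritParams water_content
#' @return conductivity (cm2 MPa-1 s-1)
#' @export
conductivity <- function(psi, p) {
  if (any(psi > 0)) stop("matric potential must be <= 0 MPa")
  ifelse(psi >= p$psi_e, p$K_s, p$K_s * (p$psi_e / psi)^p$N)
}

#' Matric flux potential (Kirchhoff transform of the soil)
#'
#' \deqn{\Phi(\psi) = \int_{-\infty}^{\psi} K(u)\,du,} in closed form
#' `K_s |psi_e|^N |psi|^(1-N) / (N-1)` for `psi <= psi_e`, continued linearly
#' with slope `K_s` up to 0. Strictly increasing; linearizes steady radial
#' flow to the root.
#'
#' @inheritParams water_content
#' @return matric flux potential (cm2 s-1)
#' @export
matric_flux_potential <- function(psi, p) {
  if (any(psi > 0)) stop("matric potential must be <= 0 MPa")
  if (p$N <= 1) stop("matric flux potential diverges for N <= 1")
  phi_e <- p$K_s * abs(p$psi_e) / (p$N - 1)
  ifelse(psi <= p$psi_e,
         p$K_s * abs(p$psi_e)^p$N * abs(psi)^(1 - p$N) / (p$N - 1),
         phi_e + p$K_s * (psi - p$psi_e))
}

# Inverse of the matric flux potential. phi must be positive and at most
# matric_flux_potential(0, p); values are produced by the radial-flow solver.
mfp_inverse <- function(phi, p) {
  phi_e <- p$K_s * abs(p$psi_e) / (p$N - 1)
  phi0 <- phi_e + p$K_s * abs(p$psi_e)
  if (any(phi <= 0)) stop("matric flux potential must be positive")
  phi <- pmin(phi, phi0)
  ifelse(phi >= phi_e,
         pmin(p$psi_e + (phi - phi_e) / p$K_s, 0),
         -(p$K_s * abs(p$psi_e)^p$N / ((p$N - 1) * phi))^(1 / (p$N - 1)))
}

#' Steady radial flow from bulk soil to the root surface
#'
#' Solves steady Darcy flow through the cylindrical soil shell between the
#' bulk-soil radius and the root surface with the matric-flux-potential
#' transform:
#' \deqn{Q = 2\pi L\,(\Phi(\psi_{bulk}) - \Phi(\psi_{sri})) / \ln(r_b/r_{root}).}
#' Positive when the bulk soil is wetter than the root-soil interface.
#'
#' @param psi_bulk bulk soil matric potential (MPa)
#' @param psi_sri root-soil interface potential (MPa)
#' @param d a [soil_domain()] object
#' @param p a [soil_params()] object
#' @return water flux (cm3 s-1)
#' @export
soil_to_root_flux <- function(psi_bulk, psi_sri, d, p) {
  (matric_flux_potential(psi_bulk, p) - matric_flux_potential(psi_sri, p)) / d$G
}

#' Maximum root water uptake the soil can supply
#'
#' The supply ceiling: the radial flux as the interface potential tends to
#' minus infinity (where the flux potential vanishes). Finite, and shrinking
#' as the bulk soil dries.
#'
#' @inheritParams soil_to_root_flux
#' @return ceiling flux (cm3 s-1)
#' @export
soil_supply_max <- function(psi_bulk, d, p) {
  matric_flux_potential(psi_bulk, p) / d$G
}

#' Root-soil interface potential implied by an uptake flux
#'
#' Inverts the radial-flow relation: the interface potential at which
#' [soil_to_root_flux()] equals `Q_soil` for the given bulk potential.
#' Fluxes at or above the supply ceiling signal hydraulic limitation.
#'
#' @param Q_soil root water uptake (cm3 s-1); may be negative (release)
#' @inheritParams soil_to_root_flux
#' @return interface potential (MPa)
#' @export
interface_potential <- function(Q_soil, psi_bulk, d, p) {
  phi_target <- matric_flux_potential(psi_bulk, p) - Q_soil * d$G
  if (any(phi_target <= 0))
    stop("hydraulic limitation: uptake flux at or above the soil supply ceiling")
  mfp_inverse(phi_target, p)
}
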