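#' Xylem hydraulic conductance (vulnerability curve)
#'
#' Constant at `K_x0` down to the onset potential `h_x0`, power-law decline
#' `K_x0 (h_x0/psi)^b_x` below it. Continuous at `h_x0`.
#'
#' @param psi_x xylem water potential (MPa, <= 0); vectorized
#' @param p a [plant_params()] object
#' @return conductance (cm3 MPa-1 s-1)
#' @export
xylem_conductance <- function(psi_x, p) {
  if (any(psi_x > 0)) stop("xylem potential must be <= 0 MPa")
  ifelse(psi_x >= p$h_x0, p$K_x0, p$K_x0 * (p$h_x0 / psi_x)^p$b_x)
}

#' Integrated xylem conductance (Kirchhoff transform of the pathway)
#'
#' \deqn{\Phi_x(\psi) = \int_{-\infty}^{\psi} K_x(u)\,du:} power-law tail
#' `K_x0 |h_x0|^b |psi|^(1-b) / (b-1)` below `h_x0` plus the linear plateau
#' above it. Segment transport is then exact:
#' `flux = Phi_x(psi_up) - Phi_x(psi_down)`, with no midpoint approximation
#' of the vulnerability curve.
#'
#' @inheritParams xylem_conductance
#' @return integrated conductance (cm3 s-1)
#' @export
xylem_kirchhoff <- function(psi_x, p) {
  if (any(psi_x > 0)) stop("xylem potential must be <= 0 MPa")
  if (p$b_x <= 1) stop("kirchhoff integral diverges for b_x <= 1")
  phi_h <- p$K_x0 * abs(p$h_x0) / (p$b_x - 1)
  ifelse(psi_x <= p$h_x0,
         p$K_x0 * abs(p$h_x0)^p$b_x * abs(psi_x)^(1 - p$b_x) / (p$b_x - 1),
         phi_h + p$K_x0 * (psi_x - p$h_x0))
}

# Inverse of xylem_kirchhoff; phi positive, capped at xylem_kirchhoff(0, p).
xylem_kirchhoff_inverse <- function(phi, p) {
  phi_h <- p$K_x0 * abs(p$h_x0) / (p$b_x - 1)
  phi0 <- phi_h + p$K_x0 * abs(p$h_x0)
  if (any(phi <= 0)) stop("integrated conductance must be positive")
  phi <- pmin(phi, phi0)
  ifelse(phi >= phi_h,
         pmin(p$h_x0 + (phi - phi_h) / p$K_x0, 0),
         -(p$K_x0 * abs(p$h_x0)^p$b_x / ((p$b_x - 1) * phi))^(1 / (p$b_x - 1)))
}

#' Potential downstream of a xylem segment carrying a given flux
#'
#' Solves `flux = Phi_x(psi_up) - Phi_x(psi_down)` for the downstream
#' potential. In the plateau regime this reduces to
#' `psi_down = psi_up - flux / K_x0`. A flux at or above `Phi_x(psi_up)`
#' cannot be carried by the segment (xylem limitation). Negative fluxes
#' (reverse flow) yield a downstream potential above the upstream one,
#' capped at 0 MPa.
#'
#' @param psi_up upstream potential (MPa)
#' @param flux segment flux (cm3 s-1)
#' @param p a [plant_params()] object
#' @return downstream potential (MPa)
#' @export
downstream_potential <- function(psi_up, flux, p) {
  phi <- xylem_kirchhoff(psi_up, p) - flux
  if (any(phi <= 0))
    stop("xylem limitation: segment cannot carry the requested flux")
  xylem_kirchhoff_inverse(phi, p)
}
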