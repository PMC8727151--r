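#' Root inclination across the shear zone
#'
#' Inclination of the deformed root segment spanning the shear zone,
#' `beta = arctan(u_x / Z)`, where `u_x` is the applied shear displacement
#' and `Z` the shear-zone thickness.
#'
#' @param u_x_mm Applied shear displacement (mm, >= 0). Vectorised.
#' @param Z_mm Shear-zone thickness (mm, > 0). Vectorised.
#' @return Angle in radians, in `[0, pi/2)`.
#' @export
compute_beta <- function(u_x_mm, Z_mm) {
  if (any(Z_mm <= 0)) stop("shear-zone thickness must be > 0 mm")
  if (any(u_x_mm < 0)) stop("shear displacement must be >= 0 mm")
  atan(u_x_mm / Z_mm)
}

#' Root-soil bond stress factor
#'
#' `k = sqrt(4 tau' Z E / D)`: the stress factor translating the limiting
#' interface stress, zone thickness, root stiffness and diameter into the
#' mobilisable root tensile stress. Inputs are in the field's customary
#' mixed units (kPa / mm / MPa); they are put onto a single stress-length
#' system (kPa, mm) internally, and the result is in kPa.
#'
#' @param tau_prime_kpa Limiting root-soil interface stress (kPa, > 0).
#' @param Z_mm Shear-zone thickness (mm, > 0).
#' @param E_mpa Root Young's modulus (MPa, > 0).
#' @param D_mm Root diameter (mm, > 0).
#' @return Stress factor k in kPa. Vectorised.
#' @export
bond_factor_k <- function(tau_prime_kpa, Z_mm, E_mpa, D_mm) {
  if (any(tau_prime_kpa <= 0) || any(Z_mm <= 0) ||
      any(E_mpa <= 0) || any(D_mm <= 0))
    stop("all inputs to bond_factor_k must be > 0")
  E_kpa <- E_mpa * 1000           # MPa -> kPa; Z/D is dimensionless
  sqrt(4 * tau_prime_kpa * Z_mm * E_kpa / D_mm)
}

#' Shear-resistance contribution of a single root
#'
#' The increase in soil shear resistance contributed by one root:
#' `dS_i = a_r_i * k * (sec beta - 1)^0.5 * (sin beta + cos beta tan phi')`,
#' combining the direct component of root tension in the shear direction
#' with the frictional component from the tension normal to the plane.
#'
#' @param root One-row root table (see [root()]).
#' @param a_r_i Per-root area ratio, `pi (D/2)^2 / plane_area` (>= 0).
#' @param u_x_mm Applied shear displacement (mm).
#' @param Z_mm Shear-zone thickness used for this root (mm).
#' @param soil A [soil_params()] object.
#' @param interface An [interface_params()] object.
#' @return Stress contribution in kPa (0 when `u_x_mm` is 0).
#' @export
root_delta_s <- function(root, a_r_i, u_x_mm, Z_mm, soil, interface) {
  if (any(a_r_i < 0)) stop("per-root area ratio must be >= 0")
  beta <- compute_beta(u_x_mm, Z_mm)
  k <- bond_factor_k(interface$tau_prime_kpa, Z_mm, root$E_MPa,
                     root$diameter_mm)
  a_r_i * k * sqrt(1 / cos(beta) - 1) *
    (sin(beta) + cos(beta) * tan(soil$phi_rad))
}

#' Root extension across the shear zone
#'
#' Change in length of the root segment spanning the zone under the
#' tri-linear deformation idealisation: `dl = Z (sec beta - 1)`.
#'
#' @param Z_mm Shear-zone thickness (mm, > 0).
#' @param beta_rad Root inclination (rad, in `[0, pi/2)`).
#' @return Extension in mm (0 iff beta is 0). Vectorised.
#' @export
root_extension <- function(Z_mm, beta_rad) {
  if (any(Z_mm <= 0)) stop("shear-zone thickness must be > 0 mm")
  if (any(beta_rad < 0) || any(beta_rad >= pi / 2))
    stop("beta must be in [0, pi/2)")
  Z_mm * (1 / cos(beta_rad) - 1)
}

#' Average axial stress in a stretched root
#'
#' Linear-elastic axial stress `sigma = (dl / l_0) E`. The stress is not
#' clipped; callers comparing against a tensile strength should use
#' [assumption_check()], which flags (rather than silently truncates)
#' stresses exceeding a configured strength fraction.
#'
#' @param delta_l_mm Root extension (mm, >= 0).
#' @param l0_mm Initial length of root under tension (mm, > 0).
#' @param E_mpa Root Young's modulus (MPa).
#' @return Axial stress in MPa. Vectorised.
#' @export
axial_stress <- function(delta_l_mm, l0_mm, E_mpa) {
  if (any(l0_mm <= 0)) stop("initial stressed length must be > 0 mm")
  if (any(delta_l_mm < 0)) stop("extension must be >= 0 mm")
  (delta_l_mm / l0_mm) * E_mpa
}

#' Length of root under stress
#'
#' The root length over which tension is transferred into the soil through
#' the limiting interface stress:
#' `l = sqrt(4 tau' Z E / D) * (sec beta - 1)^0.5 * D / (2 tau')`,
#' algebraically `k (sec beta - 1)^0.5 D / (2 tau')`.
#'
#' @inheritParams bond_factor_k
#' @param beta_rad Root inclination (rad, in `[0, pi/2)`).
#' @return Stressed length in mm (0 when beta is 0). Vectorised.
#' @export
stressed_length <- function(tau_prime_kpa, Z_mm, E_mpa, D_mm, beta_rad) {
  if (any(tau_prime_kpa <= 0)) stop("tau_prime must be > 0 kPa")
  if (any(beta_rad < 0) || any(beta_rad >= pi / 2))
    stop("beta must be in [0, pi/2)")
  k <- bond_factor_k(tau_prime_kpa, Z_mm, E_mpa, D_mm)
  k * sqrt(1 / cos(beta_rad) - 1) * D_mm / (2 * tau_prime_kpa)
}

# Per-root state (Z, beta, k, dS, extension, stressed length, axial stress)
# for one displacement under a zone-thickness policy. The workhorse behind
# specimen_delta_s / predict_stress_curve / assumption_check.
root_states <- function(spec, u_x_mm, Z_policy = c("constant", "positional",
                                                   "positional_with_growth"),
                        Z_mm = NULL) {
  Z_policy <- match.arg(Z_policy)
  roots <- spec$roots
  n <- nrow(roots)
  if (n == 0)
    return(data.frame(label = character(0), Z_mm = numeric(0),
                      beta_rad = numeric(0), k_kpa = numeric(0),
                      dS_kpa = numeric(0), delta_l_mm = numeric(0),
                      l_mm = numeric(0), sigma_axial_MPa = numeric(0),
                      stringsAsFactors = FALSE))
  zone <- spec$zone
  if (Z_policy == "constant") {
    if (is.null(Z_mm)) stop("constant policy requires Z_mm")
    Z <- rep_len(Z_mm, n)
  } else {
    d_root <- sqrt(roots$x_mm^2 + roots$y_mm^2)
    Z_peak <- local_shear_zone(zone, d_root)
    Z <- if (Z_policy == "positional") Z_peak
         else grown_shear_zone(zone, Z_peak, u_x_mm)
  }
  beta <- compute_beta(u_x_mm, Z)
  tau <- spec$interface$tau_prime_kpa
  k <- bond_factor_k(tau, Z, roots$E_MPa, roots$diameter_mm)
  a_r <- pi * (roots$diameter_mm / 2)^2 / spec$plane_area_mm2
  dS <- a_r * k * sqrt(1 / cos(beta) - 1) *
    (sin(beta) + cos(beta) * tan(spec$soil$phi_rad))
  dl <- Z * (1 / cos(beta) - 1)
  l <- k * sqrt(1 / cos(beta) - 1) * roots$diameter_mm / (2 * tau)
  sigma <- ifelse(l > 0, (dl / l) * roots$E_MPa, 0)
  data.frame(label = roots$label, Z_mm = Z, beta_rad = beta, k_kpa = k,
             dS_kpa = dS, delta_l_mm = dl, l_mm = l,
             sigma_axial_MPa = sigma, stringsAsFactors = FALSE)
}

#' Total root contribution to shear resistance of a specimen
#'
#' Sums the per-root contributions `dS_i` over all roots crossing the
#' shear plane. Three zone-thickness policies are supported:
#' `"constant"` (a single `Z_mm` for every root), `"positional"` (each
#' root's thickness from its distance to the tube centre, via
#' [local_shear_zone()]) and `"positional_with_growth"` (the positional
#' thickness additionally scaled by the displacement-dependent growth
#' schedule, via [grown_shear_zone()]).
#'
#' @param spec A [specimen()].
#' @param u_x_mm Applied shear displacement (mm, scalar).
#' @param Z_policy Zone-thickness policy (see Details).
#' @param Z_mm Thickness for the `"constant"` policy (mm).
#' @return Total root contribution dS in kPa (0 for a fallow specimen).
#' @export
specimen_delta_s <- function(spec, u_x_mm,
                             Z_policy = c("constant", "positional",
                                          "positional_with_growth"),
                             Z_mm = NULL) {
  st <- root_states(spec, u_x_mm, Z_policy, Z_mm)
  sum(st$dS_kpa)
}
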