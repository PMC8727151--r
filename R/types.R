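#' Construct a root crossing the shear plane
#'
#' A root is described by its position on the shear plane (tube-centred
#' coordinates), its diameter and its axial stiffness. Positions are in the
#' shear-plane (x, y) system with the origin at the tube centre.
#'
#' @param x_mm,y_mm Position on the shear plane (mm).
#' @param diameter_mm Root diameter at the shear plane (mm, > 0).
#' @param E_mpa Young's modulus of the root (MPa, > 0); willow roots are
#'   around 200 MPa, gorse around 500 MPa.
#' @param label Free-text identifier.
#' @return A one-row `data.frame` with columns `label`, `x_mm`, `y_mm`,
#'   `diameter_mm`, `E_MPa`. Root tables are plain data frames with these
#'   columns; several can be bound with `rbind()`.
#' @export
root <- function(x_mm, y_mm, diameter_mm, E_mpa, label = "root") {
  stopifnot(is.numeric(x_mm), is.numeric(y_mm))
  if (!is.numeric(diameter_mm) || diameter_mm <= 0)
    stop("root diameter must be > 0 (got ", diameter_mm, ")")
  if (!is.numeric(E_mpa) || E_mpa <= 0)
    stop("root Young's modulus must be > 0 (got ", E_mpa, ")")
  data.frame(label = as.character(label), x_mm = x_mm, y_mm = y_mm,
             diameter_mm = diameter_mm, E_MPa = E_mpa,
             stringsAsFactors = FALSE)
}

# validate a root table (data.frame with the canonical columns)
validate_roots <- function(roots, d_tube_mm = NULL) {
  need <- c("label", "x_mm", "y_mm", "diameter_mm", "E_MPa")
  miss <- setdiff(need, names(roots))
  if (length(miss))
    stop("root table is missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!(roots$diameter_mm > 0))
  if (length(bad))
    stop("non-positive root diameter at row ", bad[1])
  bad <- which(!(roots$E_MPa > 0))
  if (length(bad))
    stop("non-positive root stiffness at row ", bad[1])
  if (!is.null(d_tube_mm)) {
    d_root <- sqrt(roots$x_mm^2 + roots$y_mm^2)
    bad <- which(d_root > d_tube_mm / 2 + 1e-9)
    if (length(bad))
      stop("root outside the tube (d_root > D_tube/2) at row ", bad[1])
  }
  invisible(roots)
}

#' Soil parameters for the rooted direct-shear model
#'
#' @param phi_deg Internal angle of friction of the soil, in degrees
#'   (0 < phi < 90). Converted to radians once, at construction.
#' @param baseline Optional fallow (unrooted) baseline: a `data.frame` with
#'   columns `u_mm` (strictly increasing) and `S_kpa` (>= 0) giving the
#'   measured or fitted soil-alone shear stress against displacement. Total
#'   stress predictions are baseline + root contribution.
#' @return An object of class `soil_params`.
#' @export
soil_params <- function(phi_deg, baseline = NULL) {
  if (!is.numeric(phi_deg) || phi_deg <= 0 || phi_deg >= 90)
    stop("friction angle must be in (0, 90) degrees")
  if (!is.null(baseline)) {
    stopifnot(is.data.frame(baseline),
              all(c("u_mm", "S_kpa") %in% names(baseline)))
    if (any(diff(baseline$u_mm) <= 0))
      stop("baseline displacements must be strictly increasing")
    if (any(baseline$S_kpa < 0))
      stop("baseline stress must be >= 0")
  }
  structure(list(phi_deg = phi_deg, phi_rad = phi_deg * pi / 180,
                 baseline = baseline),
            class = "soil_params")
}

#' Root-soil interface parameters
#'
#' @param tau_prime_kpa Limiting bond / interface friction stress between
#'   root and soil (kPa, > 0). Encapsulates interface friction plus the
#'   anchoring effect of branches and laterals; typically obtained by
#'   back-analysis ([fit_tau_prime()]).
#' @return An object of class `interface_params`.
#' @export
interface_params <- function(tau_prime_kpa) {
  if (!is.numeric(tau_prime_kpa) || tau_prime_kpa <= 0)
    stop("tau_prime must be > 0 kPa")
  structure(list(tau_prime_kpa = tau_prime_kpa), class = "interface_params")
}

#' Shear-zone geometry and growth schedule
#'
#' Describes the spatially non-uniform shear zone in a cylindrical
#' direct-shear specimen: thickness varies linearly from `Z_max` at the tube
#' centre to `Z_min` at the wall (the tube gap), and grows with applied
#' shear displacement following a piecewise-linear schedule: 0 at zero
#' displacement, `f_step3` (default 80%) of peak at displacement `u_step3`
#' (the step where the zone is first clearly formed), and 100% at `u_final`.
#'
#' @param Z_min_mm Minimum thickness at the tube wall (mm); physically the
#'   gap between the two tube halves (2 mm in the reference apparatus).
#' @param Z_max_mm Maximum thickness at the tube centre (mm).
#' @param D_tube_mm Inner tube diameter (mm).
#' @param u_step3_mm,u_final_mm Growth-schedule displacements (mm).
#' @param f_step3 Fraction of peak thickness reached at `u_step3_mm`.
#' @param Z_floor_mm Lower clamp applied to the grown thickness (mm);
#'   defaults to `Z_min_mm` because the physical tube gap always exists.
#' @return An object of class `shear_zone_model`.
#' @export
shear_zone_model <- function(Z_min_mm = 2, Z_max_mm = 30, D_tube_mm = 103,
                             u_step3_mm = 8.15, u_final_mm = 19.83,
                             f_step3 = 0.8, Z_floor_mm = Z_min_mm) {
  if (!(Z_min_mm > 0 && Z_max_mm >= Z_min_mm))
    stop("need 0 < Z_min <= Z_max")
  if (D_tube_mm <= 0) stop("D_tube must be > 0")
  if (!(u_step3_mm > 0 && u_final_mm > u_step3_mm))
    stop("need 0 < u_step3 < u_final")
  if (!(f_step3 > 0 && f_step3 <= 1))
    stop("f_step3 must be in (0, 1]")
  structure(list(Z_min_mm = Z_min_mm, Z_max_mm = Z_max_mm,
                 D_tube_mm = D_tube_mm, u_step3_mm = u_step3_mm,
                 u_final_mm = u_final_mm, f_step3 = f_step3,
                 Z_floor_mm = Z_floor_mm),
            class = "shear_zone_model")
}

#' Assemble a direct-shear specimen
#'
#' @param roots Root table (`data.frame` as produced by [root()],
#'   [read_root_table()] or [generate_root_map()]); may have zero rows
#'   (fallow specimen).
#' @param soil A [soil_params()] object.
#' @param interface An [interface_params()] object.
#' @param zone A [shear_zone_model()] object.
#' @return An object of class `specimen`. The shear-plane area is
#'   `pi * (D_tube/2)^2`; the root area ratio (RAR) is the summed root
#'   cross-sectional area over that plane area.
#' @export
specimen <- function(roots, soil, interface, zone) {
  stopifnot(inherits(soil, "soil_params"),
            inherits(interface, "interface_params"),
            inherits(zone, "shear_zone_model"))
  if (is.null(roots))
    roots <- empty_root_table()
  validate_roots(roots, d_tube_mm = zone$D_tube_mm)
  area <- pi * (zone$D_tube_mm / 2)^2
  rar <- sum(pi * (roots$diameter_mm / 2)^2) / area
  if (rar >= 1) stop("root area ratio must be < 1")
  structure(list(roots = roots, soil = soil, interface = interface,
                 zone = zone, plane_area_mm2 = area, rar = rar),
            class = "specimen")
}

empty_root_table <- function() {
  data.frame(label = character(0), x_mm = numeric(0), y_mm = numeric(0),
             diameter_mm = numeric(0), E_MPa = numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.specimen <- function(x, ...) {
  cat("Direct-shear specimen\n")
  cat(sprintf("  roots: %d (RAR %.4f%%)\n", nrow(x$roots), 100 * x$rar))
  cat(sprintf("  phi' = %g deg, tau' = %g kPa\n",
              x$soil$phi_deg, x$interface$tau_prime_kpa))
  cat(sprintf("  zone: Z_min %g mm, Z_max %g mm, D_tube %g mm\n",
              x$zone$Z_min_mm, x$zone$Z_max_mm, x$zone$D_tube_mm))
  invisible(x)
}

#' @export
print.shear_zone_model <- function(x, ...) {
  cat(sprintf(
    "Shear-zone model: Z %g-%g mm across D_tube %g mm; growth 0 -> %g%% at %g mm -> 100%% at %g mm\n",
    x$Z_min_mm, x$Z_max_mm, x$D_tube_mm, 100 * x$f_step3,
    x$u_step3_mm, x$u_final_mm))
  invisible(x)
}
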