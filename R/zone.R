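#' Local shear-zone thickness at a root's position
#'
#' The shear zone in a cylindrical direct-shear specimen is a double cone:
#' thickest at the tube centre, pinched to the tube gap at the wall. The
#' local thickness at a root is interpolated linearly with the root's
#' distance from the centre:
#' `Z_root = Z_max - d_root (Z_max - Z_min) / (D_tube / 2)`.
#'
#' @param zone A [shear_zone_model()].
#' @param d_root_mm Distance of the root from the tube centre (mm), in
#'   `[0, D_tube/2]`. Vectorised.
#' @return Local thickness in mm: `Z_max` at the centre, `Z_min` at the wall.
#' @export
local_shear_zone <- function(zone, d_root_mm) {
  stopifnot(inherits(zone, "shear_zone_model"))
  R <- zone$D_tube_mm / 2
  if (any(d_root_mm < 0) || any(d_root_mm > R + 1e-9))
    stop("d_root must lie in [0, D_tube/2] (root outside tube)")
  zone$Z_max_mm - pmin(d_root_mm, R) * (zone$Z_max_mm - zone$Z_min_mm) / R
}

#' Displacement-dependent growth factor of the shear zone
#'
#' Piecewise-linear growth of the zone thickness with applied shear
#' displacement: 0 at zero displacement, `f_step3` (default 0.8) at
#' `u_step3`, 1 at `u_final`, clamped at 1 beyond.
#'
#' @param zone A [shear_zone_model()].
#' @param u_x_mm Applied shear displacement (mm, >= 0). Vectorised.
#' @return Growth factor in `[0, 1]`.
#' @export
growth_factor <- function(zone, u_x_mm) {
  stopifnot(inherits(zone, "shear_zone_model"))
  if (any(u_x_mm < 0)) stop("shear displacement must be >= 0 mm")
  u3 <- zone$u_step3_mm; uf <- zone$u_final_mm; f3 <- zone$f_step3
  f <- ifelse(u_x_mm <= u3,
              f3 * u_x_mm / u3,
              f3 + (1 - f3) * (u_x_mm - u3) / (uf - u3))
  pmin(f, 1)
}

#' Grown shear-zone thickness at a given displacement
#'
#' Scales a peak thickness by the growth factor and clamps from below at
#' the configured floor (default: the tube gap `Z_min`, which exists
#' physically at any displacement and keeps the inclination angle finite
#' at zero displacement).
#'
#' @param zone A [shear_zone_model()].
#' @param Z_peak_mm Peak (fully grown) thickness (mm). Vectorised.
#' @param u_x_mm Applied shear displacement (mm, >= 0).
#' @return Current thickness in mm, `max(f(u) * Z_peak, Z_floor)`.
#' @export
grown_shear_zone <- function(zone, Z_peak_mm, u_x_mm) {
  f <- growth_factor(zone, u_x_mm)
  pmax(f * Z_peak_mm, zone$Z_floor_mm)
}
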