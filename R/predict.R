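# evaluate the fallow baseline at displacements u (piecewise linear)
baseline_stress <- function(soil, u_mm, extrapolate = FALSE) {
  b <- soil$baseline
  if (is.null(b)) stop("specimen has no fallow baseline")
  if (!extrapolate &&
      (min(u_mm) < min(b$u_mm) - 1e-9 || max(u_mm) > max(b$u_mm) + 1e-9))
    stop("displacement outside the baseline domain ",
         "(set extrapolate = TRUE to clamp at the endpoints)")
  stats::approx(b$u_mm, b$S_kpa, xout = u_mm, rule = 2)$y
}

#' Predict a shear stress-displacement curve for a rooted specimen
#'
#' Assembles the total shear stress as fallow baseline plus the summed
#' root contribution at each displacement, under the chosen zone-thickness
#' policy. Per-root diagnostics (thickness, inclination, extension,
#' stressed length, axial stress) are attached for downstream validity
#' checks of the no-breakage / no-pull-out assumptions.
#'
#' @param spec A [specimen()]; must carry a baseline in its `soil` unless
#'   the specimen is fallow with `total` not requested.
#' @param u_grid_mm Displacements (mm), sorted ascending, first value >= 0.
#' @param Z_policy,Z_mm Zone-thickness policy, as in [specimen_delta_s()].
#' @param extrapolate Allow displacements beyond the baseline domain
#'   (clamped at the endpoint values).
#' @return A `data.frame` of class `shear_test_record` with columns
#'   `u_mm`, `dS_kpa`, `total_kpa`, and attributes `diagnostics` (long
#'   per-root, per-displacement table) and `Z_policy`.
#' @export
predict_stress_curve <- function(spec, u_grid_mm,
                                 Z_policy = c("constant", "positional",
                                              "positional_with_growth"),
                                 Z_mm = NULL, extrapolate = FALSE) {
  Z_policy <- match.arg(Z_policy)
  stopifnot(inherits(spec, "specimen"))
  if (is.unsorted(u_grid_mm, strictly = FALSE) || any(u_grid_mm < 0))
    stop("u_grid must be sorted ascending and >= 0")
  base <- baseline_stress(spec$soil, u_grid_mm, extrapolate)
  states <- lapply(u_grid_mm, function(u) root_states(spec, u, Z_policy, Z_mm))
  dS <- vapply(states, function(s) sum(s$dS_kpa), numeric(1))
  diag <- do.call(rbind, lapply(seq_along(u_grid_mm), function(i) {
    s <- states[[i]]
    if (nrow(s) == 0) return(NULL)
    cbind(u_mm = u_grid_mm[i], s)
  }))
  out <- data.frame(u_mm = u_grid_mm, dS_kpa = dS, total_kpa = base + dS)
  attr(out, "diagnostics") <- diag
  attr(out, "Z_policy") <- Z_policy
  class(out) <- c("shear_test_record", "data.frame")
  out
}

#' Sensitivity sweep of the root-reinforcement model
#'
#' Evaluates the single-root contribution `dS` and the stressed length `l`
#' over a grid of zone thicknesses, interface stresses and displacements,
#' for a root of diameter `D_mm` and stiffness `E_mpa` in a tube of
#' diameter `D_tube_mm`. Returns a tidy long table for plotting the
#' thickness / interface-stress sensitivity trends.
#'
#' @param Z_grid_mm Zone thicknesses (mm), e.g. `seq(2, 30, 4)`.
#' @param tau_grid_kpa Interface stresses (kPa), e.g. `seq(0.5, 5, 0.5)`.
#' @param u_grid_mm Displacements (mm), e.g. `seq(0, 20, 1)`.
#' @param D_mm,E_mpa Root diameter (mm) and stiffness (MPa).
#' @param phi_deg Soil friction angle (degrees).
#' @param D_tube_mm Tube diameter fixing the per-root area ratio.
#' @return `data.frame` with columns `Z_mm, tau_kpa, u_mm, dS_kpa, l_mm`.
#' @export
sensitivity_sweep <- function(Z_grid_mm = seq(2, 30, by = 4),
                              tau_grid_kpa = seq(0.5, 5, by = 0.5),
                              u_grid_mm = seq(0, 20, by = 1),
                              D_mm = 1, E_mpa = 200, phi_deg = 36,
                              D_tube_mm = 103) {
  stopifnot(all(Z_grid_mm > 0), all(tau_grid_kpa > 0), all(u_grid_mm >= 0),
            D_mm > 0, E_mpa > 0)
  grid <- expand.grid(Z_mm = Z_grid_mm, tau_kpa = tau_grid_kpa,
                      u_mm = u_grid_mm, KEEP.OUT.ATTRS = FALSE)
  a_r <- pi * (D_mm / 2)^2 / (pi * (D_tube_mm / 2)^2)
  phi <- phi_deg * pi / 180
  beta <- atan(grid$u_mm / grid$Z_mm)
  k <- bond_factor_k(grid$tau_kpa, grid$Z_mm, E_mpa, D_mm)
  grid$dS_kpa <- a_r * k * sqrt(1 / cos(beta) - 1) *
    (sin(beta) + cos(beta) * tan(phi))
  grid$l_mm <- k * sqrt(1 / cos(beta) - 1) * D_mm / (2 * grid$tau_kpa)
  grid
}
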