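#' Back-fit the root-soil interface stress from a measured record
#'
#' Finds the limiting interface stress tau' such that the modelled total
#' shear stress reproduces a measured stress-displacement record. Two fit
#' targets are supported: `"final"` matches the measured stress at a
#' single displacement (by default the record's last point) via bounded
#' scalar root finding, exploiting that the total stress is strictly
#' increasing in tau'; `"curve"` minimises the sum of squared stress
#' residuals over the whole record. Both are deterministic.
#'
#' @param record `data.frame` with columns `u_mm` (strictly increasing)
#'   and `S_kpa`.
#' @param spec A [specimen()]; its `interface` value is ignored (tau' is
#'   the unknown). Must contain at least one root.
#' @param Z_policy,Z_mm Zone-thickness policy, as in [specimen_delta_s()].
#' @param target `"final"` or `"curve"`.
#' @param u_target_mm Displacement at which the final-point fit matches
#'   (mm); default: the record's last displacement.
#' @param bounds_kpa Search interval for tau' (kPa).
#' @param extrapolate Passed to the baseline evaluation.
#' @return List of class `tau_fit`: `tau_prime_kpa`, `residual_kpa`
#'   (absolute stress misfit at the target, or RMS over the curve),
#'   `target`, `u_target_mm`, `diagnostics` (per-root state at the target
#'   displacement, for assumption checking).
#' @export
fit_tau_prime <- function(record, spec,
                          Z_policy = c("positional_with_growth",
                                       "positional", "constant"),
                          Z_mm = NULL, target = c("final", "curve"),
                          u_target_mm = NULL, bounds_kpa = c(0.01, 50),
                          extrapolate = FALSE) {
  Z_policy <- match.arg(Z_policy)
  target <- match.arg(target)
  stopifnot(is.data.frame(record),
            all(c("u_mm", "S_kpa") %in% names(record)))
  if (any(diff(record$u_mm) <= 0))
    stop("record displacements must be strictly increasing")
  if (nrow(spec$roots) == 0)
    stop("tau_prime is unidentifiable from a fallow record (no roots)")

  with_tau <- function(tau) {
    s <- spec
    s$interface <- interface_params(tau)
    s
  }
  if (target == "final") {
    u_t <- u_target_mm %||% max(record$u_mm)
    S_t <- stats::approx(record$u_mm, record$S_kpa, xout = u_t,
                         rule = 2)$y
    base_t <- baseline_stress(spec$soil, u_t, extrapolate)
    f <- function(tau)
      specimen_delta_s(with_tau(tau), u_t, Z_policy, Z_mm) + base_t - S_t
    flo <- f(bounds_kpa[1]); fhi <- f(bounds_kpa[2])
    if (flo * fhi > 0)
      stop(sprintf(
        "no tau' in [%g, %g] kPa matches the target stress (misfit %g to %g kPa)",
        bounds_kpa[1], bounds_kpa[2], flo, fhi))
    sol <- stats::uniroot(f, bounds_kpa, tol = 1e-10)
    tau_hat <- sol$root
    resid <- abs(f(tau_hat))
  } else {
    u_t <- max(record$u_mm)
    sse <- function(tau) {
      curve <- predict_stress_curve(with_tau(tau), record$u_mm, Z_policy,
                                    Z_mm, extrapolate = extrapolate)
      sum((curve$total_kpa - record$S_kpa)^2)
    }
    opt <- stats::optimize(sse, bounds_kpa, tol = 1e-9)
    tau_hat <- opt$minimum
    resid <- sqrt(opt$objective / nrow(record))
  }
  diag <- root_states(with_tau(tau_hat), u_t, Z_policy, Z_mm)
  structure(list(tau_prime_kpa = tau_hat, residual_kpa = resid,
                 target = target, u_target_mm = u_t, Z_policy = Z_policy,
                 diagnostics = diag),
            class = "tau_fit")
}

#' @export
print.tau_fit <- function(x, ...) {
  cat(sprintf("tau' = %.4f kPa (%s fit at u = %.2f mm, residual %.3g kPa)\n",
              x$tau_prime_kpa, x$target, x$u_target_mm, x$residual_kpa))
  invisible(x)
}

#' Check the no-breakage / no-pull-out model assumptions
#'
#' The reinforcement model assumes roots never break in tension and never
#' pull out. This report evaluates, per root at a given displacement, the
#' mobilised axial stress as a fraction of tensile strength and the
#' stressed length against the available root length, flagging violations
#' rather than altering the model output. Missing strength or length
#' inputs yield `NA` fractions (reported as unavailable, not as zero).
#'
#' @param spec A [specimen()] (with the tau' of interest set).
#' @param u_x_mm Displacement at which to evaluate (mm).
#' @param Z_policy,Z_mm As in [specimen_delta_s()].
#' @param tensile_strength_mpa Per-root tensile strength (MPa; recycled),
#'   or NULL if unavailable.
#' @param available_length_mm Per-root available root length (mm;
#'   recycled), or NULL.
#' @param strength_fraction Breakage flag threshold as a fraction of
#'   tensile strength (default 0.8).
#' @return List of class `assumption_report`: `per_root` (`data.frame`
#'   with stresses, lengths, fractions, flags), `no_breakage`,
#'   `no_pullout` (summary booleans; `NA` when inputs are unavailable).
#' @export
assumption_check <- function(spec, u_x_mm,
                             Z_policy = "positional_with_growth",
                             Z_mm = NULL, tensile_strength_mpa = NULL,
                             available_length_mm = NULL,
                             strength_fraction = 0.8) {
  st <- root_states(spec, u_x_mm, Z_policy, Z_mm)
  n <- nrow(st)
  frac <- if (is.null(tensile_strength_mpa)) rep(NA_real_, n)
          else st$sigma_axial_MPa / rep_len(tensile_strength_mpa, n)
  l_avail <- if (is.null(available_length_mm)) rep(NA_real_, n)
             else rep_len(available_length_mm, n)
  breakage <- frac > strength_fraction
  pullout <- st$l_mm > l_avail
  per_root <- cbind(st, strength_fraction = frac,
                    available_length_mm = l_avail,
                    breakage_flag = breakage, pullout_flag = pullout)
  structure(list(per_root = per_root,
                 no_breakage = if (all(is.na(breakage))) NA
                               else !any(breakage, na.rm = TRUE),
                 no_pullout = if (all(is.na(pullout))) NA
                              else !any(pullout, na.rm = TRUE),
                 u_x_mm = u_x_mm),
            class = "assumption_report")
}

#' @export
print.assumption_report <- function(x, ...) {
  cat(sprintf("Assumption check at u = %.2f mm: no breakage = %s, no pull-out = %s\n",
              x$u_x_mm, format(x$no_breakage), format(x$no_pullout)))
  invisible(x)
}
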