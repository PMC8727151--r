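#' Read a root table from CSV
#'
#' Expects the header `label,x_mm,y_mm,diameter_mm,E_MPa`, one row per
#' root crossing the shear plane. Rows are validated (positive diameter
#' and stiffness; inside the tube when `d_tube_mm` is given) and row order
#' is preserved.
#'
#' @param path CSV file path.
#' @param d_tube_mm Optional tube diameter for the inside-tube check (mm).
#' @return Root table `data.frame` with attribute `rar` when `d_tube_mm`
#'   is supplied.
#' @export
read_root_table <- function(path, d_tube_mm = NULL) {
  roots <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(roots) == 0) {
    roots <- empty_root_table()
  }
  validate_roots(roots, d_tube_mm = d_tube_mm)
  if (!is.null(d_tube_mm))
    attr(roots, "rar") <- sum(pi * (roots$diameter_mm / 2)^2) /
      (pi * (d_tube_mm / 2)^2)
  roots
}

#' Write a root table to CSV
#' @param roots Root table.
#' @param path Output CSV path.
#' @export
write_root_table <- function(roots, path) {
  utils::write.csv(roots, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a displacement field (plain-text container)
#'
#' A field is stored as two files sharing a stem: `<stem>.json` (metadata
#' sidecar: axes, pitch, step index, applied displacement, noise level)
#' and `<stem>.csv` (flat node table `ix,iy,iz,ux_mm,uy_mm,uz_mm,mask`).
#' Values are written with 17 significant digits so the round trip is
#' bit-identical.
#'
#' @param field A `displacement_field`.
#' @param stem Path stem (no extension).
#' @return `write_field` returns the stem invisibly; `read_field` returns
#'   the reconstructed `displacement_field`.
#' @export
write_field <- function(field, stem) {
  stopifnot(inherits(field, "displacement_field"))
  meta <- list(x_mm = field$x, y_mm = field$y, z_mm = field$z,
               pitch_mm = field$pitch_mm, step_index = field$step_index,
               u_applied_mm = field$u_applied_mm,
               noise_sd = field$noise_sd)
  jsonlite::write_json(meta, paste0(stem, ".json"), digits = NA,
                       auto_unbox = TRUE)
  dims <- dim(field$u)
  idx <- expand.grid(ix = seq_len(dims[1]), iy = seq_len(dims[2]),
                     iz = seq_len(dims[3]), KEEP.OUT.ATTRS = FALSE)
  lines <- c("ix,iy,iz,ux_mm,uy_mm,uz_mm,mask",
             sprintf("%d,%d,%d,%.17g,%.17g,%.17g,%d",
                     idx$ix, idx$iy, idx$iz,
                     as.vector(field$u[, , , 1]),
                     as.vector(field$u[, , , 2]),
                     as.vector(field$u[, , , 3]),
                     as.integer(as.vector(field$mask))))
  writeLines(lines, paste0(stem, ".csv"))
  invisible(stem)
}

#' @rdname write_field
#' @export
read_field <- function(stem) {
  jpath <- paste0(stem, ".json"); cpath <- paste0(stem, ".csv")
  if (!file.exists(jpath)) stop("missing field metadata sidecar: ", jpath)
  meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  if (is.null(meta$pitch_mm) || is.null(meta$x_mm))
    stop("field metadata missing pitch/axes (no silent defaults)")
  tab <- utils::read.csv(cpath)
  need <- c("ix", "iy", "iz", "ux_mm", "uy_mm", "uz_mm")
  if (!all(need %in% names(tab))) stop("field table missing columns")
  nx <- length(meta$x_mm); ny <- length(meta$y_mm); nz <- length(meta$z_mm)
  u <- array(NA_real_, dim = c(nx, ny, nz, 3))
  lin <- cbind(tab$ix, tab$iy, tab$iz)
  u[cbind(lin, 1)] <- tab$ux_mm
  u[cbind(lin, 2)] <- tab$uy_mm
  u[cbind(lin, 3)] <- tab$uz_mm
  mask <- array(TRUE, dim = c(nx, ny, nz))
  if ("mask" %in% names(tab)) {
    mask[lin] <- tab$mask != 0
  } else {
    warning("field has no mask column; assuming all nodes valid")
  }
  structure(list(x = meta$x_mm, y = meta$y_mm, z = meta$z_mm, u = u,
                 mask = mask, pitch_mm = meta$pitch_mm,
                 step_index = meta$step_index,
                 u_applied_mm = meta$u_applied_mm,
                 noise_sd = meta$noise_sd),
            class = "displacement_field")
}

#' Read a specimen configuration from JSON
#'
#' Keys: `phi_deg`, `tau_prime_kpa`, `Z_min_mm`, `Z_max_mm`, `D_tube_mm`,
#' `growth` (`u_step3_mm`, `u_final_mm`, `f_step3`), optional
#' `baseline_csv` (path, columns `u_mm,S_kpa`, resolved relative to the
#' JSON file) and optional `roots_csv`.
#'
#' @param path JSON file path.
#' @return A [specimen()].
#' @export
read_specimen_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("phi_deg", "tau_prime_kpa", "Z_min_mm", "Z_max_mm", "D_tube_mm")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("specimen config missing key(s): ", paste(miss, collapse = ", "))
  g <- cfg$growth %||% list()
  zone <- shear_zone_model(cfg$Z_min_mm, cfg$Z_max_mm, cfg$D_tube_mm,
                           u_step3_mm = g$u_step3_mm %||% 8.15,
                           u_final_mm = g$u_final_mm %||% 19.83,
                           f_step3 = g$f_step3 %||% 0.8)
  rel <- function(p) if (file.exists(p)) p else file.path(dirname(path), p)
  baseline <- NULL
  if (!is.null(cfg$baseline_csv))
    baseline <- utils::read.csv(rel(cfg$baseline_csv))
  roots <- if (!is.null(cfg$roots_csv))
    read_root_table(rel(cfg$roots_csv), d_tube_mm = cfg$D_tube_mm)
  else empty_root_table()
  specimen(roots, soil_params(cfg$phi_deg, baseline),
           interface_params(cfg$tau_prime_kpa), zone)
}

#' Read a shear stress-displacement record from CSV
#'
#' @param path CSV with columns `u_mm`, `S_kpa`.
#' @return Validated `data.frame`.
#' @export
read_shear_record <- function(path) {
  rec <- utils::read.csv(path)
  if (!all(c("u_mm", "S_kpa") %in% names(rec)))
    stop("record must have columns u_mm, S_kpa")
  if (any(diff(rec$u_mm) <= 0))
    stop("record displacements must be strictly increasing")
  if (any(!is.finite(rec$S_kpa))) stop("record stresses must be finite")
  rec
}

#' Write a shear-zone map to CSV
#' @param map A `shear_zone_map` (or growth-map `data.frame`).
#' @param path Output path.
#' @export
write_map <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}

#' Run the full synthetic analysis pipeline
#'
#' End-to-end quick-look run on synthetic data: generate a root map and
#' displacement fields at an early and the final load step, map the
#' shear-zone thickness at both steps, take the zone peak from the map,
#' forward-simulate a stress record with a known tau', back-fit tau' from
#' that record, and check the no-breakage / no-pull-out assumptions.
#' Deterministic per seed; rerunning with the same configuration
#' reproduces the report.
#'
#' @param out_dir Output directory (created if needed); artifacts:
#'   `roots.csv`, `map_step3.csv`, `map_final.csv`, `growth.csv`,
#'   `record.csv`, `report.json`.
#' @param seed Integer seed driving all randomness.
#' @param field_cfg A [field_gen_config()]; the default uses a coarse
#'   demonstration grid (1.85 mm pitch over a +-20 mm window).
#' @param root_cfg A [root_map_config()].
#' @param tau_true_kpa Interface stress used by the forward simulation.
#' @param phi_deg Soil friction angle.
#' @param record_noise_kpa Stress noise in the simulated record.
#' @param map_stride Analyse every n-th map column (quick-look thinning).
#' @return The report as a list (also written to `report.json`).
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         field_cfg = field_gen_config(extent_mm = 20,
                                                      pitch_mm = 1.85,
                                                      noise_sd_mm = 0.0054,
                                                      seed = seed),
                         root_cfg = root_map_config(seed = seed),
                         tau_true_kpa = 1.25, phi_deg = 36,
                         record_noise_kpa = 0.2, map_stride = 2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  roots <- generate_root_map(root_cfg)
  write_root_table(roots, file.path(out_dir, "roots.csv"))

  f3 <- generate_field(field_cfg, step = 3)
  f7 <- generate_field(field_cfg, step = length(field_cfg$u_schedule_mm))
  m3 <- thickness_map(f3, stride = map_stride)
  m7 <- thickness_map(f7, stride = map_stride)
  write_map(m3, file.path(out_dir, "map_step3.csv"))
  write_map(m7, file.path(out_dir, "map_final.csv"))
  write_map(growth_map(m3, m7), file.path(out_dir, "growth.csv"))
  Z_max_map <- max(m7$thickness_mm[m7$ok], na.rm = TRUE)

  sched <- field_cfg$u_schedule_mm
  zone <- shear_zone_model(Z_min_mm = field_cfg$Z_min_mm,
                           Z_max_mm = Z_max_map,
                           D_tube_mm = field_cfg$D_tube_mm,
                           u_step3_mm = sched[3],
                           u_final_mm = sched[length(sched)])
  u_grid <- seq(0, max(sched), length.out = 41)
  baseline <- data.frame(u_mm = u_grid,
                         S_kpa = 5 * u_grid / (2 + u_grid))  # hyperbolic
  spec <- specimen(roots, soil_params(phi_deg, baseline),
                   interface_params(tau_true_kpa), zone)
  record <- generate_stress_record(spec, u_grid, noise_sd_kpa =
                                     record_noise_kpa, seed = seed)
  utils::write.csv(record, file.path(out_dir, "record.csv"),
                   row.names = FALSE)
  fallow <- nrow(roots) == 0
  fit <- if (fallow) NULL else fit_tau_prime(record, spec, target = "curve")
  checks <- assumption_check(spec, max(sched),
                             tensile_strength_mpa = 30,
                             available_length_mm = 200)
  report <- list(
    seed = seed,
    rar = attr(roots, "achieved_rar"),
    n_roots = nrow(roots),
    Z_max_from_map_mm = Z_max_map,
    map_columns_ok = sum(m7$ok),
    map_columns_total = nrow(m7),
    tau_true_kpa = tau_true_kpa,
    tau_fit_kpa = if (fallow) NA_real_ else fit$tau_prime_kpa,
    fit_residual_kpa = if (fallow) NA_real_ else fit$residual_kpa,
    dS_final_kpa = specimen_delta_s(spec, max(sched),
                                    "positional_with_growth"),
    no_breakage = checks$no_breakage,
    no_pullout = checks$no_pullout)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}
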