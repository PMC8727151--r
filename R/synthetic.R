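#' Configuration for the synthetic displacement-field generator
#'
#' Defaults reproduce the reference measurement conditions: a 0.37 mm
#' displacement grid over an 80 x 80 x 80 mm field of view centred on a
#' 103 mm tube, a double-cone shear zone pinched to the 2 mm tube gap at
#' the wall and peaking at 30 mm in the centre, local thickening bumps at
#' roots, and Gaussian displacement noise of 5.4 um per correlation step
#' accumulating linearly over steps.
#'
#' @param extent_mm Half-width of the cubic field of view (mm); nodes span
#'   `[-extent, extent]` in x, y and z.
#' @param pitch_mm Grid pitch (mm).
#' @param D_tube_mm Tube inner diameter (mm); nodes outside the tube radius
#'   are masked out.
#' @param Z_min_mm,Z_max_mm Zone thickness at the wall / centre (mm).
#' @param bumps Optional `data.frame` (`x_mm, y_mm, amplitude_mm,
#'   radius_mm`): Gaussian thickening bumps added near roots.
#' @param ramp `"trilinear"` (piecewise-linear, the fit's own idealisation)
#'   or `"smooth"` (cubic smoothstep across the same nominal width,
#'   emulating root/soil curvature at the zone edges).
#' @param u_schedule_mm Applied x-displacement at each load step (mm);
#'   default is the Willow C step schedule.
#' @param noise_sd_mm Displacement noise per correlation step (mm).
#' @param seed Integer seed; fields are deterministic per (seed, step).
#' @return List of class `field_gen_config`.
#' @export
field_gen_config <- function(extent_mm = 40, pitch_mm = 0.37,
                             D_tube_mm = 103, Z_min_mm = 2, Z_max_mm = 30,
                             bumps = NULL, ramp = c("trilinear", "smooth"),
                             u_schedule_mm = c(1.72, 4.87, 8.15, 11.39,
                                               14.69, 17.93, 19.83),
                             noise_sd_mm = 0.0054, seed = 1L) {
  ramp <- match.arg(ramp)
  stopifnot(pitch_mm > 0, extent_mm > 0, noise_sd_mm >= 0,
            Z_max_mm >= Z_min_mm, Z_min_mm > 0, all(u_schedule_mm >= 0))
  if (pitch_mm > Z_min_mm)
    stop("grid pitch coarser than Z_min: shear zone unresolvable")
  if (!is.null(bumps))
    stopifnot(all(c("x_mm", "y_mm", "amplitude_mm", "radius_mm")
                  %in% names(bumps)))
  structure(list(extent_mm = extent_mm, pitch_mm = pitch_mm,
                 D_tube_mm = D_tube_mm, Z_min_mm = Z_min_mm,
                 Z_max_mm = Z_max_mm, bumps = bumps, ramp = ramp,
                 u_schedule_mm = u_schedule_mm, noise_sd_mm = noise_sd_mm,
                 seed = as.integer(seed)),
            class = "field_gen_config")
}

# local zone thickness of the generator: double cone + bumps, floored at Z_min
generator_thickness <- function(cfg, x, y) {
  r <- sqrt(outer(x^2, y^2, `+`))
  Z <- cfg$Z_min_mm +
    (cfg$Z_max_mm - cfg$Z_min_mm) * (1 - 2 * r / cfg$D_tube_mm)
  if (!is.null(cfg$bumps)) {
    for (i in seq_len(nrow(cfg$bumps))) {
      d2 <- outer((x - cfg$bumps$x_mm[i])^2, (y - cfg$bumps$y_mm[i])^2, `+`)
      Z <- Z + cfg$bumps$amplitude_mm[i] *
        exp(-d2 / (2 * (cfg$bumps$radius_mm[i] / 2)^2))
    }
  }
  pmax(Z, cfg$Z_min_mm)
}

#' Generate a synthetic displacement field for one load step
#'
#' Emulates the displacement output of digital volume correlation on a
#' direct-shear test: the lower tube half carries the step's full applied
#' x-displacement, the upper half is fixed, and the transition occurs
#' across a zone of local thickness given by the double-cone geometry plus
#' any root bumps. Gaussian noise with standard deviation
#' `noise_sd_mm * step` (linear accumulation over correlation steps) is
#' added to every component; the noise-free part is identical across seeds.
#'
#' @param cfg A [field_gen_config()].
#' @param step Load step index (1-based, indexing `u_schedule_mm`).
#' @return List of class `displacement_field`: coordinate vectors `x`,
#'   `y`, `z` (mm, tube-centred, z = 0 at the shear plane), array `u`
#'   (nx x ny x nz x 3, mm), logical `mask`, plus `pitch_mm`,
#'   `step_index`, `u_applied_mm`, `noise_sd` (the accumulated level) and
#'   `zone_thickness` (the nx x ny generator truth, for validation).
#' @export
generate_field <- function(cfg, step = length(cfg$u_schedule_mm)) {
  stopifnot(inherits(cfg, "field_gen_config"),
            step >= 1, step <= length(cfg$u_schedule_mm))
  ax <- seq(-cfg$extent_mm, cfg$extent_mm, by = cfg$pitch_mm)
  nx <- length(ax)
  u_app <- cfg$u_schedule_mm[step]
  Zxy <- generator_thickness(cfg, ax, ax)

  u <- array(0, dim = c(nx, nx, nx, 3))
  # ramp: fraction of u_app carried at height z for zone thickness Z
  for (iz in seq_len(nx)) {
    z <- ax[iz]
    t <- (z / Zxy) + 0.5            # 0 at lower zone edge, 1 at upper
    t <- pmin(pmax(t, 0), 1)
    frac <- if (cfg$ramp == "trilinear") 1 - t
            else 1 - (t * t * (3 - 2 * t))   # cubic smoothstep
    u[, , iz, 1] <- u_app * frac
  }
  sd_acc <- cfg$noise_sd_mm * step
  if (sd_acc > 0) {
    set.seed(cfg$seed + 1000L * as.integer(step))
    u <- u + array(stats::rnorm(length(u), sd = sd_acc), dim = dim(u))
  }
  mask <- array(rep(sqrt(outer(ax^2, ax^2, `+`)) <= cfg$D_tube_mm / 2, nx),
                dim = c(nx, nx, nx))
  structure(list(x = ax, y = ax, z = ax, u = u, mask = mask,
                 pitch_mm = cfg$pitch_mm, step_index = as.integer(step),
                 u_applied_mm = u_app, noise_sd = sd_acc,
                 zone_thickness = Zxy),
            class = "displacement_field")
}

#' Configuration for the synthetic root-map generator
#'
#' @param target_rar Target root area ratio (fraction, e.g. 0.00409 for
#'   0.409%).
#' @param D_tube_mm Tube inner diameter (mm).
#' @param meanlog,sdlog Lognormal diameter distribution parameters
#'   (diameters in mm, truncated to `d_range_mm`); the default gives many
#'   fine roots and a few large ones.
#' @param d_range_mm Diameter truncation range (mm).
#' @param edge_weight Probability mass placed within `edge_band_mm` of the
#'   tube wall (pot-grown systems concentrate roots near the boundary).
#' @param edge_band_mm Width of the edge band (mm).
#' @param E_mpa Root stiffness assigned to every generated root (MPa).
#' @param n_roots Optional fixed root count (overrides draw-until-RAR).
#' @param seed Integer seed.
#' @return List of class `root_map_config`.
#' @export
root_map_config <- function(target_rar = 0.00409, D_tube_mm = 103,
                            meanlog = log(0.5), sdlog = 0.7,
                            d_range_mm = c(0.1, 4), edge_weight = 0.6,
                            edge_band_mm = 20, E_mpa = 200,
                            n_roots = NULL, seed = 1L) {
  stopifnot(target_rar >= 0, target_rar < 1, D_tube_mm > 0,
            edge_weight >= 0, edge_weight <= 1,
            d_range_mm[1] > 0, d_range_mm[2] > d_range_mm[1])
  structure(list(target_rar = target_rar, D_tube_mm = D_tube_mm,
                 meanlog = meanlog, sdlog = sdlog, d_range_mm = d_range_mm,
                 edge_weight = edge_weight, edge_band_mm = edge_band_mm,
                 E_mpa = E_mpa, n_roots = n_roots, seed = as.integer(seed)),
            class = "root_map_config")
}

# one position inside the tube, with edge bias (uniform in area per region)
draw_position <- function(cfg) {
  R <- cfg$D_tube_mm / 2
  r0 <- max(R - cfg$edge_band_mm, 0)
  in_edge <- stats::runif(1) < cfg$edge_weight
  r <- if (in_edge) sqrt(stats::runif(1, r0^2, R^2))
       else sqrt(stats::runif(1, 0, r0^2))
  th <- stats::runif(1, 0, 2 * pi)
  c(r * cos(th), r * sin(th))
}

#' Generate a synthetic root map on the shear plane
#'
#' Draws root positions (edge-biased, uniform in area within each region)
#' and diameters (truncated lognormal) until the target root area ratio is
#' reached, then adjusts the last diameter so the achieved RAR is within
#' 5% relative of the target. Deterministic per seed.
#'
#' @param cfg A [root_map_config()].
#' @param max_attempts Bounded retries before declaring the target RAR
#'   unreachable with the configured diameter distribution.
#' @return Root table (`data.frame` with the [root()] columns) with
#'   attribute `achieved_rar` (exactly the summed-area ratio of the
#'   returned table).
#' @export
generate_root_map <- function(cfg, max_attempts = 100) {
  stopifnot(inherits(cfg, "root_map_config"))
  area <- pi * (cfg$D_tube_mm / 2)^2
  set.seed(cfg$seed)
  if (!is.null(cfg$n_roots) && cfg$n_roots == 0) {
    out <- empty_root_table()
    attr(out, "achieved_rar") <- 0
    return(out)
  }
  target_area <- cfg$target_rar * area
  for (attempt in seq_len(max_attempts)) {
    rows <- list(); tot <- 0; i <- 0
    repeat {
      i <- i + 1
      if (!is.null(cfg$n_roots) && i > cfg$n_roots) break
      d <- stats::rlnorm(1, cfg$meanlog, cfg$sdlog)
      if (d < cfg$d_range_mm[1] || d > cfg$d_range_mm[2]) { i <- i - 1; next }
      p <- draw_position(cfg)
      rows[[length(rows) + 1]] <- root(p[1], p[2], d, cfg$E_mpa,
                                       label = sprintf("r%03d", i))
      tot <- tot + pi * (d / 2)^2
      if (is.null(cfg$n_roots) && tot >= target_area) break
      if (i > 10000) break
    }
    roots <- do.call(rbind, rows)
    if (is.null(cfg$n_roots) && nrow(roots) > 0) {
      # shrink the last root so the achieved area matches the target
      excess <- tot - target_area
      a_last <- pi * (roots$diameter_mm[nrow(roots)] / 2)^2
      a_new <- a_last - excess
      d_new <- 2 * sqrt(max(a_new, 0) / pi)
      if (d_new >= cfg$d_range_mm[1]) {
        roots$diameter_mm[nrow(roots)] <- d_new
      } else if (nrow(roots) > 1) {
        roots <- roots[-nrow(roots), , drop = FALSE]
      }
    }
    achieved <- sum(pi * (roots$diameter_mm / 2)^2) / area
    if (is.null(cfg$n_roots) && cfg$target_rar > 0 &&
        abs(achieved - cfg$target_rar) > 0.05 * cfg$target_rar)
      next
    attr(roots, "achieved_rar") <- achieved
    return(roots)
  }
  stop("target RAR unreachable with the configured diameter distribution ",
       "after ", max_attempts, " attempts")
}

#' Generate a synthetic shear stress record
#'
#' Forward-models the total stress curve for a specimen and adds i.i.d.
#' Gaussian stress noise; used for exercising [fit_tau_prime()] with a
#' known ground truth.
#'
#' @param spec A [specimen()] (with baseline).
#' @param u_grid_mm Displacement schedule (mm).
#' @param noise_sd_kpa Stress noise standard deviation (kPa).
#' @param seed Integer seed.
#' @inheritParams predict_stress_curve
#' @return `data.frame` with columns `u_mm`, `S_kpa`.
#' @export
generate_stress_record <- function(spec, u_grid_mm,
                                   Z_policy = "positional_with_growth",
                                   Z_mm = NULL, noise_sd_kpa = 0,
                                   seed = 1L, extrapolate = FALSE) {
  curve <- predict_stress_curve(spec, u_grid_mm, Z_policy, Z_mm,
                                extrapolate = extrapolate)
  S <- curve$total_kpa
  if (noise_sd_kpa > 0) {
    set.seed(as.integer(seed))
    S <- S + stats::rnorm(length(S), sd = noise_sd_kpa)
  }
  data.frame(u_mm = curve$u_mm, S_kpa = S)
}

#' Generate a synthetic deformed root path
#'
#' Builds the 3-D polyline of a root spanning the shear zone at shear
#' displacement `u_x`: the below-zone anchor leg carries the full
#' displacement, the above-zone leg none, with either sharp knees at the
#' zone edges (`"trilinear"`, the model's idealisation) or circular arcs
#' of radius `bend_radius_mm` tangent to both segments (`"curved"`, the
#' behaviour of a real root that bends rather than kinks). Curved paths
#' with the same endpoints are strictly shorter than the tri-linear path.
#'
#' @param kind `"trilinear"` or `"curved"`.
#' @param Z_mm Shear-zone thickness (mm).
#' @param u_x_mm Applied shear displacement (mm, >= 0).
#' @param bend_radius_mm Arc radius at each knee (mm); 0 degenerates to
#'   the tri-linear path.
#' @param anchor_mm Length of the straight legs beyond each zone edge (mm).
#' @param n_arc Points used to discretise each arc.
#' @return `data.frame` with columns `x_mm`, `y_mm`, `z_mm`, ordered along
#'   the root from bottom anchor to top anchor.
#' @export
generate_root_path <- function(kind = c("trilinear", "curved"), Z_mm,
                               u_x_mm, bend_radius_mm = 0, anchor_mm = 30,
                               n_arc = 64) {
  kind <- match.arg(kind)
  stopifnot(Z_mm > 0, u_x_mm >= 0, bend_radius_mm >= 0, anchor_mm > 0)
  p0 <- c(u_x_mm, -Z_mm / 2 - anchor_mm)       # (x, z) bottom anchor
  k1 <- c(u_x_mm, -Z_mm / 2)                   # lower knee
  k2 <- c(0, Z_mm / 2)                         # upper knee
  p3 <- c(0, Z_mm / 2 + anchor_mm)             # top anchor
  if (kind == "trilinear" || bend_radius_mm == 0 || u_x_mm == 0) {
    pts <- rbind(p0, k1, k2, p3)
  } else {
    beta <- atan(u_x_mm / Z_mm)
    t <- bend_radius_mm * tan(beta / 2)        # tangent trim length
    ramp_len <- sqrt(u_x_mm^2 + Z_mm^2)
    if (t > anchor_mm || t > ramp_len / 2)
      stop("bend radius too large for the path geometry")
    dir_ramp <- (k2 - k1) / ramp_len
    arc <- function(knee, d_in, d_out) {
      # fillet arc tangent to both segments at distance t from the knee
      a <- knee - t * d_in                     # arc start
      n_in <- c(-d_in[2], d_in[1])             # normal to incoming dir
      if (sum(n_in * (d_out - d_in)) < 0) n_in <- -n_in
      centre <- a + bend_radius_mm * n_in
      b <- knee + t * d_out                    # arc end
      a0 <- atan2(a[2] - centre[2], a[1] - centre[1])
      a1 <- atan2(b[2] - centre[2], b[1] - centre[1])
      da <- a1 - a0
      if (da > pi) da <- da - 2 * pi
      if (da < -pi) da <- da + 2 * pi
      ang <- a0 + seq(0, da, length.out = n_arc)
      cbind(centre[1] + bend_radius_mm * cos(ang),
            centre[2] + bend_radius_mm * sin(ang))
    }
    up <- c(0, 1)
    pts <- rbind(p0, arc(k1, up, dir_ramp), arc(k2, dir_ramp, up), p3)
  }
  data.frame(x_mm = pts[, 1], y_mm = 0, z_mm = pts[, 2])
}

#' Displacement-grid pitch implied by DVC subset settings
#'
#' The displacement grid produced by subset-based volume correlation has a
#' node spacing of `subset_px * (1 - overlap)` voxels.
#'
#' @param subset_px Subset edge length in voxels.
#' @param voxel_mm Voxel size (mm).
#' @param overlap Subset overlap fraction (e.g. 0.75).
#' @return List with `step_px` (grid step in voxels) and `pitch_mm`.
#' @export
dvc_grid_pitch <- function(subset_px = 32, voxel_mm = 0.046, overlap = 0.75) {
  stopifnot(subset_px > 0, voxel_mm > 0, overlap >= 0, overlap < 1)
  step_px <- subset_px * (1 - overlap)
  list(step_px = step_px, pitch_mm = step_px * voxel_mm)
}

#' Hydrostatic matric suction above a water table
#'
#' Under hydrostatic conditions the matric suction at a point `depth_m`
#' above the water table is `gamma_w * depth_m`.
#'
#' @param height_m Height of the point above the water table (m).
#' @param gamma_w_kn_m3 Unit weight of water (kN/m^3).
#' @return Suction in kPa.
#' @export
hydrostatic_suction_kpa <- function(height_m, gamma_w_kn_m3 = 9.81) {
  stopifnot(height_m >= 0)
  gamma_w_kn_m3 * height_m
}
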