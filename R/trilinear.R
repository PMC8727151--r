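# Closed-form least-squares plateaus for fixed knee positions.
# Model: u(z) = u_below for z <= z_lower, u_above for z >= z_upper,
# linear in between (continuous at both knees). For fixed knees the model
# is linear in (u_below, u_above), so the plateaus come from a 2x2 normal
# system. Returns list(u_below, u_above, rss) or NULL if singular.
trilinear_plateaus <- function(z, u, z_lower, z_upper) {
  w <- (z - z_lower) / (z_upper - z_lower)
  w <- pmin(pmax(w, 0), 1)
  x1 <- 1 - w
  s11 <- sum(x1 * x1); s12 <- sum(x1 * w); s22 <- sum(w * w)
  det <- s11 * s22 - s12 * s12
  if (!is.finite(det) || det < 1e-12 * (s11 + s22)^2) return(NULL)
  b1 <- sum(u * x1); b2 <- sum(u * w)
  a <- (s22 * b1 - s12 * b2) / det
  b <- (s11 * b2 - s12 * b1) / det
  r <- a * x1 + b * w - u
  list(u_below = a, u_above = b, rss = sum(r * r))
}

#' Fit a tri-linear profile to a depth vs displacement column
#'
#' Least-squares fit of the idealised shear-band profile: constant
#' displacement above and below the zone (vertical lines in a depth vs
#' displacement plot) joined by a linear ramp; the two knees mark the zone
#' edges and their separation is the local shear-zone thickness. Knees are
#' located by an exhaustive search over pairs of observed depths (each pair
#' scored with closed-form plateaus) followed by deterministic Nelder-Mead
#' refinement of the knee depths; ties in residual are broken towards the
#' smallest thickness. No randomness enters the fit.
#'
#' @param profile `data.frame` with columns `z_mm` (depth) and `ux_mm`
#'   (displacement in the shear direction), at least 6 rows.
#' @param noise_sd Displacement noise level (mm) used for the quality flag:
#'   the fit is marked not-ok when the plateau separation is below
#'   `3 * noise_sd` (no resolvable band) or a knee sits at the profile
#'   boundary.
#' @param refine Refine knee depths continuously after the grid stage.
#' @param max_candidates Cap on the number of candidate knee depths used in
#'   the exhaustive stage (the profile is thinned evenly above this).
#' @return List of class `trilinear_fit`: `z_lower`, `z_upper`,
#'   `u_below`, `u_above`, `thickness` (= z_upper - z_lower), `rss`, `ok`,
#'   `n` (points used).
#' @export
fit_trilinear <- function(profile, noise_sd = 0, refine = TRUE,
                          max_candidates = 80) {
  bad <- function() structure(list(z_lower = NA_real_, z_upper = NA_real_,
                                   u_below = NA_real_, u_above = NA_real_,
                                   thickness = NA_real_, rss = NA_real_,
                                   ok = FALSE, n = nrow(profile)),
                              class = "trilinear_fit")
  stopifnot(is.data.frame(profile),
            all(c("z_mm", "ux_mm") %in% names(profile)))
  keep <- is.finite(profile$z_mm) & is.finite(profile$ux_mm)
  z <- profile$z_mm[keep]; u <- profile$ux_mm[keep]
  o <- order(z); z <- z[o]; u <- u[o]
  n <- length(z)
  if (n < 6) return(bad())
  if (diff(range(u)) <= max(1e-12, 1e-9 * max(abs(u)))) return(bad())

  cand <- z
  if (n > max_candidates)
    cand <- z[unique(round(seq(1, n, length.out = max_candidates)))]
  nc <- length(cand)
  best <- NULL; best_rss <- Inf; best_th <- Inf
  for (i in seq_len(nc - 1)) {
    for (j in seq((i + 1), nc)) {
      fit <- trilinear_plateaus(z, u, cand[i], cand[j])
      if (is.null(fit)) next
      th <- cand[j] - cand[i]
      if (fit$rss < best_rss - 1e-12 * (1 + best_rss) ||
          (fit$rss <= best_rss + 1e-12 * (1 + best_rss) && th < best_th)) {
        best_rss <- fit$rss; best_th <- th
        best <- c(cand[i], cand[j])
      }
    }
  }
  if (is.null(best)) return(bad())

  zr <- range(z)
  obj <- function(p) {
    if (!is.finite(p[1]) || !is.finite(p[2])) return(.Machine$double.xmax)
    if (p[1] >= p[2] || p[1] < zr[1] || p[2] > zr[2])
      return(.Machine$double.xmax)
    fit <- trilinear_plateaus(z, u, p[1], p[2])
    if (is.null(fit)) return(.Machine$double.xmax)
    fit$rss
  }
  knees <- best
  if (refine) {
    opt <- stats::optim(best, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, abstol = 1e-300,
                                       maxit = 2000))
    if (is.finite(opt$value) && opt$value <= best_rss + 1e-15)
      knees <- opt$par
  }
  fit <- trilinear_plateaus(z, u, knees[1], knees[2])
  if (is.null(fit)) return(bad())

  spacing <- stats::median(diff(z))
  at_edge <- knees[1] <= zr[1] + 0.5 * spacing ||
             knees[2] >= zr[2] - 0.5 * spacing
  sep <- abs(fit$u_above - fit$u_below)
  ok <- !at_edge && sep > 3 * noise_sd && sep > 1e-9
  structure(list(z_lower = knees[1], z_upper = knees[2],
                 u_below = fit$u_below, u_above = fit$u_above,
                 thickness = knees[2] - knees[1], rss = fit$rss,
                 ok = ok, n = n),
            class = "trilinear_fit")
}

#' @export
print.trilinear_fit <- function(x, ...) {
  if (!x$ok) {
    cat("Tri-linear fit: not ok (no resolvable shear band)\n")
  } else {
    cat(sprintf(
      "Tri-linear fit: knees %.3f / %.3f mm, thickness %.3f mm, rss %.3g\n",
      x$z_lower, x$z_upper, x$thickness, x$rss))
  }
  invisible(x)
}

#' Extract a depth vs displacement profile from a displacement field
#'
#' Pulls the x-displacement column at a shear-plane position `(x, y)`,
#' excluding masked-out nodes, sorted by depth.
#'
#' @param field A `displacement_field` (see [generate_field()] /
#'   [read_field()]).
#' @param x_mm,y_mm Shear-plane position; must coincide with a grid node
#'   (within half a pitch).
#' @param min_points Minimum number of valid nodes for a usable profile.
#' @return `data.frame` with columns `z_mm`, `ux_mm` and attribute `ok`
#'   (`FALSE`, with zero usable content, when fewer than `min_points`
#'   valid nodes remain).
#' @export
extract_profile <- function(field, x_mm, y_mm, min_points = 6) {
  stopifnot(inherits(field, "displacement_field"))
  ix <- which.min(abs(field$x - x_mm))
  iy <- which.min(abs(field$y - y_mm))
  if (abs(field$x[ix] - x_mm) > field$pitch_mm / 2 ||
      abs(field$y[iy] - y_mm) > field$pitch_mm / 2)
    stop("(x, y) = (", x_mm, ", ", y_mm, ") mm is not on the field grid")
  ok_nodes <- field$mask[ix, iy, ]
  prof <- data.frame(z_mm = field$z[ok_nodes],
                     ux_mm = field$u[ix, iy, ok_nodes, 1])
  prof <- prof[order(prof$z_mm), , drop = FALSE]
  rownames(prof) <- NULL
  attr(prof, "ok") <- nrow(prof) >= min_points
  prof
}

#' Map shear-zone thickness over the shear plane
#'
#' Runs the tri-linear fit on every (x, y) column of a displacement field,
#' producing a per-position thickness map. Columns whose fit fails or is
#' unreliable are flagged, never aborting the whole map.
#'
#' @param field A `displacement_field`.
#' @param noise_sd Displacement noise level (mm) for the per-column quality
#'   flag; defaults to the field's own recorded noise level (0 if absent).
#' @param stride Analyse every `stride`-th column in x and y (1 = all).
#' @return `data.frame` of class `shear_zone_map` with columns `x_mm`,
#'   `y_mm`, `thickness_mm`, `z_lower_mm`, `z_upper_mm`, `rss`, `ok`;
#'   attributes `step_index` and `pitch_mm`.
#' @export
thickness_map <- function(field, noise_sd = NULL, stride = 1) {
  stopifnot(inherits(field, "displacement_field"))
  if (is.null(noise_sd)) noise_sd <- field$noise_sd %||% 0
  xs <- field$x[seq(1, length(field$x), by = stride)]
  ys <- field$y[seq(1, length(field$y), by = stride)]
  grid <- expand.grid(x_mm = xs, y_mm = ys, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    prof <- extract_profile(field, grid$x_mm[i], grid$y_mm[i])
    if (!attr(prof, "ok"))
      return(data.frame(thickness_mm = NA_real_, z_lower_mm = NA_real_,
                        z_upper_mm = NA_real_, rss = NA_real_, ok = FALSE))
    f <- fit_trilinear(prof, noise_sd = noise_sd)
    data.frame(thickness_mm = f$thickness, z_lower_mm = f$z_lower,
               z_upper_mm = f$z_upper, rss = f$rss, ok = f$ok)
  })
  out <- cbind(grid, do.call(rbind, res))
  attr(out, "step_index") <- field$step_index
  attr(out, "pitch_mm") <- field$pitch_mm
  class(out) <- c("shear_zone_map", "data.frame")
  out
}

#' Shear-zone growth between two load steps
#'
#' Pointwise thickness difference `b - a` between two congruent maps;
#' positive values mean the zone thickened between the steps. Positions
#' where either fit is flagged unreliable get `NaN`.
#'
#' @param map_a,map_b `shear_zone_map`s on identical (x, y) grids
#'   (the earlier step first).
#' @return `data.frame` with columns `x_mm`, `y_mm`, `dthickness_mm`, `ok`.
#' @export
growth_map <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "shear_zone_map"),
            inherits(map_b, "shear_zone_map"))
  if (nrow(map_a) != nrow(map_b) ||
      any(abs(map_a$x_mm - map_b$x_mm) > 1e-9) ||
      any(abs(map_a$y_mm - map_b$y_mm) > 1e-9))
    stop("maps are on different (x, y) grids")
  ok <- map_a$ok & map_b$ok
  d <- ifelse(ok, map_b$thickness_mm - map_a$thickness_mm, NaN)
  data.frame(x_mm = map_a$x_mm, y_mm = map_a$y_mm,
             dthickness_mm = d, ok = ok)
}

#' Summarise a thickness map at and away from roots
#'
#' Local mean thickness near each root (within `radius_mm`; `radius_mm = 0`
#' takes the nearest node) against the far-field mean (beyond twice the
#' radius from every root), plus global extrema over reliable columns.
#'
#' @param map A `shear_zone_map`.
#' @param roots Optional root table; roots outside the map footprint are
#'   skipped with a warning.
#' @param radius_mm Averaging radius around each root (mm).
#' @return List of class `map_summary` with elements `per_root`
#'   (`data.frame`: label, n_cells, at_root_mean_mm), `far_field_mean_mm`,
#'   `global_max_mm`, `global_min_mm`.
#' @export
summarize_map <- function(map, roots = NULL, radius_mm = 5) {
  stopifnot(inherits(map, "shear_zone_map"))
  okm <- map[map$ok & is.finite(map$thickness_mm), , drop = FALSE]
  gmax <- if (nrow(okm)) max(okm$thickness_mm) else NA_real_
  gmin <- if (nrow(okm)) min(okm$thickness_mm) else NA_real_
  per_root <- NULL
  far_mean <- NA_real_
  if (!is.null(roots) && nrow(roots) > 0) {
    in_fp <- roots$x_mm >= min(map$x_mm) & roots$x_mm <= max(map$x_mm) &
             roots$y_mm >= min(map$y_mm) & roots$y_mm <= max(map$y_mm)
    if (any(!in_fp))
      warning(sum(!in_fp), " root(s) outside the map footprint, skipped")
    roots <- roots[in_fp, , drop = FALSE]
    rows <- lapply(seq_len(nrow(roots)), function(i) {
      d <- sqrt((okm$x_mm - roots$x_mm[i])^2 + (okm$y_mm - roots$y_mm[i])^2)
      sel <- if (radius_mm > 0) d <= radius_mm else d == min(d)
      data.frame(label = roots$label[i], n_cells = sum(sel),
                 at_root_mean_mm = if (any(sel)) mean(okm$thickness_mm[sel])
                                   else NA_real_,
                 stringsAsFactors = FALSE)
    })
    per_root <- do.call(rbind, rows)
    dmin <- rep(Inf, nrow(okm))
    for (i in seq_len(nrow(roots)))
      dmin <- pmin(dmin, sqrt((okm$x_mm - roots$x_mm[i])^2 +
                              (okm$y_mm - roots$y_mm[i])^2))
    far <- dmin > 2 * radius_mm
    far_mean <- if (any(far)) mean(okm$thickness_mm[far]) else NA_real_
  }
  structure(list(per_root = per_root, far_field_mean_mm = far_mean,
                 global_max_mm = gmax, global_min_mm = gmin),
            class = "map_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
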