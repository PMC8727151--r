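#' Length of a root path polyline
#'
#' Sum of segment lengths of an ordered 3-D polyline between two anchor
#' points; always at least the straight-line anchor distance.
#'
#' @param path `data.frame` with columns `x_mm`, `y_mm`, `z_mm` (ordered
#'   along the root), at least 2 rows.
#' @return Length in mm.
#' @export
path_length <- function(path) {
  stopifnot(is.data.frame(path),
            all(c("x_mm", "y_mm", "z_mm") %in% names(path)))
  if (nrow(path) < 2) stop("a path needs at least 2 points")
  d <- sqrt(diff(path$x_mm)^2 + diff(path$y_mm)^2 + diff(path$z_mm)^2)
  sum(d)
}

#' Measured root extension between two states
#'
#' Difference in measured path length between the deformed and the
#' reference state of the same root (same anchors). Negative values are
#' reported (with a warning), not clipped: measurement noise can produce
#' them and clipping would bias the comparison with the tri-linear
#' formula.
#'
#' @param path_0 Reference (undeformed) path.
#' @param path_t Deformed path.
#' @param anchor_tol_mm Warn if the first/last points of the two paths
#'   differ in (y) position by more than this (different root suspected);
#'   the x/z endpoints legitimately move with shear.
#' @return Extension in mm (`path_length(path_t) - path_length(path_0)`).
#' @export
measured_delta_l <- function(path_0, path_t, anchor_tol_mm = 1e-6) {
  dl <- path_length(path_t) - path_length(path_0)
  if (dl < 0) warning("negative measured extension (", signif(dl, 3),
                      " mm): kept, not clipped")
  dl
}

#' Compare tri-linear and measured root extension
#'
#' For each root, evaluates the tri-linear extension formula
#' `dl = Z (sec beta - 1)` with `beta = arctan(u_x / Z)` and compares it
#' with the directly measured path-length change. For real (curved) root
#' paths the formula is an upper bound, so the ratio
#' `dl_trilinear / dl_measured` is expected to exceed 1.
#'
#' @param paths_0,paths_t Lists of reference / deformed paths (same order,
#'   same roots).
#' @param Z_mm Shear-zone thickness per root (mm; recycled).
#' @param u_x_mm Applied displacement per root (mm; recycled).
#' @param labels Optional root labels.
#' @return `data.frame` with columns `label`, `Z_mm`, `u_x_mm`,
#'   `dl_trilinear_mm`, `dl_measured_mm`, `ratio` (NA, flagged via the
#'   `undefined` column, when `u_x` is 0 or the measured change is 0).
#' @export
compare_extension <- function(paths_0, paths_t, Z_mm, u_x_mm,
                              labels = NULL) {
  stopifnot(length(paths_0) == length(paths_t))
  n <- length(paths_0)
  Z_mm <- rep_len(Z_mm, n)
  u_x_mm <- rep_len(u_x_mm, n)
  if (is.null(labels)) labels <- sprintf("r%03d", seq_len(n))
  beta <- compute_beta(u_x_mm, Z_mm)
  dl_tri <- Z_mm * (1 / cos(beta) - 1)
  dl_meas <- vapply(seq_len(n), function(i)
    suppressWarnings(measured_delta_l(paths_0[[i]], paths_t[[i]])),
    numeric(1))
  undefined <- u_x_mm == 0 | dl_meas == 0
  ratio <- ifelse(undefined, NA_real_, dl_tri / dl_meas)
  data.frame(label = labels, Z_mm = Z_mm, u_x_mm = u_x_mm,
             dl_trilinear_mm = dl_tri, dl_measured_mm = dl_meas,
             ratio = ratio, undefined = undefined,
             stringsAsFactors = FALSE)
}
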