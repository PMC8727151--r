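test_that("the fitter recovers noiseless tri-linear profiles, on and off the depth grid", {
  prof <- make_trilinear_profile(z_lower = -5, z_upper = 7)
  f <- fit_trilinear(prof)
  expect_true(f$ok)
  expect_equal(f$thickness, 12, tolerance = 1e-6)
  expect_equal(f$z_lower, -5, tolerance = 1e-6)
  expect_equal(f$z_upper, 7, tolerance = 1e-6)
  expect_lt(f$rss, 1e-16)
  # knees between sample depths
  prof2 <- make_trilinear_profile(z_lower = -5.13, z_upper = 6.87)
  f2 <- fit_trilinear(prof2)
  expect_equal(f2$thickness, 12, tolerance = 1e-6)
})

test_that("degenerate and translated profiles are handled", {
  const <- data.frame(z_mm = seq(-10, 10), ux_mm = rep(3, 21))
  expect_false(fit_trilinear(const)$ok)
  expect_false(fit_trilinear(make_trilinear_profile()[1:4, ])$ok)
  # thickness invariant under a rigid column shift
  prof <- make_trilinear_profile()
  shifted <- prof; shifted$ux_mm <- shifted$ux_mm + 4.2
  expect_equal(fit_trilinear(shifted)$thickness,
               fit_trilinear(prof)$thickness, tolerance = 1e-9)
})

test_that("thickness recovery is robust to accumulated correlation noise", {
  prof <- make_trilinear_profile()
  sd7 <- 0.0054 * 7   # per-step noise accumulated linearly over 7 steps
  set.seed(101)
  errs <- replicate(30, {
    p <- prof
    p$ux_mm <- p$ux_mm + rnorm(nrow(p), sd = sd7)
    fit_trilinear(p, noise_sd = sd7)$thickness - 12
  })
  expect_lt(median(abs(errs)), 1)
  expect_lt(max(abs(errs)), 0.5)
})

test_that("profile extraction honours the mask and the grid", {
  cfg <- field_gen_config(extent_mm = 10, pitch_mm = 1, noise_sd_mm = 0)
  f <- generate_field(cfg, step = 3)
  prof <- extract_profile(f, 0, 0)
  expect_true(attr(prof, "ok"))
  expect_equal(nrow(prof), length(f$z))
  expect_true(!is.unsorted(prof$z_mm))
  # masked column: mark a column invalid and expect a flagged-empty profile
  f$mask[3, 3, ] <- FALSE
  prof2 <- extract_profile(f, f$x[3], f$y[3])
  expect_false(attr(prof2, "ok"))
  expect_equal(nrow(prof2), 0)
  expect_error(extract_profile(f, 100, 0), "not on the field grid")
})

test_that("thickness maps show the double-cone pattern and local root thickening", {
  # zone must fit well inside the z-range so knees stay interior
  bump <- data.frame(x_mm = 6, y_mm = -6, amplitude_mm = 4, radius_mm = 4)
  cfg <- field_gen_config(extent_mm = 12, pitch_mm = 1, noise_sd_mm = 0,
                          Z_max_mm = 10, bumps = bump)
  f <- generate_field(cfg, step = 7)
  m <- thickness_map(f, stride = 2)
  okm <- m[m$ok, ]
  r <- sqrt(okm$x_mm^2 + okm$y_mm^2)
  expect_gt(mean(okm$thickness_mm[r < 4]),
            mean(okm$thickness_mm[r > 10 & okm$y_mm > 0]))
  # local maximum at the bump position, against same-radius columns away
  away <- okm[abs(okm$x_mm - 6) > 4 | abs(okm$y_mm + 6) > 4, ]
  near <- okm[abs(okm$x_mm - 6) <= 2 & abs(okm$y_mm + 6) <= 2, ]
  same_r <- away[abs(sqrt(away$x_mm^2 + away$y_mm^2) - sqrt(72)) < 2, ]
  expect_gt(mean(near$thickness_mm), mean(same_r$thickness_mm))
})

test_that("a rigid uniform translation yields no resolvable shear band", {
  cfg <- field_gen_config(extent_mm = 8, pitch_mm = 1, noise_sd_mm = 0)
  f <- generate_field(cfg, step = 3)
  f$u[, , , 1] <- 5   # both halves moved together
  m <- thickness_map(f, stride = 2)
  expect_true(all(!m$ok))
})

test_that("maps of point-symmetric fields are point-symmetric", {
  cfg <- field_gen_config(extent_mm = 10, pitch_mm = 1, noise_sd_mm = 0,
                          Z_max_mm = 8)
  f <- generate_field(cfg, step = 5)   # double cone is symmetric already
  m <- thickness_map(f, stride = 2)
  okm <- m[m$ok & is.finite(m$thickness_mm), ]
  key <- function(x, y) paste(round(x, 6), round(y, 6))
  mirrored <- okm$thickness_mm[match(key(-okm$x_mm, -okm$y_mm),
                                     key(okm$x_mm, okm$y_mm))]
  keep <- !is.na(mirrored)
  expect_lt(max(abs(okm$thickness_mm[keep] - mirrored[keep])), 1e-6)
})

test_that("growth maps difference two steps with the right sign and flags", {
  cfg <- field_gen_config(extent_mm = 10, pitch_mm = 1, noise_sd_mm = 0,
                          Z_max_mm = 8)
  f3 <- generate_field(cfg, step = 3)
  m3 <- thickness_map(f3, stride = 2)
  g0 <- growth_map(m3, m3)
  expect_true(all(g0$dthickness_mm[g0$ok] == 0))
  # grown zone: scale the generator thickness by 1/0.8 between the steps
  cfg2 <- field_gen_config(extent_mm = 10, pitch_mm = 1, noise_sd_mm = 0,
                           Z_min_mm = 2 / 0.8, Z_max_mm = 8 / 0.8)
  f7 <- generate_field(cfg2, step = 3)
  m7 <- thickness_map(f7, stride = 2)
  g <- growth_map(m3, m7)
  rel <- g$dthickness_mm[g$ok] / m3$thickness_mm[g$ok]
  expect_true(all(g$dthickness_mm[g$ok] > 0))
  expect_equal(unname(median(rel)), 0.25, tolerance = 0.02)
  # shrinking zone: reversed order gives negative differences
  gneg <- growth_map(m7, m3)
  expect_true(all(gneg$dthickness_mm[gneg$ok] < 0))
  expect_true(all(is.nan(g$dthickness_mm[!g$ok])))
  m_sub <- m3[1:4, ]; class(m_sub) <- class(m3)
  expect_error(growth_map(m3, m_sub), "grids")
})

test_that("map summaries contrast thickness at roots with the far field", {
  bump <- data.frame(x_mm = 5, y_mm = 5, amplitude_mm = 5, radius_mm = 3)
  cfg <- field_gen_config(extent_mm = 12, pitch_mm = 1, noise_sd_mm = 0,
                          Z_max_mm = 10, bumps = bump)
  m <- thickness_map(generate_field(cfg, step = 7), stride = 1)
  rt <- root(5, 5, 2, 200, "big")
  s <- summarize_map(m, rt, radius_mm = 3)
  expect_gt(s$per_root$at_root_mean_mm, s$far_field_mean_mm)
  expect_true(s$global_max_mm >= s$per_root$at_root_mean_mm)
  s0 <- summarize_map(m, rt, radius_mm = 0)
  expect_gte(s0$per_root$n_cells, 1)
  sg <- summarize_map(m)
  expect_null(sg$per_root)
  expect_true(is.finite(sg$global_max_mm))
  expect_warning(summarize_map(m, root(400, 0, 1, 200), radius_mm = 3),
                 "outside")
})
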