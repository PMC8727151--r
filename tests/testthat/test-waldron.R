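test_that("root inclination follows the arctangent of displacement over thickness", {
  expect_identical(compute_beta(0, 10), 0)
  # independent arctangent evaluation for u/Z = 2/3
  expect_equal(compute_beta(20, 30), atan2(2, 3), tolerance = 1e-15)
  # strictly decreasing in thickness at fixed displacement
  Zs <- seq(2, 30, by = 2)
  expect_true(all(diff(compute_beta(10, Zs)) < 0))
  expect_error(compute_beta(5, 0), "thickness")
  expect_error(compute_beta(-1, 10), ">= 0")
})

test_that("bond stress factor matches long-hand evaluation and square-root scaling", {
  # long-hand: 4 * 1.25 kPa * 30 mm * 200e3 kPa / 1 mm = 3e7 kPa^2
  expect_equal(bond_factor_k(1.25, 30, 200, 1), sqrt(3e7), tolerance = 1e-12)
  k1 <- bond_factor_k(1, 10, 100, 2)
  expect_equal(bond_factor_k(4, 10, 100, 2), 2 * k1, tolerance = 1e-12)
  # tau -> 0 limit
  expect_lt(bond_factor_k(1e-12, 10, 100, 2), 1e-2)
  expect_error(bond_factor_k(0, 10, 100, 2))
})

test_that("single-root contribution is zero at rest, linear in area ratio, and composes term by term", {
  r <- root(0, 0, 2, 200)
  soil <- soil_params(36)
  ifc <- interface_params(1.25)
  a_r <- pi / (pi * 51.5^2)
  expect_identical(root_delta_s(r, a_r, 0, 10, soil, ifc), 0)
  expect_equal(root_delta_s(r, 2 * a_r, 7, 10, soil, ifc),
               2 * root_delta_s(r, a_r, 7, 10, soil, ifc),
               tolerance = 1e-14)
  # term-by-term oracle: independent plain-arithmetic composition
  for (case in list(c(5, 8), c(12, 20), c(19, 3))) {
    u <- case[1]; Z <- case[2]
    beta <- atan(u / Z)
    k <- sqrt(4 * 1.25 * Z * 200e3 / 2)
    want <- a_r * k * sqrt(1 / cos(beta) - 1) *
      (sin(beta) + cos(beta) * tan(36 * pi / 180))
    expect_equal(root_delta_s(r, a_r, u, Z, soil, ifc), want,
                 tolerance = 1e-13)
  }
  expect_error(root_delta_s(r, -a_r, 5, 10, soil, ifc), ">= 0")
})

test_that("specimen contribution is additive over roots and matches the constant policy for centred roots", {
  base <- make_baseline()
  fallow <- specimen(NULL, soil_params(36, base), interface_params(1.25),
                     shear_zone_model())
  expect_identical(specimen_delta_s(fallow, 12, "constant", Z_mm = 10), 0)

  one <- make_specimen(roots = root(10, -5, 2, 200))
  two <- make_specimen(roots = rbind(root(10, -5, 2, 200),
                                     root(10, -5, 2, 200)))
  expect_equal(specimen_delta_s(two, 9, "positional"),
               2 * specimen_delta_s(one, 9, "positional"),
               tolerance = 1e-14)

  centred <- make_specimen(roots = rbind(root(0, 0, 2, 200),
                                         root(0, 0, 1, 500)))
  expect_equal(specimen_delta_s(centred, 9, "positional"),
               specimen_delta_s(centred, 9, "constant", Z_mm = 30),
               tolerance = 1e-14)
})

test_that("positional thickness interpolates linearly from centre to wall", {
  zone <- shear_zone_model(Z_min_mm = 2, Z_max_mm = 30, D_tube_mm = 103)
  expect_identical(local_shear_zone(zone, 0), 30)
  expect_equal(local_shear_zone(zone, 103 / 2), 2, tolerance = 1e-14)
  expect_equal(local_shear_zone(zone, 103 / 4), (30 + 2) / 2,
               tolerance = 1e-14)
  expect_error(local_shear_zone(zone, 60), "outside")
  expect_error(local_shear_zone(zone, -1), "outside")
})

test_that("growth schedule hits its waypoints, is continuous and non-decreasing, and floors at the tube gap", {
  zone <- shear_zone_model(u_step3_mm = 8.15, u_final_mm = 19.83)
  expect_identical(growth_factor(zone, 0), 0)
  expect_equal(growth_factor(zone, 8.15), 0.8, tolerance = 1e-14)
  expect_equal(growth_factor(zone, 19.83), 1, tolerance = 1e-14)
  expect_equal(growth_factor(zone, 25), 1, tolerance = 1e-14)
  expect_equal(growth_factor(zone, 8.15 / 2), 0.4, tolerance = 1e-14)
  u <- seq(0, 25, by = 0.01)
  f <- growth_factor(zone, u)
  expect_true(all(diff(f) >= -1e-12))
  expect_lt(max(abs(diff(f))), 0.005)  # no jumps on a fine grid
  # floor: at zero displacement the tube gap still exists
  expect_equal(grown_shear_zone(zone, 30, 0), 2, tolerance = 1e-14)
  expect_equal(grown_shear_zone(zone, 30, 8.15), 24, tolerance = 1e-12)
  expect_error(growth_factor(zone, -1), ">= 0")
})

test_that("root extension and axial stress follow their closed forms", {
  expect_identical(root_extension(30, 0), 0)
  # long-hand secant oracle: sec(atan(2/3)) = sqrt(13)/3
  expect_equal(root_extension(30, atan(2 / 3)), 30 * (sqrt(13) / 3 - 1),
               tolerance = 1e-13)
  betas <- seq(0, 1.4, by = 0.1)
  expect_true(all(diff(root_extension(30, betas)) > 0))
  expect_error(root_extension(30, pi / 2))

  expect_identical(axial_stress(0, 50, 200), 0)
  expect_equal(axial_stress(3, 50, 200), axial_stress(6, 100, 200),
               tolerance = 1e-14)
  expect_equal(axial_stress(2.5, 40, 180), 180 * 2.5 / 40,
               tolerance = 1e-14)
  expect_error(axial_stress(1, 0, 200))
})

test_that("stressed length equals its k-composition form and scales as tau^(-1/2)", {
  set.seed(11)
  for (i in 1:25) {
    tau <- runif(1, 0.2, 10); Z <- runif(1, 2, 30)
    E <- runif(1, 50, 800); D <- runif(1, 0.2, 4)
    beta <- runif(1, 0.01, 1.3)
    via_k <- bond_factor_k(tau, Z, E, D) * sqrt(1 / cos(beta) - 1) * D /
      (2 * tau)
    alg <- sqrt(Z * E * 1000 * D * (1 / cos(beta) - 1) / tau)
    l <- stressed_length(tau, Z, E, D, beta)
    expect_equal(l, via_k, tolerance = 1e-12)
    expect_equal(l, alg, tolerance = 1e-12)
    expect_equal(stressed_length(4 * tau, Z, E, D, beta), l / 2,
                 tolerance = 1e-12)
  }
  expect_identical(stressed_length(1, 10, 200, 1, 0), 0)
  expect_error(stressed_length(-1, 10, 200, 1, 0.3))
})

test_that("small-displacement limit matches the second-order series of the reinforcement formula", {
  r <- root(0, 0, 1, 200)
  soil <- soil_params(36); ifc <- interface_params(1.25)
  a_r <- 1e-3; Z <- 20
  errs <- vapply(c(0.1, 0.01), function(u) {
    beta <- atan(u / Z)
    k <- bond_factor_k(1.25, Z, 200, 1)
    series <- a_r * k * sqrt(beta^2 / 2) * (beta + tan(36 * pi / 180))
    ratio <- root_delta_s(r, a_r, u, Z, soil, ifc) / series
    expect_equal(ratio, 1, tolerance = max(beta^2, 1e-7))
    abs(ratio - 1)
  }, numeric(1))
  # the series error shrinks as the displacement shrinks
  expect_lt(errs[2], errs[1])
})

test_that("predicted curves respect the baseline, thickness ordering and per-root composition", {
  base <- make_baseline()
  fallow <- specimen(NULL, soil_params(36, base), interface_params(1.25),
                     shear_zone_model())
  u <- seq(0, 20, by = 1)
  cf <- predict_stress_curve(fallow, u, "constant", Z_mm = 10)
  expect_equal(cf$total_kpa, approx(base$u_mm, base$S_kpa, u)$y,
               tolerance = 1e-12)
  expect_true(all(cf$dS_kpa == 0))

  spec <- make_specimen()
  c2 <- predict_stress_curve(spec, u, "constant", Z_mm = 2)
  c30 <- predict_stress_curve(spec, u, "constant", Z_mm = 30)
  expect_true(all(c2$dS_kpa[u > 0] > c30$dS_kpa[u > 0]))

  # symmetric two-root layout: curve equals hand-composed grown contributions
  roots <- rbind(root(20, 0, 1.5, 200, "p"), root(-20, 0, 1.5, 200, "q"))
  spec2 <- make_specimen(roots = roots)
  cg <- predict_stress_curve(spec2, u, "positional_with_growth")
  zone <- spec2$zone
  Zp <- local_shear_zone(zone, 20)
  hand <- vapply(u, function(ui) {
    Zi <- grown_shear_zone(zone, Zp, ui)
    2 * root_delta_s(roots[1, ], pi * 0.75^2 / spec2$plane_area_mm2,
                     ui, Zi, spec2$soil, spec2$interface)
  }, numeric(1))
  expect_equal(cg$dS_kpa, hand, tolerance = 1e-12)

  expect_error(predict_stress_curve(spec, seq(0, 30, 5), "constant",
                                    Z_mm = 10), "baseline domain")
  expect_silent(predict_stress_curve(spec, seq(0, 30, 5), "constant",
                                     Z_mm = 10, extrapolate = TRUE))
})

test_that("sensitivity sweep reproduces the thickness and interface-stress trends", {
  tab <- sensitivity_sweep(Z_grid_mm = c(2, 10, 20, 30),
                           tau_grid_kpa = c(0.5, 1, 2.5, 5),
                           u_grid_mm = c(0, 5, 10, 20))
  expect_true(all(tab$dS_kpa[tab$u_mm == 0] == 0))
  for (u in c(5, 10, 20)) {
    for (tau in unique(tab$tau_kpa)) {
      s <- tab[tab$u_mm == u & tab$tau_kpa == tau, ]
      expect_true(all(diff(s$dS_kpa[order(s$Z_mm)]) < 0))
    }
    for (Z in unique(tab$Z_mm)) {
      s <- tab[tab$u_mm == u & tab$Z_mm == Z, ]
      expect_true(all(diff(s$dS_kpa[order(s$tau_kpa)]) > 0))
    }
  }
})
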