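# shared fixtures, all built in code

# hyperbolic fallow baseline over [0, u_max]
make_baseline <- function(u_max = 20, S_inf = 5, u_half = 2, n = 41) {
  u <- seq(0, u_max, length.out = n)
  data.frame(u_mm = u, S_kpa = S_inf * u / (u_half + u))
}

# willow-like three-root specimen in the standard tube
make_specimen <- function(roots = NULL, tau = 1.25, phi = 36,
                          zone = shear_zone_model(), baseline = make_baseline()) {
  if (is.null(roots))
    roots <- rbind(root(10, 0, 2, 200, "a"),
                   root(-25, 8, 1.5, 200, "b"),
                   root(40, 20, 1, 200, "c"))
  specimen(roots, soil_params(phi, baseline), interface_params(tau), zone)
}

# exact tri-linear profile sampled on z
make_trilinear_profile <- function(z = seq(-15, 15, by = 0.5),
                                   z_lower = -5, z_upper = 7,
                                   u_below = 10, u_above = 0) {
  w <- pmin(pmax((z - z_lower) / (z_upper - z_lower), 0), 1)
  data.frame(z_mm = z, ux_mm = u_below * (1 - w) + u_above * w)
}
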