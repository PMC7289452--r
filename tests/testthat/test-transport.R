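test_that("Henyey-Greenstein sampling matches its inversion formula", {
  expect_equal(sample_hg_deflection(0, 0.5), 0)
  expect_equal(sample_hg_deflection(0, c(0, 0.25, 1 - 1e-12)),
               c(-1, -0.5, 1), tolerance = 1e-9)
  # forward limit
  expect_gt(sample_hg_deflection(0.8, 1 - 1e-12), 0.9999)
  # closed-form check at an arbitrary quantile
  g <- 0.9; u <- 0.3
  expect_equal(sample_hg_deflection(g, u),
               (1 + g^2 - ((1 - g^2) / (1 - g + 2 * g * u))^2) / (2 * g))
  # E[cos theta] = g
  set.seed(31)
  expect_equal(mean(sample_hg_deflection(0.9, runif(2e5))), 0.9,
               tolerance = 0.003)
  expect_error(sample_hg_deflection(1, 0.5), "< 1")
})

test_that("Fresnel reflectance has the right limits and normal value", {
  expect_equal(fresnel_reflectance(1.37, 1.37, 0.4), 0)
  expect_equal(fresnel_reflectance(1.33, 1.37, 1),
               ((1.37 - 1.33) / (1.37 + 1.33))^2)
  expect_equal(fresnel_reflectance(1.33, 1.37, 1), 2.19e-4,
               tolerance = 0.005)
  # total internal reflection from the denser side
  crit <- asin(1.33 / 1.37)
  expect_equal(fresnel_reflectance(1.37, 1.33, cos(crit * 1.01)), 1)
  expect_lt(fresnel_reflectance(1.37, 1.33, cos(crit * 0.95)), 1)
  # reflectance grows towards grazing incidence
  r <- fresnel_reflectance(1.33, 1.37, cos(seq(0, 1.5, by = 0.25)))
  expect_true(all(diff(r) > 0))
})

test_that("clear void + absorbing wall reproduces the inverse-square law", {
  g <- sphere_48()
  p <- patches_48()
  cfg <- transport_config(n_packets = 2e5, seed = 7)
  dm <- run_transport(g, absorbing_map(), source_spec(c(0, 0, 0), 2500),
                      p, cfg)
  expected <- 2500 / (4 * pi * g$geom$r0^2) * 100  # mW/cm^2
  se <- sd(dm$surface_irradiance) / sqrt(p$n_patches)
  expect_lt(abs(dm$mean_irradiance - expected), 3 * se)
  expect_lt(sd(dm$surface_irradiance) / mean(dm$surface_irradiance), 0.05)
  expect_true(all(dm$surface_irradiance >= 0))
  expect_lt(abs(dm$conservation_residual), 1e-6)
  expect_lt(abs(dm$absorbed_fraction + dm$escaped_fraction - 1), 1e-9)

  # displaced source: primary light follows 1/r^2 at the proximal patch
  dm2 <- run_transport(g, absorbing_map(), source_spec(c(0, -10, 0), 2500),
                       p, transport_config(n_packets = 3e5, seed = 9))
  d <- sqrt(rowSums(sweep(p$patch_centers, 2, c(0, -10, 0))^2))
  k <- which.min(d)
  expect_equal(dm2$surface_irradiance[k], 2500 / (4 * pi * d[k]^2) * 100,
               tolerance = 0.1)
})

test_that("degenerate inputs are handled: zero power, bad source", {
  g <- sphere_48()
  p <- patches_48()
  cfg <- transport_config(n_packets = 1e3, seed = 1)
  dm0 <- run_transport(g, absorbing_map(), source_spec(c(0, 0, 0), 0), p, cfg)
  expect_true(all(dm0$surface_irradiance == 0))
  expect_true(all(dm0$volumetric_absorption$absorbed_mW_mm3 == 0))
  expect_error(run_transport(g, absorbing_map(),
                             source_spec(c(100, 0, 0)), p, cfg),
               "outside")
})

test_that("runs are deterministic given the seed", {
  g <- sphere_48()
  p <- patches_48()
  pm <- preset_map()
  cfg <- transport_config(n_packets = 2e4, seed = 123)
  a <- run_transport(g, pm, source_spec(), p, cfg)
  b <- run_transport(g, pm, source_spec(), p, cfg)
  expect_identical(a$surface_irradiance, b$surface_irradiance)
  expect_identical(a$volumetric_absorption, b$volumetric_absorption)
  expect_identical(a$absorbed_fraction, b$absorbed_fraction)
  c_ <- run_transport(g, pm, source_spec(), p,
                      transport_config(n_packets = 2e4, seed = 124))
  expect_false(identical(a$surface_irradiance, c_$surface_irradiance))
})

test_that("energy is conserved with the full 525-nm preset", {
  dm <- preset_run()
  expect_lt(abs(dm$conservation_residual), 1e-6)
  expect_lt(abs(dm$absorbed_fraction + dm$escaped_fraction - 1), 1e-9)
  # adipose backing is optically thick: essentially nothing escapes
  expect_lt(dm$escaped_fraction, 0.01)
})

test_that("depth profile decays at the diffusion-theory attenuation rate", {
  dm <- preset_run()
  va <- dm$volumetric_absorption
  # fit beyond ~2 transport mean free paths, before the adipose interface
  sel <- va$depth_mm > 1.2 & va$depth_mm < 2.8
  fit <- stats::lm(log(absorbed_mW_mm3) ~ depth_mm, data = va[sel, ])
  rate <- -unname(coef(fit)[2])
  mu_eff <- effective_attenuation(preset_map()$wall)
  expect_equal(rate, mu_eff, tolerance = 0.15)
})

test_that("Lambertian-wall cavity obeys the integrating-sphere law", {
  g <- sphere_48()
  p <- patches_48()
  cfg <- transport_config(n_packets = 2e5, seed = 5)
  lw0 <- run_lambertian_wall(g, source_spec(), 0, p, cfg)
  expect_equal(lw0$multiplication_factor, 1, tolerance = 1e-12)
  lw5 <- run_lambertian_wall(g, source_spec(), 0.5, p, cfg)
  expect_equal(lw5$multiplication_factor, 2, tolerance = 0.02)
  expect_lt(abs(lw5$conservation_residual), 1e-6)
  expect_error(run_lambertian_wall(g, source_spec(), 1, p, cfg), "rho")
  ge <- make_bladder_shape("ellipsoid", 50)
  expect_error(run_lambertian_wall(ge, source_spec(), 0.5, p, cfg),
               "spherical")
})

test_that("configuration validation rejects non-physical settings", {
  expect_error(transport_config(n_packets = 0), ">= 1")
  expect_error(transport_config(roulette_survival = 0), "survival")
  expect_error(source_spec(c(0, 0)), "3-vector")
  expect_error(source_spec(power_mW = -5), "non-negative")
})
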