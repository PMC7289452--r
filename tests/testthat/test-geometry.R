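test_that("sphere radii follow the closed form and volumes calibrate to 1%", {
  g <- sphere_48()
  expect_equal(g$geom$r0, (3 * 48500 / (4 * pi))^(1 / 3), tolerance = 1e-10)
  expect_equal(g$geom$r0, 22.6, tolerance = 0.005)
  expect_equal(g$volume_mm3, 48500, tolerance = 0.01)

  g173 <- make_bladder_shape("sphere", 173)
  expect_equal(g173$geom$r0, 34.6, tolerance = 0.005)

  for (spec in list(list("ellipsoid", 120, list(aspect = c(1, 0.8, 1.3))),
                    list("superellipsoid", 90, list(exponent = 3.5)),
                    list("lobulated", 85, list()))) {
    g2 <- make_bladder_shape(spec[[1]], spec[[2]], spec[[3]], seed = 7)
    expect_equal(g2$volume_mm3, spec[[2]] * 1000, tolerance = 0.01)
  }
})

test_that("sphere-equivalent radius converts ml to cm", {
  expect_equal(sphere_equivalent_radius(100), 2.879, tolerance = 5e-4)
  expect_equal(round(sphere_equivalent_radius(100)), 3)
  expect_equal(sphere_equivalent_radius(4 * pi / 3), 1, tolerance = 1e-12)
  expect_equal(sphere_equivalent_radius(48.5), 2.26, tolerance = 0.005)
  expect_error(sphere_equivalent_radius(-1), "positive")
})

test_that("invalid shape requests are rejected with a message", {
  expect_error(make_bladder_shape("sphere", -5), "positive")
  expect_error(make_bladder_shape("torus", 50), "arg")
  expect_error(make_bladder_shape("lobulated", 50,
                                  list(n_bumps = 10, amplitude = 0.2)),
               "star-shaped")
  expect_error(make_bladder_shape("sphere", 50, wall_thickness_mm = 0),
               "positive")
})

test_that("region labels partition space consistently with the layers", {
  g <- sphere_48()
  r0 <- g$geom$r0
  expect_equal(region_at(g, c(0, 0, 0)), "void")
  # mid-wall point along an arbitrary ray
  u <- c(1, 2, -0.5) / sqrt(5.25)
  expect_equal(region_at(g, (r0 + g$wall_thickness_mm / 2) * u), "wall")
  expect_equal(region_at(g, (r0 + g$wall_thickness_mm + 1) * u), "adipose")
  expect_equal(region_at(g, c(500, 0, 0)), "outside")
  # signs of the implicit field match the labels
  expect_lt(g$implicit_fn(c(5, 5, 5)), 0)
  expect_gt(g$implicit_fn(c(r0 + 1, 0, 0)), 0)
  expect_error(region_at(g, c(Inf, 0, 0)), "finite")
})

test_that("all generated shapes are star-shaped about the centre", {
  for (spec in list(list("ellipsoid", 120, list(aspect = c(1, 0.7, 1.4))),
                    list("lobulated", 85, list(n_bumps = 6,
                                               amplitude = 0.12)))) {
    g <- make_bladder_shape(spec[[1]], spec[[2]], spec[[3]], seed = 11)
    set.seed(2)
    u <- matrix(rnorm(3000), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    tt <- seq(0.5, 80, by = 0.1)
    crossings <- vapply(seq_len(nrow(u)), function(i) {
      f <- g$implicit_fn(outer(tt, u[i, ]))
      sum(diff(sign(f)) != 0)
    }, numeric(1))
    expect_true(all(crossings == 1))
  }
})

test_that("identical seeds reproduce the lobulated shape bit-for-bit", {
  g1 <- make_bladder_shape("lobulated", 85, seed = 42)
  g2 <- make_bladder_shape("lobulated", 85, seed = 42)
  expect_identical(g1$geom, g2$geom)
  set.seed(5)
  pts <- matrix(rnorm(300, sd = 30), ncol = 3)
  expect_identical(g1$implicit_fn(pts), g2$implicit_fn(pts))
  g3 <- make_bladder_shape("lobulated", 85, seed = 43)
  expect_false(identical(g1$geom, g3$geom))
})

test_that("tessellation areas agree with analytic and quadrature oracles", {
  g <- sphere_48()
  p <- patches_48()
  expect_equal(p$n_patches, 200L)
  expect_equal(sum(p$patch_areas), 4 * pi * g$geom$r0^2, tolerance = 0.01)
  expect_equal(sum(p$patch_areas), 6418, tolerance = 0.01)
  # sphere patches are quasi-uniform (within 20% of the mean)
  expect_true(all(abs(p$patch_areas / mean(p$patch_areas) - 1) < 0.2))
  # outward unit normals point radially for a sphere
  nr <- rowSums(p$patch_normals * p$patch_centers) /
    sqrt(rowSums(p$patch_centers^2))
  expect_true(all(abs(nr - 1) < 1e-6))

  p12 <- tessellate_surface(g, 12)
  expect_equal(p12$n_patches, 12L)
  expect_error(tessellate_surface(g, 6), "at least 12")

  skip_if_not_installed("pracma")
  ge <- make_bladder_shape("ellipsoid", 120, list(aspect = c(1, 0.8, 1.3)))
  pe <- tessellate_surface(ge, 150)
  ax <- ge$geom$axes
  f <- function(th, ph)
    sqrt((ax[2] * ax[3] * sin(th)^2 * cos(ph))^2 +
         (ax[1] * ax[3] * sin(th)^2 * sin(ph))^2 +
         (ax[1] * ax[2] * sin(th) * cos(th))^2)
  A_oracle <- pracma::integral2(f, 0, pi, 0, 2 * pi)$Q
  expect_equal(sum(pe$patch_areas), A_oracle, tolerance = 0.01)
})
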