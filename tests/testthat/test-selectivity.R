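test_that("uptake and threshold ratios reproduce the preclinical values", {
  m <- threshold_model()
  expect_equal(specific_uptake_ratio(m), 77 / 0.4)
  expect_equal(specific_uptake_ratio(m), 192.5)
  expect_equal(threshold_ratio(m, "urothelium"), 2.121 / 0.161)
  expect_equal(threshold_ratio(m, "urothelium"), 13.2, tolerance = 0.005)
  expect_equal(threshold_ratio(m, "muscle"), 16.6, tolerance = 0.005)
  m_eq <- threshold_model(T_tumor = 2, T_urothelium = 1, T_muscle = 1,
                          uptake_tumor = 1, uptake_normal = 1)
  expect_equal(specific_uptake_ratio(m_eq), 1)
  # SUR is linear in tumor uptake
  m2 <- threshold_model(uptake_tumor = 154)
  expect_equal(specific_uptake_ratio(m2), 2 * specific_uptake_ratio(m))
  expect_error(threshold_model(uptake_normal = 0), "positive")
  expect_error(threshold_model(T_tumor = 0.1), "selective")
})

test_that("allowable fluence ratio combines SUR and threshold contrast", {
  expect_equal(allowable_fluence_ratio(192, 0.0757), 14.53, tolerance = 0.001)
  expect_equal(allowable_fluence_ratio(192, 0.0757), 14.5, tolerance = 0.005)
  expect_equal(allowable_fluence_ratio(192, 0.161 / 2.121), 14.58,
               tolerance = 0.001)
  expect_equal(allowable_fluence_ratio(1, 1), 1)
  # multiplicative in SUR
  expect_equal(allowable_fluence_ratio(384, 0.0757),
               2 * allowable_fluence_ratio(192, 0.0757))
  expect_error(allowable_fluence_ratio(-1, 0.1), "positive")
})

test_that("selectivity depth modes give their closed forms", {
  expect_equal(selectivity_depth(mode = "attenuation_lengths",
                                 mu_eff_inv_mm = 0.75), 1.875)
  expect_equal(selectivity_depth(14.5, 0.75, "planar"), log(14.5) * 0.75)
  expect_equal(selectivity_depth(14.5, 0.75, "planar"), 2.01,
               tolerance = 0.005)
  expect_equal(selectivity_depth(1, 0.75, "planar"), 0)
  # logarithmic in the ratio, linear in the attenuation length
  expect_equal(selectivity_depth(14.5^2, 0.75, "planar"),
               2 * selectivity_depth(14.5, 0.75, "planar"))
  expect_equal(selectivity_depth(14.5, 1.5, "planar"),
               2 * selectivity_depth(14.5, 0.75, "planar"))
  expect_error(selectivity_depth(14.5, 0.75, "spherical"), "radius")
  expect_error(selectivity_depth(0.5, 0.75, "planar"), ">= 1")
})

test_that("spherical divergence always shortens the selective depth", {
  for (R in seq(20, 40, by = 5)) {
    d_sph <- selectivity_depth(14.5, 0.75, "spherical",
                               sphere_radius_mm = R)
    d_pl <- selectivity_depth(14.5, 0.75, "planar")
    expect_lt(d_sph, d_pl)
    # consistency: the spherical profile at that depth hits the ratio
    prof <- fluence_profile_spherical(d_sph, 0.75, R)
    expect_equal(prof$ratio, 14.5, tolerance = 1e-6)
  }
})

test_that("profile checks flag the loss of selectivity at depth", {
  m <- threshold_model()
  flat <- structure(data.frame(depth_mm = seq(0, 3, 0.1), ratio = 1),
                    class = c("fluence_profile", "data.frame"))
  chk <- check_selectivity_profile(m, flat, 3)
  expect_true(all(chk$selective))
  expect_equal(chk$margin, rep(attr(chk, "allowable_ratio"), nrow(chk)))

  prof <- fluence_profile_planar(seq(0, 3, 0.01), 0.75)
  chk2 <- check_selectivity_profile(m, prof, 3)
  allowable <- specific_uptake_ratio(m) / threshold_ratio(m, "urothelium")
  d_loss <- log(allowable) * 0.75
  expect_equal(max(chk2$depth_mm[chk2$selective]), d_loss, tolerance = 0.01)

  # allowable ratio of exactly 1: nothing below the surface is selective
  m1 <- threshold_model(T_tumor = 2, T_urothelium = 1, T_muscle = 1,
                        uptake_tumor = 2, uptake_normal = 1)
  chk3 <- check_selectivity_profile(m1, prof, 3)
  expect_true(all(!chk3$selective[chk3$depth_mm > 0]))

  expect_error(check_selectivity_profile(m, prof, 5), "cover")
})

test_that("transport-derived fluence profiles keep ~1.5 mm selective", {
  dm <- preset_run()
  prof <- fluence_profile_from_transport(dm, preset_map(), max_depth_mm = 3)
  expect_true(all(prof$ratio >= 1))
  # beyond the sub-surface build-up region the ratio grows monotonically
  deep <- prof$ratio[prof$depth_mm > 0.5]
  expect_true(all(diff(deep) > 0))
  chk <- check_selectivity_profile(threshold_model(), prof, 2.5)
  expect_true(all(chk$selective[chk$depth_mm <= 1.5]))
  # and selectivity is lost within the wall, not far beyond the 2-mm aim
  expect_false(all(chk$selective))
})
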