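test_that("acceptance cone solid angle follows the NA formula", {
  expect_equal(acceptance_solid_angle(1.33, 1.33), 2 * pi)
  expect_equal(acceptance_solid_angle(0.625, 1.33), 0.737, tolerance = 1e-3)
  expect_lt(acceptance_solid_angle(1e-4, 1.33), 1e-7)
  expect_error(acceptance_solid_angle(1.4, 1.33), "exceed")
  expect_error(acceptance_solid_angle(0), "positive")
})

test_that("sensor sets have the documented layouts", {
  g <- sphere_48()
  single <- build_sensor_set(g, "single")
  expect_length(single, 1)
  expect_equal(single[[1]]$kind, "cut_end")
  # at the neck pole (-z), aimed at the void centre
  expect_equal(single[[1]]$position, c(0, 0, -g$geom$r0), tolerance = 1e-9)
  expect_equal(single[[1]]$axis, c(0, 0, 1), tolerance = 1e-9)

  triple <- build_sensor_set(g, "triple")
  expect_length(triple, 3)
  expect_true(all(vapply(triple, function(s) s$kind, "") == "angled_cut"))
  expect_true(all(vapply(triple, function(s) s$polish_angle_deg, 1) == 25))

  cage <- build_sensor_set(g, "cage12")
  expect_length(cage, 12)
  expect_true(all(vapply(cage, function(s) s$kind, "") == "isotropic_2pi"))
  az <- sort(unique(round((atan2(
    vapply(cage, function(s) s$position[2], 1),
    vapply(cage, function(s) s$position[1], 1)) * 180 / pi) %% 360)))
  expect_equal(az, c(0, 120, 240))
  # all sensors on the inner surface, facing the void
  for (s in cage) {
    expect_lt(abs(g$implicit_fn(s$position)), 1e-6)
    expect_lt(sum(s$axis * s$position), 0)
  }
})

test_that("every sensor kind reads E0 in a uniform diffuse field", {
  set.seed(42)
  n <- 2e5
  z <- -sqrt(runif(n))                     # cosine-weighted into the wall
  phi <- runif(n, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  E0 <- 3.7   # mW/cm^2 over a 1-cm^2 patch
  cl <- crossing_log(dirs, rep(E0 / n, n), normal = c(0, 0, -1),
                     area_cm2 = 1)
  sens <- list(sensor_spec("isotropic_2pi", c(0, 0, 0), c(0, 0, 1),
                           id = "iso"),
               sensor_spec("cut_end", c(0, 0, 0), c(0, 0, 1), id = "cut"),
               sensor_spec("angled_cut", c(0, 0, 0),
                           tilt <- c(sin(25 * pi / 180), 0,
                                     cos(25 * pi / 180)), id = "ang"))
  rd <- sensor_readings(cl, sens)
  expect_equal(rd$irradiance_estimate, rep(E0, 3), tolerance = 0.02)
})

test_that("a collimated normal beam reads with the known diffuse-calibration bias", {
  # diffuse-field calibration implies a cos^2 sensor over-reads a normal
  # collimated beam by exactly 3/2, a cone sensor by pi/Omega
  dirs <- matrix(rep(c(0, 0, -1), 10), ncol = 3, byrow = TRUE)
  cl <- crossing_log(dirs, rep(0.1, 10), normal = c(0, 0, -1), area_cm2 = 1)
  iso <- sensor_readings(cl, sensor_spec("isotropic_2pi", c(0, 0, 0),
                                         c(0, 0, 1)))
  expect_equal(iso$irradiance_estimate, 1.5)
  cut <- sensor_readings(cl, sensor_spec("cut_end", c(0, 0, 0), c(0, 0, 1)))
  expect_equal(cut$irradiance_estimate,
               pi / acceptance_solid_angle(0.625, 1.33), tolerance = 1e-9)
  # source outside the acceptance cone: no primary signal
  oblique <- matrix(rep(c(sin(0.8), 0, -cos(0.8)), 10), ncol = 3,
                    byrow = TRUE)
  cl2 <- crossing_log(oblique, rep(0.1, 10), normal = c(0, 0, -1),
                      area_cm2 = 1)
  cut2 <- sensor_readings(cl2, sensor_spec("cut_end", c(0, 0, 0),
                                           c(0, 0, 1)))
  expect_equal(cut2$irradiance_estimate, 0)
})

test_that("virtual sensors read a transport run and track the true mean", {
  g <- sphere_48()
  p <- patches_48()
  cfg <- transport_config(n_packets = 1e5, seed = 21,
                          record_crossings = TRUE)
  dm <- run_transport(g, absorbing_map(), source_spec(), p, cfg)
  cage <- build_sensor_set(g, "cage12")
  rd <- sensor_readings(dm, cage, p)
  expect_equal(nrow(rd), 12)
  # absorbing wall, central source: pure normal primary, so each cos^2
  # sensor reads ~1.5 x P/(4 pi r^2) (slightly less: neighbour-patch
  # pooling tilts the primary a few degrees off each sensor's axis)
  expected <- 1.5 * 2500 / (4 * pi * g$geom$r0^2) * 100
  expect_equal(mean(rd$irradiance_estimate), expected, tolerance = 0.1)
  ratio <- mean_irradiance_ratio(dm, rd, p)
  expect_equal(ratio, 1 / 1.5, tolerance = 0.1)
  # readings require a crossing log
  dm_nolog <- run_transport(g, absorbing_map(), source_spec(), p,
                            transport_config(n_packets = 1e4, seed = 2))
  expect_error(sensor_readings(dm_nolog, cage, p), "record_crossings")
})

test_that("calibration applies responsivity and the water-immersion factor", {
  expect_equal(apply_calibration(10, 1, "water"), 15.8)
  expect_equal(apply_calibration(10, 1, "air"), 10)
  expect_equal(apply_calibration(10, 2, "air"), 5)
  expect_equal(apply_calibration(4, 0.5, "water"),
               2 * apply_calibration(2, 0.5, "water"))
  expect_error(apply_calibration(1, 0, "air"), "positive")
})

test_that("synthetic traces are reproducible and respond to their knobs", {
  tr1 <- synth_trace(600, 1, 4, noise_sd = 0.5, seed = 9)
  tr2 <- synth_trace(600, 1, 4, noise_sd = 0.5, seed = 9)
  expect_identical(tr1$irradiance, tr2$irradiance)
  flat <- synth_trace(600, 1, 3, mean_irradiance = 20, sensor_spread = 0,
                      noise_sd = 0, seed = 1)
  expect_true(all(flat$irradiance == 20))
  intr <- synth_trace(600, 1, 3, mean_irradiance = 20, sensor_spread = 0,
                      baseline_offset = 0.5,
                      interruptions = list(c(100, 200)), seed = 1)
  expect_true(all(intr$irradiance[intr$time >= 100 & intr$time < 200, ]
                  == 0.5))
})

test_that("exposure integration terminates exactly at the target", {
  tr <- synth_trace(4000, 1, 4, mean_irradiance = 30, sensor_spread = 0,
                    seed = 1)
  out <- integrate_exposure(tr, 90)
  expect_equal(out$termination_time_s, 3000)
  expect_true(all(out$responding))
  # a 600-s interruption delays termination additively
  tri <- synth_trace(4000, 1, 4, mean_irradiance = 30, sensor_spread = 0,
                     interruptions = list(c(1000, 1600)), seed = 1)
  expect_equal(integrate_exposure(tri, 90)$termination_time_s, 3600)
  # time-grid refinement does not move the termination
  tr4 <- synth_trace(4000, 0.25, 4, mean_irradiance = 30,
                     sensor_spread = 0, seed = 1)
  expect_equal(integrate_exposure(tr4, 90)$termination_time_s, 3000,
               tolerance = 1e-9)
})

test_that("dead sensors are excluded and baselines subtracted", {
  tr <- synth_trace(4000, 1, 4, mean_irradiance = 30, sensor_spread = 0,
                    baseline_offset = 2, dead_sensors = 4, seed = 1)
  out <- integrate_exposure(tr, 90)
  expect_equal(unname(out$responding), c(TRUE, TRUE, TRUE, FALSE))
  # baseline is removed before integration: termination still at 3000 s
  expect_equal(out$termination_time_s, 3000)
  expect_equal(unname(out$exposure_J_cm2[4]), 0)
  dead_all <- synth_trace(400, 1, 3, mean_irradiance = 30,
                          dead_sensors = 1:3, seed = 1)
  expect_error(integrate_exposure(dead_all, 90), "no responding")
})

test_that("a downward drift postpones reaching the target exposure", {
  drift <- synth_trace(6000, 1, 4, mean_irradiance = 30, sensor_spread = 0,
                       drift_frac = -0.2, seed = 1)
  out <- integrate_exposure(drift, 90)
  expect_gt(out$termination_time_s, 3000)
})

test_that("trace CSV round-trips including metadata", {
  tr <- synth_trace(300, 1, 3, baseline_offset = 1.5,
                    interruptions = list(c(50, 80)), noise_sd = 0.3,
                    seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- read_trace_csv(path)
  expect_equal(back$time, tr$time)
  expect_equal(unname(back$irradiance), unname(tr$irradiance),
               tolerance = 1e-6)
  expect_equal(back$baseline_offset, 1.5)
  expect_equal(back$interruption_intervals[[1]], c(50, 80))
})
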