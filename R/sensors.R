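#' Acceptance solid angle of a fiber sensor
#'
#' Solid angle of the acceptance cone of an optical fiber of numerical
#' aperture `NA` immersed in a medium of index `n_medium`:
#' `Omega = 2 pi (1 - cos(asin(NA / n_medium)))`.
#'
#' @param numerical_aperture fiber NA (0 < NA <= n_medium).
#' @param n_medium refractive index of the surrounding medium (1.33 for a
#'   water-filled bladder).
#' @return solid angle in steradians.
#' @examples
#' acceptance_solid_angle(0.625, 1.33)   # ~0.737 sr
#' @export
acceptance_solid_angle <- function(numerical_aperture, n_medium = 1.33) {
  if (any(numerical_aperture <= 0)) stop("NA must be positive")
  if (any(numerical_aperture > n_medium))
    stop("NA cannot exceed the medium's refractive index")
  2 * pi * (1 - cos(asin(numerical_aperture / n_medium)))
}

#' Specify a virtual irradiance sensor
#'
#' @param kind `"cut_end"` (bare fiber tip, NA-limited cone acceptance),
#'   `"isotropic_2pi"` (epoxy-bulb sensor with a blackened backside,
#'   cos^2 angular response over the void-facing hemisphere), or
#'   `"angled_cut"` (fiber polished at ~25 deg, cone acceptance about a
#'   tilted axis).
#' @param position sensor position on the inner wall, mm.
#' @param axis unit vector the sensor looks along (into the void).
#' @param numerical_aperture fiber NA (cone-limited kinds; default 0.625).
#' @param polish_angle_deg polish angle for `angled_cut` (default 25).
#' @param angular_response `"cosine_squared"` or `"cone"`; defaults by kind
#'   (`isotropic_2pi` uses the measured cos^2 law, fiber kinds a top-hat
#'   cone). A cosine-squared fiber can be requested for sensitivity
#'   analysis.
#' @param responsivity raw-signal units per mW cm^-2 (default 1).
#' @param id sensor label.
#' @return object of class `sensor_spec`.
#' @export
sensor_spec <- function(kind = c("cut_end", "isotropic_2pi", "angled_cut"),
                        position, axis,
                        numerical_aperture = 0.625,
                        polish_angle_deg = 25,
                        angular_response = NULL,
                        responsivity = 1,
                        id = kind) {
  kind <- match.arg(kind)
  axis <- as.numeric(axis)
  axis <- axis / sqrt(sum(axis^2))
  if (kind != "isotropic_2pi" &&
      (numerical_aperture <= 0 || numerical_aperture >= 1.6))
    stop("fiber NA must be positive and physically plausible")
  angular_response <- angular_response %||%
    if (kind == "isotropic_2pi") "cosine_squared" else "cone"
  structure(list(kind = kind, position = as.numeric(position), axis = axis,
                 numerical_aperture = numerical_aperture,
                 polish_angle_deg = polish_angle_deg,
                 angular_response = angular_response,
                 responsivity = responsivity, id = id),
            class = "sensor_spec")
}

# rotate unit vector v by angle_deg towards unit vector t (Gram-Schmidt)
tilt_towards <- function(v, t, angle_deg) {
  t_perp <- t - sum(t * v) * v
  nt <- sqrt(sum(t_perp^2))
  if (nt < 1e-12) return(v)
  a <- angle_deg * pi / 180
  cos(a) * v + sin(a) * t_perp / nt
}

# inner-surface point and inward axis for a polar/azimuth direction
surface_point <- function(geometry, polar_deg, azimuth_deg) {
  th <- polar_deg * pi / 180
  ph <- azimuth_deg * pi / 180
  u <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  r <- as.numeric(radius_cpp(geometry$geom, rbind(u)))
  list(position = r * u, u = u)
}

#' Build the sensor layout of a monitoring implementation
#'
#' Three device designs are modelled.  The bladder dome is the +z pole and
#' the bladder neck (urethral entry) the -z pole.
#' \describe{
#'   \item{`single`}{one cut-end fiber at the neck pole, aimed at the void
#'     centre.}
#'   \item{`triple`}{three angled-cut fibers near the neck at 120-deg
#'     azimuthal spacing, each acceptance axis tilted by the polish angle
#'     (~25 deg) towards its azimuth so the three observe different wall
#'     areas.}
#'   \item{`cage12`}{twelve isotropic (2 pi sr, cos^2-response) sensors on
#'     the inner wall: three columns 120 deg apart in azimuth, four sensors
#'     per column at equal polar spacing from dome (20 deg) towards neck
#'     (140 deg), facing inward.}
#' }
#'
#' @param geometry a [make_bladder_shape()] object.
#' @param implementation `"single"`, `"triple"`, or `"cage12"`.
#' @return list of [sensor_spec()] objects.
#' @export
build_sensor_set <- function(geometry,
                             implementation = c("single", "triple",
                                                "cage12")) {
  implementation <- match.arg(implementation)
  stopifnot(inherits(geometry, "bladder_geometry"))
  ctr <- geometry$center
  if (implementation == "single") {
    sp <- surface_point(geometry, 180, 0)
    axis <- -sp$position
    return(list(sensor_spec("cut_end", sp$position,
                            axis / sqrt(sum(axis^2)), id = "single_1")))
  }
  if (implementation == "triple") {
    out <- vector("list", 3)
    for (j in 1:3) {
      az <- (j - 1) * 120
      sp <- surface_point(geometry, 165, az)
      inward <- -sp$u
      tangent <- c(cos(az * pi / 180), sin(az * pi / 180), 0)
      axis <- tilt_towards(inward, tangent, 25)
      out[[j]] <- sensor_spec("angled_cut", sp$position, axis,
                              polish_angle_deg = 25,
                              id = paste0("triple_", j))
    }
    return(out)
  }
  # cage12
  out <- list()
  for (az in c(0, 120, 240)) {
    for (polar in seq(20, 140, length.out = 4)) {
      sp <- surface_point(geometry, polar, az)
      out[[length(out) + 1]] <-
        sensor_spec("isotropic_2pi", sp$position, -sp$u,
                    id = sprintf("cage_a%03d_p%03.0f", az, polar))
    }
  }
  out
}

# normalization constant so a uniform diffuse (Lambertian) field of
# irradiance E0 is read as E0: C = pi / integral of R(angle) over the
# hemisphere
sensor_norm_constant <- function(sensor, n_medium = 1.33) {
  if (sensor$angular_response == "cosine_squared") {
    3 / 2                          # pi / (2 pi / 3)
  } else {
    theta_c <- asin(min(sensor$numerical_aperture / n_medium, 1))
    0.5 / (1 - cos(theta_c))       # pi / (2 pi (1 - cos theta_c))
  }
}

# per-crossing response: d = propagation direction (into the wall),
# axis points into the void
sensor_response <- function(sensor, d, n_medium = 1.33) {
  cos_beta <- -(d %*% sensor$axis)[, 1]
  if (sensor$angular_response == "cosine_squared") {
    pmax(cos_beta, 0)^2
  } else {
    theta_c <- asin(min(sensor$numerical_aperture / n_medium, 1))
    as.numeric(cos_beta >= cos(theta_c))
  }
}

#' Construct a synthetic surface-crossing log
#'
#' A minimal stand-in for the engine's crossing record: a set of surface
#' crossings (propagation directions and packet weights) through a patch of
#' known area and outward normal.  Used to feed [sensor_readings()] with
#' analytically generated fields (e.g. a uniform diffuse field) when testing
#' sensor normalization.
#'
#' @param directions n x 3 matrix of propagation directions (into the wall).
#' @param weights packet weights (power = `weight * power_per_weight` mW).
#' @param normal outward surface normal.
#' @param area_cm2 patch area in cm^2.
#' @param power_per_weight mW carried by unit weight (default 1).
#' @return object of class `crossing_log`.
#' @export
crossing_log <- function(directions, weights, normal, area_cm2,
                         power_per_weight = 1) {
  directions <- rbind(directions)
  normal <- normal / sqrt(sum(normal^2))
  structure(list(directions = directions, weights = weights,
                 normal = normal, area_cm2 = area_cm2,
                 power_per_weight = power_per_weight),
            class = "crossing_log")
}

#' Read virtual irradiance sensors against a light field
#'
#' Computes what each sensor would report given the angular distribution of
#' light crossing the surface where it sits.  Every sensor kind is
#' normalized so that a uniform diffuse field of irradiance `E0` reads
#' exactly `E0`; deviations of a reading from the local irradiance are then
#' purely due to the anisotropy of the actual field (primary-light
#' dominance, shape effects), which is the effect under study.
#'
#' For a `dose_maps` input the run must have been made with
#' `record_crossings = TRUE`; each sensor is snapped to its nearest surface
#' patch and reads the crossing log of that patch plus its
#' `neighborhood_k - 1` nearest neighbours (variance reduction).
#'
#' @param x a `dose_maps` (with crossing log) or a [crossing_log()].
#' @param sensors list of [sensor_spec()] (or a single one).
#' @param ... passed to methods.
#' @return data.frame of class `sensor_readings`: `sensor_id`, `kind`,
#'   `irradiance_estimate` (mW cm^-2), `accepted_weight`.
#' @export
sensor_readings <- function(x, sensors, ...) UseMethod("sensor_readings")

#' @param patches the [tessellate_surface()] object of the run.
#' @param n_medium refractive index of the void medium (1.33).
#' @param neighborhood_k number of patches pooled per sensor (default 5).
#' @rdname sensor_readings
#' @export
sensor_readings.dose_maps <- function(x, sensors, patches,
                                      n_medium = 1.33,
                                      neighborhood_k = 5, ...) {
  if (is.null(x$crossings))
    stop("run_transport() must be called with record_crossings = TRUE ",
         "for direction-sensitive sensor readings")
  if (inherits(sensors, "sensor_spec")) sensors <- list(sensors)
  cr <- x$crossings
  w_per_packet <- x$power_mW / x$n_packets_run
  dmat <- as.matrix(cr[, c("dx", "dy", "dz")])
  rows <- lapply(sensors, function(s) {
    # snap to nearest patch centers by direction
    su <- s$position / sqrt(sum(s$position^2))
    dots <- patches$patch_dirs %*% su
    pset <- order(dots, decreasing = TRUE)[seq_len(neighborhood_k)]
    sel <- cr$patch %in% pset
    area_cm2 <- sum(patches$patch_areas[pset]) / 100
    if (!any(sel)) {
      return(data.frame(sensor_id = s$id, kind = s$kind,
                        irradiance_estimate = 0, accepted_weight = 0))
    }
    resp <- sensor_response(s, dmat[sel, , drop = FALSE], n_medium)
    # flux -> radiance conversion: weight w crossing at incidence cosine
    # ci contributes w / ci to the radiance integral (cosine floored to
    # bound the variance of grazing crossings)
    ci <- pmax(cr$cos_incidence[sel], 0.05)
    raw <- sum(cr$weight[sel] * resp / ci) * w_per_packet / area_cm2
    est <- sensor_norm_constant(s, n_medium) * raw
    data.frame(sensor_id = s$id, kind = s$kind,
               irradiance_estimate = est,
               accepted_weight = sum(cr$weight[sel] * (resp > 0)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sensor_readings", class(out))
  out
}

#' @rdname sensor_readings
#' @export
sensor_readings.crossing_log <- function(x, sensors, n_medium = 1.33, ...) {
  if (inherits(sensors, "sensor_spec")) sensors <- list(sensors)
  ci <- pmax((x$directions %*% x$normal)[, 1], 0.05)
  rows <- lapply(sensors, function(s) {
    resp <- sensor_response(s, x$directions, n_medium)
    raw <- sum(x$weights * resp / ci) * x$power_per_weight / x$area_cm2
    data.frame(sensor_id = s$id, kind = s$kind,
               irradiance_estimate = sensor_norm_constant(s, n_medium) * raw,
               accepted_weight = sum(x$weights * (resp > 0)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sensor_readings", class(out))
  out
}

#' True-mean to sensor-mean irradiance ratio
#'
#' Ratio of the area-weighted true mean wall irradiance (from the transport
#' run) to the arithmetic mean of the sensor estimates.  A perfect
#' monitoring implementation gives 1; the spread of this ratio across
#' optical-property space measures how robustly an implementation tracks
#' the average dose.
#'
#' @param dose_maps a [run_transport()] result.
#' @param readings a [sensor_readings()] data.frame.
#' @param patches the run's [tessellate_surface()] object.
#' @return dimensionless ratio.
#' @export
mean_irradiance_ratio <- function(dose_maps, readings, patches) {
  if (nrow(readings) < 1) stop("need at least one sensor reading")
  sensor_mean <- mean(readings$irradiance_estimate)
  if (sensor_mean <= 0) stop("zero mean sensor reading")
  true_mean <- sum(dose_maps$surface_irradiance * patches$patch_areas) /
    sum(patches$patch_areas)
  true_mean / sensor_mean
}

#' Convert a raw sensor signal to irradiance
#'
#' Divides the raw signal by the sensor responsivity; when the sensor was
#' calibrated in air but deployed in the water-filled bladder, the
#' refractive-index change requires an additional correction factor of
#' 1.58.
#'
#' @param raw_signal raw signal (responsivity units).
#' @param responsivity signal per mW cm^-2 (> 0).
#' @param medium `"water"` (apply the 1.58 air-to-water correction) or
#'   `"air"`.
#' @return irradiance in mW cm^-2.
#' @examples
#' apply_calibration(10, 1, "water")   # 15.8
#' @export
apply_calibration <- function(raw_signal, responsivity,
                              medium = c("water", "air")) {
  medium <- match.arg(medium)
  if (responsivity <= 0) stop("'responsivity' must be positive")
  irr <- raw_signal / responsivity
  if (medium == "water") irr <- irr * 1.58
  irr
}

#' Generate a synthetic irradiance time trace
#'
#' Emulates the irradiance traces recorded during a monitored treatment:
#' several sensors with a spread of base irradiances, slow drift (e.g.
#' from accumulating void turbidity), delivery interruptions (source off,
#' only the cystoscope-light baseline remains), a constant baseline offset
#' from the cystoscope illumination, measurement noise, and optionally
#' dead sensors reading exactly zero.
#'
#' @param duration_s trace length, s.
#' @param dt_s sampling interval, s.
#' @param n_sensors number of sensors.
#' @param mean_irradiance mean base irradiance, mW cm^-2 (default 30).
#' @param sensor_spread relative spread of per-sensor base irradiance.
#' @param drift_frac total fractional drift over the trace (e.g. -0.2 for
#'   a 20\% decline).
#' @param noise_sd additive Gaussian noise sd, mW cm^-2.
#' @param baseline_offset cystoscope-light offset, mW cm^-2.
#' @param interruptions list of `c(start, end)` intervals (s) with the
#'   source off.
#' @param dead_sensors indices of sensors reading exactly zero.
#' @param seed RNG seed; identical seeds give identical traces.
#' @return object of class `irradiance_trace`: `time` (s), `irradiance`
#'   (time x sensor matrix, mW cm^-2), `baseline_offset`,
#'   `interruption_intervals`.
#' @export
synth_trace <- function(duration_s = 4000, dt_s = 1, n_sensors = 8,
                        mean_irradiance = 30, sensor_spread = 0.2,
                        drift_frac = 0, noise_sd = 0,
                        baseline_offset = 0, interruptions = list(),
                        dead_sensors = integer(0), seed = 1L) {
  time <- seq(0, duration_s, by = dt_s)
  with_local_seed(seed, {
    base <- mean_irradiance *
      (1 + stats::runif(n_sensors, -sensor_spread, sensor_spread))
    on <- rep(1, length(time))
    for (iv in interruptions) on[time >= iv[1] & time < iv[2]] <- 0
    drift <- 1 + drift_frac * time / max(duration_s, 1)
    irr <- outer(on * drift, base) + baseline_offset
    if (noise_sd > 0)
      irr <- irr + matrix(stats::rnorm(length(irr), 0, noise_sd),
                          nrow = nrow(irr))
    irr <- pmax(irr, 0)
    if (length(dead_sensors)) irr[, dead_sensors] <- 0
    colnames(irr) <- paste0("sensor_", seq_len(n_sensors))
    structure(list(time = time, irradiance = irr,
                   baseline_offset = baseline_offset,
                   interruption_intervals = interruptions),
              class = "irradiance_trace")
  })
}

#' Integrate an irradiance trace to radiant exposure and find termination
#'
#' Reproduces the clinical monitoring rule: the cystoscope-light baseline is
#' subtracted (readings clipped at zero), interruption intervals contribute
#' nothing, each sensor's irradiance is trapezoid-integrated to a radiant
#' exposure (J cm^-2), and light delivery terminates at the first time the
#' average cumulative exposure of the *responding* sensors reaches the
#' target (clinical target 90 J cm^-2).  A sensor is responding if its
#' median baseline-subtracted irradiance exceeds `responding_threshold`
#' (default: 5\% of the across-sensor median).
#'
#' @param trace an [synth_trace()] object (or compatible list).
#' @param target_J_cm2 target radiant exposure (default 90 J cm^-2).
#' @param responding_threshold absolute threshold in mW cm^-2, or `NULL`
#'   for the 5\%-of-median default.
#' @return list: `termination_time_s` (NA if the target is never reached),
#'   `exposure_J_cm2` (per sensor, at termination or trace end),
#'   `responding` (logical per sensor), `target_J_cm2`.
#' @examples
#' tr <- synth_trace(4000, 1, 4, mean_irradiance = 30, sensor_spread = 0)
#' integrate_exposure(tr, 90)$termination_time_s   # 3000
#' @export
integrate_exposure <- function(trace, target_J_cm2 = 90,
                               responding_threshold = NULL) {
  if (target_J_cm2 <= 0) stop("'target_J_cm2' must be positive")
  t <- trace$time
  if (is.unsorted(t, strictly = TRUE)) stop("time must be strictly increasing")
  irr <- pmax(trace$irradiance - trace$baseline_offset, 0)
  for (iv in trace$interruption_intervals %||% list())
    irr[t >= iv[1] & t < iv[2], ] <- 0
  med <- apply(irr, 2, median)
  thr <- responding_threshold %||% (0.05 * median(med))
  responding <- med > max(thr, 0)
  if (!any(responding)) stop("no responding sensors")

  # per-sensor cumulative trapezoid exposure, mJ cm^-2 -> J cm^-2
  dt <- diff(t)
  mid <- (irr[-1, , drop = FALSE] + irr[-nrow(irr), , drop = FALSE]) / 2
  cum <- apply(mid * dt, 2, cumsum) / 1000
  cum <- rbind(0, cum)
  avg <- rowMeans(cum[, responding, drop = FALSE])

  term <- NA_real_
  k <- which(avg >= target_J_cm2)[1]
  if (!is.na(k)) {
    if (k == 1L) term <- t[1]
    else {
      rate <- (avg[k] - avg[k - 1]) / (t[k] - t[k - 1])
      term <- if (rate > 0)
        t[k - 1] + (target_J_cm2 - avg[k - 1]) / rate else t[k]
    }
  }
  idx <- if (is.na(term)) nrow(cum) else max(which(t <= term))
  list(termination_time_s = term,
       exposure_J_cm2 = cum[idx, ],
       responding = responding,
       target_J_cm2 = target_J_cm2)
}

#' Write / read an irradiance trace as CSV
#'
#' Plain-text exchange format: a `time_s` column plus one column per
#' sensor.  Baseline offset and interruptions are carried in a JSON
#' sidecar field inside the header comment when writing, and default to
#' none when reading a bare CSV.
#'
#' @param trace an `irradiance_trace`.
#' @param path file path.
#' @return `write_trace_csv`: the path, invisibly; `read_trace_csv`: an
#'   `irradiance_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(time_s = trace$time, trace$irradiance,
                   check.names = FALSE)
  meta <- jsonlite::toJSON(list(
    baseline_offset = trace$baseline_offset,
    interruption_intervals = trace$interruption_intervals),
    auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# bladderdose-trace ", meta), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  first <- readLines(path, n = 1)
  baseline <- 0
  intervals <- list()
  skip <- 0
  if (startsWith(first, "# bladderdose-trace ")) {
    meta <- jsonlite::fromJSON(sub("^# bladderdose-trace ", "", first),
                               simplifyMatrix = FALSE)
    baseline <- meta$baseline_offset %||% 0
    intervals <- lapply(meta$interruption_intervals %||% list(), unlist)
    skip <- 1
  }
  df <- read.csv(path, skip = skip, check.names = FALSE)
  structure(list(time = df$time_s,
                 irradiance = as.matrix(df[, -1, drop = FALSE]),
                 baseline_offset = baseline,
                 interruption_intervals = intervals),
            class = "irradiance_trace")
}
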