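#' Isotropic point-source specification
#'
#' The treatment source is an isotropic emitter (spherical-tip fiber) placed
#' inside the bladder void, nominally at the geometric centre; clinically
#' relevant displacements are about 1 cm (dorsal displacement is -y).
#'
#' @param position 3-vector, mm, relative to the void centre.
#' @param power_mW optical power in mW (clinical default 2500 mW at 525 nm).
#' @return object of class `source_spec`.
#' @export
source_spec <- function(position = c(0, 0, 0), power_mW = 2500) {
  if (length(position) != 3 || any(!is.finite(position)))
    stop("'position' must be a finite 3-vector (mm)")
  if (!is.finite(power_mW) || power_mW < 0)
    stop("'power_mW' must be non-negative")
  structure(list(position = as.numeric(position), power_mW = power_mW),
            class = "source_spec")
}

#' Transport-run configuration
#'
#' @param n_packets number of photon packets (desk-scale default 1e6;
#'   increase for production accuracy).
#' @param seed integer seed; every packet gets an independent substream
#'   derived from it, so results are reproducible under any batching.
#' @param roulette_threshold packet weight below which Russian roulette is
#'   played (default 1e-4).
#' @param roulette_survival roulette survival probability (default 0.1).
#' @param max_path_mm guard on total path length per packet; weight of a
#'   pathological packet is deposited locally.
#' @param h_max_mm boundary-search marching step (must stay below the
#'   thinnest layer; default 0.3 mm).
#' @param shell_width_mm width of the concentric depth shells used for
#'   volumetric absorption scoring (default 0.1 mm).
#' @param record_crossings if `TRUE`, log every void-to-wall surface
#'   crossing (patch, weight, incidence direction); required for
#'   direction-sensitive virtual sensor readings.
#' @param max_crossings cap on the crossing log length.
#' @return object of class `transport_config`.
#' @export
transport_config <- function(n_packets = 1e6, seed = 1L,
                             roulette_threshold = 1e-4,
                             roulette_survival = 0.1,
                             max_path_mm = 1e4, h_max_mm = 0.3,
                             shell_width_mm = 0.1,
                             record_crossings = FALSE,
                             max_crossings = 5e6) {
  if (n_packets < 1) stop("'n_packets' must be >= 1")
  if (roulette_survival <= 0 || roulette_survival > 1)
    stop("'roulette_survival' must be in (0, 1]")
  structure(list(n_packets = as.integer(n_packets), seed = as.integer(seed),
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival,
                 max_path_mm = max_path_mm, h_max_mm = h_max_mm,
                 shell_width_mm = shell_width_mm,
                 record_crossings = isTRUE(record_crossings),
                 max_crossings = as.integer(max_crossings)),
            class = "transport_config")
}

#' Sample a Henyey-Greenstein scattering deflection
#'
#' Inverse-CDF sampling of the deflection-angle cosine for the
#' Henyey-Greenstein phase function with anisotropy `g`; for `g = 0` the
#' deflection is isotropic (`cos theta = 2u - 1`).  The sample mean of
#' `cos theta` equals `g`.
#'
#' @param g anisotropy, |g| < 1.
#' @param u uniform variates in \[0, 1).
#' @return cosines of the deflection angle.
#' @export
sample_hg_deflection <- function(g, u) {
  if (abs(g) >= 1) stop("|g| must be < 1")
  if (any(u < 0 | u >= 1)) stop("'u' must lie in [0, 1)")
  as.numeric(hg_cos_cpp(g, u))
}

#' Unpolarized Fresnel reflectance
#'
#' Reflection probability at a planar refractive-index step for unpolarized
#' light, averaged over the s and p polarizations; returns 1 beyond the
#' total-internal-reflection angle.
#'
#' @param n1,n2 refractive indices of the incident and transmitting media.
#' @param cos_incident cosine(s) of the incidence angle (\eqn{|cos| \le 1}).
#' @return reflectance in \[0, 1\].
#' @examples
#' fresnel_reflectance(1.33, 1.37, 1)   # ~2.19e-4
#' @export
fresnel_reflectance <- function(n1, n2, cos_incident) {
  if (n1 < 1 || n2 < 1) stop("refractive indices must be >= 1")
  if (any(abs(cos_incident) > 1 + 1e-12))
    stop("|cos_incident| must be <= 1")
  as.numeric(fresnel_cpp(n1, n2, pmin(abs(cos_incident), 1)))
}

#' Run a Monte Carlo transport simulation
#'
#' Propagates photon packets from an isotropic point source through the
#' void / wall / adipose regions with Henyey-Greenstein scattering,
#' absorption weighting, Russian roulette, and Fresnel reflection /
#' refraction at refractive-index boundaries.  Scores (i) the irradiance
#' exiting the void through each surface patch (every void-to-wall crossing
#' counts, so the score includes both primary and diffusely back-scattered
#' light) and (ii) volumetric absorption on concentric depth shells below
#' the inner surface.
#'
#' Energy bookkeeping is exact: launched weight plus roulette boosts equals
#' absorbed plus escaped plus roulette-killed weight to floating-point
#' precision, and the net roulette residual (zero in expectation) is folded
#' into the absorbed fraction so that
#' `absorbed_fraction + escaped_fraction == 1`.
#'
#' @param geometry a [make_bladder_shape()] object.
#' @param property_map a [property_map()] (e.g. [preset_properties()]).
#' @param source a [source_spec()]; must lie inside the void.
#' @param patches a [tessellate_surface()] object.
#' @param config a [transport_config()].
#' @return object of class `dose_maps`: `surface_irradiance` (mW cm^-2 per
#'   patch), `volumetric_absorption` (data.frame: depth_mm, region,
#'   absorbed_mW_mm3), `absorbed_fraction`, `escaped_fraction`,
#'   `conservation_residual`, `n_packets_run`, `seed`, `power_mW`,
#'   `mean_irradiance` (area-weighted), and (if recorded) `crossings`.
#' @export
run_transport <- function(geometry, property_map, source, patches, config) {
  stopifnot(inherits(geometry, "bladder_geometry"),
            inherits(property_map, "property_map"),
            inherits(source, "source_spec"),
            inherits(patches, "surface_patches"),
            inherits(config, "transport_config"))
  if (region_at(geometry, source$position) != "void")
    stop("source position lies outside the bladder void")
  props <- rbind(
    unlist(property_map$void[c("mu_a", "mu_s", "g", "n")]),
    unlist(property_map$wall[c("mu_a", "mu_s", "g", "n")]),
    unlist(property_map$adipose[c("mu_a", "mu_s", "g", "n")]))
  if (any(!is.finite(props))) stop("non-finite optical properties")

  total_thick <- geometry$wall_thickness_mm + geometry$adipose_thickness_mm
  n_shells <- as.integer(ceiling(total_thick / config$shell_width_mm))

  res <- mc_transport_cpp(geometry$geom, props, source$position,
                          config$n_packets, as.double(config$seed),
                          patches$patch_dirs,
                          config$roulette_threshold,
                          config$roulette_survival,
                          config$max_path_mm, config$h_max_mm,
                          config$shell_width_mm, n_shells,
                          1.0, config$record_crossings,
                          config$max_crossings)

  N <- config$n_packets
  w_per_packet <- source$power_mW / N   # mW carried by unit weight
  # patch irradiance: weight crossing / patch area; mW mm^-2 -> mW cm^-2
  irr <- res$patch_weight * w_per_packet / patches$patch_areas * 100

  # shell volumes by quadrature over the direction lattice
  Kq <- 8192L
  dirs <- fibonacci_directions(Kq)
  Rin <- radius_cpp(geometry$geom, dirs)
  edges <- seq(0, n_shells) * config$shell_width_mm
  # V_k = (1/3) * integral over directions of ((R+d2)^3 - (R+d1)^3)
  shell_vol <- vapply(seq_len(n_shells), function(k) {
    sum((Rin + edges[k + 1])^3 - (Rin + edges[k])^3) / 3 * (4 * pi / Kq)
  }, numeric(1))
  depth_mid <- (edges[-1] + edges[-length(edges)]) / 2
  vol_abs <- data.frame(
    depth_mm = depth_mid,
    region = ifelse(depth_mid < geometry$wall_thickness_mm, "wall",
                    "adipose"),
    absorbed_mW_mm3 = res$shell_weight * w_per_packet / shell_vol)

  absorbed_frac <- (res$absorbed + res$killed - res$boosted) / N
  escaped_frac <- res$escaped / N
  residual <- (res$absorbed + res$escaped + res$killed - res$boosted) / N - 1

  out <- structure(list(
    surface_irradiance = irr,
    patch_weight = res$patch_weight,
    volumetric_absorption = vol_abs,
    absorbed_fraction = absorbed_frac,
    escaped_fraction = escaped_frac,
    conservation_residual = residual,
    n_packets_run = N,
    seed = config$seed,
    power_mW = source$power_mW,
    mean_irradiance = sum(irr * patches$patch_areas) / sum(patches$patch_areas),
    n_crossings = res$n_crossings
  ), class = "dose_maps")
  if (config$record_crossings) {
    if (isTRUE(res$crossings_overflow))
      warning("crossing log truncated at max_crossings; ",
              "direction-sensitive sensor readings will be biased low")
    cr <- res$crossings
    colnames(cr) <- c("patch", "weight", "cos_incidence", "dx", "dy", "dz")
    out$crossings <- as.data.frame(cr)
    out$crossings$patch <- as.integer(out$crossings$patch)
  }
  out
}

#' @export
print.dose_maps <- function(x, ...) {
  cat(sprintf(
    "<dose_maps> %g packets (seed %d), %d patches\n", x$n_packets_run,
    x$seed, length(x$surface_irradiance)))
  cat(sprintf(
    "  mean irradiance %.3g mW/cm^2; absorbed %.3f, escaped %.3f (residual %.1e)\n",
    x$mean_irradiance, x$absorbed_fraction, x$escaped_fraction,
    x$conservation_residual))
  invisible(x)
}

#' Idealized Lambertian-wall cavity run (integrating-sphere oracle)
#'
#' Treats a spherical cavity wall as an ideal diffuse (Lambertian) reflector
#' of reflectance `rho` with a clear void: every packet flies ballistically,
#' deposits `(1 - rho)` of its weight at each wall hit, and is re-emitted
#' cosine-weighted.  The total-to-primary irradiance ratio then follows the
#' integrating-sphere law `1 / (1 - rho)`, providing an analytic oracle for
#' the cavity "multiplication factor".
#'
#' @param geometry a spherical [make_bladder_shape()] object.
#' @param source a [source_spec()] inside the void.
#' @param rho wall reflectance, 0 <= rho < 1.
#' @param patches a [tessellate_surface()] object.
#' @param config a [transport_config()] (packet count, seed, roulette).
#' @return list of class `dose_maps` with `surface_irradiance` (total),
#'   `primary_irradiance`, and `multiplication_factor`
#'   (total / primary irradiance, ~ `1 / (1 - rho)`).
#' @export
run_lambertian_wall <- function(geometry, source, rho, patches, config) {
  stopifnot(inherits(geometry, "bladder_geometry"),
            inherits(source, "source_spec"),
            inherits(patches, "surface_patches"),
            inherits(config, "transport_config"))
  if (geometry$kind != "sphere")
    stop("the Lambertian-wall oracle is defined for spherical cavities")
  if (rho < 0 || rho >= 1) stop("'rho' must satisfy 0 <= rho < 1")
  res <- mc_lambertian_cpp(geometry$geom$r0, source$position,
                           config$n_packets, as.double(config$seed),
                           patches$patch_dirs, rho,
                           config$roulette_threshold,
                           config$roulette_survival)
  N <- config$n_packets
  w_per_packet <- source$power_mW / N
  total <- res$patch_weight * w_per_packet / patches$patch_areas * 100
  primary <- res$primary_weight * w_per_packet / patches$patch_areas * 100
  structure(list(
    surface_irradiance = total,
    primary_irradiance = primary,
    multiplication_factor = sum(res$patch_weight) /
      sum(res$primary_weight),
    absorbed_fraction = (res$absorbed + res$killed - res$boosted) / N,
    escaped_fraction = 0,
    conservation_residual =
      (res$absorbed + res$killed - res$boosted) / N - 1,
    n_packets_run = N,
    seed = config$seed,
    power_mW = source$power_mW,
    mean_irradiance = sum(total * patches$patch_areas) /
      sum(patches$patch_areas)
  ), class = "dose_maps")
}
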