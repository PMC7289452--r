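#' Photodynamic-threshold model
#'
#' Holds the tissue-specific photodynamic threshold doses (photons absorbed
#' per unit volume needed for necrosis) and the photosensitizer uptake in
#' tumor and normal tissue.  Defaults are the preclinical (AY-27 rat
#' bladder tumor model) estimates for the ruthenium-complex photosensitizer
#' TLD1433: thresholds 2.121e18 (tumor), 0.161e18 (urothelium), 0.128e18
#' (muscle) photons cm^-3, and uptakes 77 mg/kg (tumor) vs 0.4 mg/kg
#' (normal bladder).
#'
#' @param T_tumor,T_urothelium,T_muscle threshold doses, photons cm^-3.
#' @param uptake_tumor,uptake_normal photosensitizer uptake, mg kg^-1.
#' @return object of class `threshold_model`.
#' @examples
#' m <- threshold_model()
#' specific_uptake_ratio(m)          # 192.5
#' threshold_ratio(m, "urothelium")  # ~13.2
#' @export
threshold_model <- function(T_tumor = 2.121e18,
                            T_urothelium = 0.161e18,
                            T_muscle = 0.128e18,
                            uptake_tumor = 77,
                            uptake_normal = 0.4) {
  vals <- c(T_tumor, T_urothelium, T_muscle, uptake_tumor, uptake_normal)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all thresholds and uptakes must be positive")
  if (T_tumor <= T_urothelium || T_tumor <= T_muscle)
    stop("a selective photosensitizer requires T_tumor > T_normal")
  structure(list(T_tumor = T_tumor, T_urothelium = T_urothelium,
                 T_muscle = T_muscle, uptake_tumor = uptake_tumor,
                 uptake_normal = uptake_normal),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf(
    "<threshold_model> T: tumor %.3g, urothelium %.3g, muscle %.3g hv/cm^3\n",
    x$T_tumor, x$T_urothelium, x$T_muscle))
  cat(sprintf("  uptake: tumor %.3g, normal %.3g mg/kg (SUR %.1f)\n",
              x$uptake_tumor, x$uptake_normal, specific_uptake_ratio(x)))
  invisible(x)
}

#' Specific uptake ratio (SUR)
#'
#' Tumor-to-normal photosensitizer concentration ratio,
#' `SUR = uptake_tumor / uptake_normal` (192.5 for the default model).
#'
#' @param model a [threshold_model()].
#' @return dimensionless SUR.
#' @export
specific_uptake_ratio <- function(model) {
  stopifnot(inherits(model, "threshold_model"))
  model$uptake_tumor / model$uptake_normal
}

#' Tumor-to-normal threshold dose ratio
#'
#' `T_tumor / T_normal`: how many times more photons must be absorbed per
#' unit volume in the tumor than in the normal tissue for both to reach
#' their respective necrosis thresholds (~13.2 for urothelium, ~16.6 for
#' muscle with the default model; the worst case governs selectivity).
#'
#' @param model a [threshold_model()].
#' @param normal_tissue `"urothelium"` or `"muscle"`.
#' @return dimensionless ratio.
#' @export
threshold_ratio <- function(model,
                            normal_tissue = c("urothelium", "muscle")) {
  stopifnot(inherits(model, "threshold_model"))
  normal_tissue <- match.arg(normal_tissue)
  model$T_tumor /
    switch(normal_tissue, urothelium = model$T_urothelium,
           muscle = model$T_muscle)
}

#' Maximum fluence ratio compatible with PDT selectivity
#'
#' The selectivity condition requires
#' `(T_tumor / uptake_tumor) * (phi(0) / phi(d)) < T_normal / uptake_normal`,
#' i.e. the fluence may fall from the surface to the treatment depth by at
#' most `SUR * (T_normal / T_tumor)`.  With SUR = 192 and a
#' tumor-to-urothelium threshold ratio whose inverse is 0.0757, the
#' allowable fluence ratio is ~14.5.
#'
#' @param SUR specific uptake ratio (see [specific_uptake_ratio()]).
#' @param threshold_ratio_inverse `T_normal / T_tumor` (default 0.0757, the
#'   reported rounded value; `0.161 / 2.121 = 0.0759` from the printed
#'   thresholds is an equally valid input).
#' @return maximum permitted `phi(0) / phi(d)`.
#' @examples
#' allowable_fluence_ratio(192, 0.0757)   # ~14.5
#' @export
allowable_fluence_ratio <- function(SUR, threshold_ratio_inverse = 0.0757) {
  if (SUR <= 0 || threshold_ratio_inverse <= 0)
    stop("both arguments must be positive")
  SUR * threshold_ratio_inverse
}

#' Treatment depth at which PDT selectivity is lost
#'
#' Converts the allowable fluence ratio into a depth below the urothelial
#' surface, given the effective attenuation length of diffuse green light
#' in the bladder wall (`mu_eff_inv_mm`, default 0.75 mm).  Three modes:
#' \describe{
#'   \item{`attenuation_lengths`}{`depth = n_lengths * mu_eff_inv` with
#'     `n_lengths = 2.5` by default -- the conventional rule of thumb that
#'     an allowable ratio of ~14.5 affords about 2.5 attenuation lengths
#'     (~2 mm at 750 um), which already discounts some spherical
#'     divergence.}
#'   \item{`planar`}{pure exponential decay:
#'     `depth = ln(ratio) * mu_eff_inv`.}
#'   \item{`spherical`}{exponential decay plus spherical divergence from a
#'     cavity of radius `sphere_radius_mm`: solves
#'     `(R/(R+d))^2 exp(-d / mu_eff_inv) = 1 / ratio`; always shallower
#'     than the planar depth.}
#' }
#'
#' @param allowable_ratio maximum permitted `phi(0)/phi(d)` (> 1 except in
#'   `attenuation_lengths` mode, where it is unused).
#' @param mu_eff_inv_mm effective attenuation length, mm (default 0.75).
#' @param mode see above.
#' @param sphere_radius_mm cavity radius, required for `"spherical"`.
#' @param n_lengths multiplier for `"attenuation_lengths"` (default 2.5).
#' @return depth in mm.
#' @examples
#' selectivity_depth(mode = "attenuation_lengths")          # 1.875
#' selectivity_depth(14.5, mode = "planar")                 # ~2.01
#' selectivity_depth(14.5, mode = "spherical",
#'                   sphere_radius_mm = 22.6)
#' @export
selectivity_depth <- function(allowable_ratio = NULL,
                              mu_eff_inv_mm = 0.75,
                              mode = c("attenuation_lengths", "planar",
                                       "spherical"),
                              sphere_radius_mm = NULL,
                              n_lengths = 2.5) {
  mode <- match.arg(mode)
  if (mu_eff_inv_mm <= 0) stop("'mu_eff_inv_mm' must be positive")
  if (mode == "attenuation_lengths") return(n_lengths * mu_eff_inv_mm)
  if (is.null(allowable_ratio) || allowable_ratio < 1)
    stop("'allowable_ratio' must be >= 1")
  d_planar <- log(allowable_ratio) * mu_eff_inv_mm
  if (mode == "planar") return(d_planar)
  if (is.null(sphere_radius_mm))
    stop("spherical mode requires 'sphere_radius_mm'")
  if (allowable_ratio == 1) return(0)
  R <- sphere_radius_mm
  f <- function(d) (R / (R + d))^2 * exp(-d / mu_eff_inv_mm) -
    1 / allowable_ratio
  uniroot(f, c(0, d_planar), tol = 1e-10)$root
}

#' Analytic fluence-depth profiles
#'
#' `fluence_profile_planar()` gives the pure exponential decay
#' `phi(0)/phi(d) = exp(d / mu_eff_inv)`; `fluence_profile_spherical()`
#' adds spherical divergence from a cavity of radius `R`:
#' `phi(0)/phi(d) = ((R + d)/R)^2 exp(d / mu_eff_inv)`.
#'
#' @param depths_mm depths below the inner surface, mm (>= 0).
#' @param mu_eff_inv_mm effective attenuation length, mm.
#' @param sphere_radius_mm cavity radius, mm.
#' @return object of class `fluence_profile`: data.frame with `depth_mm`
#'   and `ratio` (`phi(0)/phi(d)`, >= 1, non-decreasing).
#' @export
fluence_profile_planar <- function(depths_mm, mu_eff_inv_mm = 0.75) {
  if (any(depths_mm < 0)) stop("depths must be non-negative")
  structure(data.frame(depth_mm = depths_mm,
                       ratio = exp(depths_mm / mu_eff_inv_mm)),
            class = c("fluence_profile", "data.frame"))
}

#' @rdname fluence_profile_planar
#' @export
fluence_profile_spherical <- function(depths_mm, mu_eff_inv_mm = 0.75,
                                      sphere_radius_mm = 22.6) {
  if (any(depths_mm < 0)) stop("depths must be non-negative")
  R <- sphere_radius_mm
  structure(data.frame(
    depth_mm = depths_mm,
    ratio = ((R + depths_mm) / R)^2 * exp(depths_mm / mu_eff_inv_mm)),
    class = c("fluence_profile", "data.frame"))
}

#' Fluence-depth profile from a transport run
#'
#' Extracts `phi(0)/phi(d)` from the volumetric absorption scored on depth
#' shells: within a region of absorption coefficient `mu_a`, the fluence
#' rate is proportional to `absorbed energy density / mu_a`, so the ratio
#' of the shallowest shell to each deeper shell estimates the fluence
#' fall-off that the selectivity criterion needs.  The profile is clipped
#' at ratio 1 (Monte Carlo noise can make the sub-surface build-up region
#' nominally brighter than the first shell).
#'
#' @param dose_maps a [run_transport()] result.
#' @param property_map the [property_map()] used for the run.
#' @param max_depth_mm truncate the profile here (default: full scored
#'   depth).
#' @return a `fluence_profile` data.frame (`depth_mm`, `ratio`).
#' @export
fluence_profile_from_transport <- function(dose_maps, property_map,
                                           max_depth_mm = NULL) {
  va <- dose_maps$volumetric_absorption
  if (!is.null(max_depth_mm)) va <- va[va$depth_mm <= max_depth_mm, ]
  mu_a <- ifelse(va$region == "wall", property_map$wall$mu_a,
                 property_map$adipose$mu_a)
  phi <- va$absorbed_mW_mm3 / mu_a
  if (phi[1] <= 0) stop("no absorption scored in the first depth shell")
  structure(data.frame(depth_mm = va$depth_mm,
                       ratio = pmax(phi[1] / phi, 1)),
            class = c("fluence_profile", "data.frame"))
}

#' Check PDT selectivity along a fluence-depth profile
#'
#' Applies the threshold-dose selectivity criterion at every depth of a
#' fluence profile: treatment at depth `d` is selective iff
#' `phi(0)/phi(d) < SUR * T_normal / T_tumor`.  The margin is the
#' allowable ratio divided by the actual ratio (> 1 means selective with
#' room to spare).
#'
#' @param model a [threshold_model()].
#' @param profile a `fluence_profile`.
#' @param depth_max_mm the profile must cover \[0, depth_max_mm\].
#' @param normal_tissue `"urothelium"` (default; the worst case) or
#'   `"muscle"`.
#' @return data.frame: `depth_mm`, `ratio`, `selective`, `margin`; the
#'   allowable ratio is attached as attribute `allowable_ratio`.
#' @export
check_selectivity_profile <- function(model, profile, depth_max_mm,
                                      normal_tissue = "urothelium") {
  stopifnot(inherits(model, "threshold_model"),
            inherits(profile, "fluence_profile"))
  if (max(profile$depth_mm) < depth_max_mm)
    stop("profile does not cover the requested depth range")
  allowable <- specific_uptake_ratio(model) /
    threshold_ratio(model, normal_tissue)
  p <- profile[profile$depth_mm <= depth_max_mm, ]
  out <- data.frame(depth_mm = p$depth_mm, ratio = p$ratio,
                    selective = p$ratio < allowable,
                    margin = allowable / p$ratio)
  attr(out, "allowable_ratio") <- allowable
  out
}
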