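# Shared fixtures, built in code. The memo environment avoids recomputing
# the more expensive transport runs across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

sphere_48 <- function() memo("sphere_48", make_bladder_shape("sphere", 48.5))

patches_48 <- function(n = 200)
  memo(paste0("patches_48_", n), tessellate_surface(sphere_48(), n))

# clear void + an effectively perfectly absorbing, index-matched wall:
# the surface irradiance is then primary light only (inverse-square oracle)
absorbing_map <- function() property_map(
  void = optical_properties(0.000041, 0.000017, 0.8, 1.33),
  wall = optical_properties(1e4, 0, 0, 1.33),
  adipose = optical_properties(0.149, 6.9, 0.9, 1.37))

preset_map <- function() preset_properties("bladder_525nm")

# one 2e5-packet run with the 525-nm preset, reused by several files
preset_run <- function() memo("preset_run", run_transport(
  sphere_48(), preset_map(), source_spec(), patches_48(),
  transport_config(n_packets = 2e5, seed = 3)))

# minimal stand-in patch set for DSH-only arithmetic
flat_patches <- function(areas) list(patch_areas = areas)
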