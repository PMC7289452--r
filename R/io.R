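#' Export a bladder geometry for visualization
#'
#' Writes the tessellated inner surface as legacy ASCII VTK polydata or as
#' ASCII PLY, viewable in Paraview and standard mesh viewers.  Two modes:
#' \describe{
#'   \item{`patches`}{one point (with a vertex cell) per surface patch;
#'     per-patch scalars (e.g. irradiance) attach as point data.  Cell
#'     count equals the patch count.}
#'   \item{`grid`}{a triangulated latitude/longitude graph of the inner
#'     surface for a smooth rendering; scalars are mapped to vertices by
#'     nearest patch.}
#' }
#'
#' @param geometry a [make_bladder_shape()] object.
#' @param patches a [tessellate_surface()] object.
#' @param path output file.
#' @param format `"vtk"` (legacy polydata) or `"ply"`.
#' @param scalars optional per-patch values (e.g.
#'   `dose_maps$surface_irradiance`); name taken from `scalar_name`.
#' @param scalar_name name of the scalar field (default "irradiance").
#' @param mode `"patches"` or `"grid"`.
#' @param grid_res latitude resolution of grid mode (default 48).
#' @return the path, invisibly.
#' @export
export_geometry <- function(geometry, patches, path,
                            format = c("vtk", "ply"),
                            scalars = NULL, scalar_name = "irradiance",
                            mode = c("patches", "grid"), grid_res = 48) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  stopifnot(inherits(geometry, "bladder_geometry"),
            inherits(patches, "surface_patches"))
  if (!is.null(scalars) && length(scalars) != patches$n_patches)
    stop("'scalars' must have one value per patch")

  if (mode == "patches") {
    pts <- patches$patch_centers
    vert_scalars <- scalars
    faces <- NULL
  } else {
    nth <- grid_res
    nph <- 2 * grid_res
    th <- seq(0, pi, length.out = nth)
    ph <- seq(0, 2 * pi, length.out = nph + 1)[-(nph + 1)]
    u <- cbind(c(outer(sin(th), cos(ph))), c(outer(sin(th), sin(ph))),
               c(outer(cos(th), rep(1, nph))))
    u <- u / sqrt(rowSums(u^2))
    r <- as.numeric(radius_cpp(geometry$geom, u))
    pts <- u * r
    idx <- function(i, j) (j - 1) * nth + i   # column-major over (th, ph)
    faces <- list()
    for (j in seq_len(nph)) {
      j2 <- if (j == nph) 1L else j + 1L
      for (i in seq_len(nth - 1)) {
        faces[[length(faces) + 1]] <- c(idx(i, j), idx(i + 1, j),
                                        idx(i + 1, j2))
        faces[[length(faces) + 1]] <- c(idx(i, j), idx(i + 1, j2),
                                        idx(i, j2))
      }
    }
    faces <- do.call(rbind, faces)
    vert_scalars <- if (!is.null(scalars)) {
      near <- max.col(u %*% t(patches$patch_dirs))
      scalars[near]
    }
  }

  if (format == "vtk")
    write_vtk_polydata(pts, faces, vert_scalars, scalar_name, path)
  else
    write_ply(pts, faces, vert_scalars, path)
  invisible(path)
}

# legacy ASCII VTK polydata writer; faces = NULL emits VERTICES cells
write_vtk_polydata <- function(points, faces, scalars, scalar_name, path) {
  con <- file(path, "w")
  on.exit(close(con))
  np <- nrow(points)
  writeLines(c("# vtk DataFile Version 3.0",
               "bladderdose surface export", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", np)), con)
  writeLines(apply(points, 1, function(p)
    sprintf("%.6f %.6f %.6f", p[1], p[2], p[3])), con)
  if (is.null(faces)) {
    writeLines(sprintf("VERTICES %d %d", np, 2 * np), con)
    writeLines(sprintf("1 %d", seq_len(np) - 1), con)
  } else {
    writeLines(sprintf("POLYGONS %d %d", nrow(faces), 4 * nrow(faces)), con)
    writeLines(apply(faces - 1, 1, function(f)
      sprintf("3 %d %d %d", f[1], f[2], f[3])), con)
  }
  if (!is.null(scalars)) {
    writeLines(c(sprintf("POINT_DATA %d", np),
                 sprintf("SCALARS %s float 1", scalar_name),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.6g", scalars), con)
  }
  invisible(path)
}

# minimal ASCII PLY writer
write_ply <- function(points, faces, scalars, path) {
  con <- file(path, "w")
  on.exit(close(con))
  np <- nrow(points)
  hdr <- c("ply", "format ascii 1.0",
           "comment bladderdose surface export",
           sprintf("element vertex %d", np),
           "property float x", "property float y", "property float z")
  if (!is.null(scalars)) hdr <- c(hdr, "property float quality")
  nf <- if (is.null(faces)) 0 else nrow(faces)
  hdr <- c(hdr, sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  if (is.null(scalars))
    writeLines(apply(points, 1, function(p)
      sprintf("%.6f %.6f %.6f", p[1], p[2], p[3])), con)
  else
    writeLines(sprintf("%.6f %.6f %.6f %.6g",
                       points[, 1], points[, 2], points[, 3], scalars), con)
  if (nf > 0)
    writeLines(apply(faces - 1, 1, function(f)
      sprintf("3 %d %d %d", f[1], f[2], f[3])), con)
  invisible(path)
}

#' Count the vertices declared in an exported surface file
#'
#' Lightweight round-trip check for [export_geometry()] output: parses the
#' vertex count from a legacy VTK `POINTS` line or a PLY `element vertex`
#' header line.
#'
#' @param path file written by [export_geometry()].
#' @return integer vertex count.
#' @export
count_exported_vertices <- function(path) {
  lines <- readLines(path, n = 50)
  vtk <- grep("^POINTS ", lines, value = TRUE)
  if (length(vtk))
    return(as.integer(strsplit(vtk[1], " ")[[1]][2]))
  ply <- grep("^element vertex ", lines, value = TRUE)
  if (length(ply))
    return(as.integer(strsplit(ply[1], " ")[[1]][3]))
  stop("unrecognized surface file format")
}

#' Write a transport-run summary as JSON
#'
#' Machine-readable provenance record of a run: seed, packet count, power,
#' energy-conservation ledger, and mean irradiance.
#'
#' @param dose_maps a [run_transport()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_run_summary <- function(dose_maps, path) {
  jsonlite::write_json(list(
    seed = dose_maps$seed,
    n_packets = dose_maps$n_packets_run,
    power_mW = dose_maps$power_mW,
    absorbed_fraction = dose_maps$absorbed_fraction,
    escaped_fraction = dose_maps$escaped_fraction,
    conservation_residual = dose_maps$conservation_residual,
    mean_irradiance_mW_cm2 = dose_maps$mean_irradiance
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-patch dose maps as CSV
#'
#' Columns: patch id, area (mm^2), irradiance (mW cm^-2).
#'
#' @param dose_maps a [run_transport()] result.
#' @param patches the run's [tessellate_surface()] object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_dose_csv <- function(dose_maps, patches, path) {
  write.csv(data.frame(patch = seq_len(patches$n_patches),
                       area_mm2 = patches$patch_areas,
                       irradiance_mW_cm2 = dose_maps$surface_irradiance),
            path, row.names = FALSE)
  invisible(path)
}
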