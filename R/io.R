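#' Write a scene to its on-disk layout
#'
#' Writes `intensity.tif` (single-channel 16-bit TIFF), `probstack.tif`
#' (multi-page TIFF, one page per class in the order PARTICLE, PORE, MB, RB,
#' PB), `root_geometry.json` (centreline and boundary vertex lists in um,
#' tip-first), `ground_truth_patches.csv` and `scene_config.json`, under
#' `dir/root_<k>/t<hours>/tile_<j>/`.
#'
#' @param scene A `rhizo_scene`.
#' @param dir Dataset root directory.
#' @return The scene directory, invisibly.
#' @export
write_scene <- function(scene, dir) {
  sdir <- file.path(dir, sprintf("root_%d", scene$root_id),
                    sprintf("t%g", scene$timepoint_h),
                    sprintf("tile_%d", scene$tile_id))
  dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(pmin(scene$intensity, 65535) / 65535,
                  file.path(sdir, "intensity.tif"), bits.per.sample = 16)
  pages <- lapply(1:5, function(k) scene$probstack[, , k])
  tiff::writeTIFF(pages, file.path(sdir, "probstack.tif"),
                  bits.per.sample = 16)
  g <- scene$geometry
  jsonlite::write_json(
    list(centreline = as.list(g$centreline),
         boundary = as.list(g$boundary),
         s_offset_um = g$s_offset_um),
    file.path(sdir, "root_geometry.json"), digits = NA, auto_unbox = TRUE)
  truth <- dplyr::select(scene$truth, -dplyr::any_of("pixels"))
  truth$scene_id <- basename(sdir)
  write.csv(truth, file.path(sdir, "ground_truth_patches.csv"),
            row.names = FALSE)
  cfg <- scene$config
  cfg$placement <- unclass(cfg$placement)
  jsonlite::write_json(
    c(unclass(cfg), list(root_id = scene$root_id, tile_id = scene$tile_id,
                         timepoint_h = scene$timepoint_h, seed = scene$seed)),
    file.path(sdir, "scene_config.json"), digits = NA, auto_unbox = TRUE)
  invisible(sdir)
}

#' Read a scene directory
#'
#' Reads the files written by [write_scene()] (or equivalently structured
#' external exports) back into a `rhizo_scene`. Masks are reconstructed from
#' the probability stack and the traced geometry; ground truth is attached
#' when present.
#'
#' @param sdir Scene directory containing `intensity.tif`, `probstack.tif`,
#'   `root_geometry.json` and `scene_config.json`.
#' @return A `rhizo_scene`.
#' @export
read_scene <- function(sdir) {
  for (f in c("intensity.tif", "probstack.tif", "root_geometry.json",
              "scene_config.json")) {
    if (!file.exists(file.path(sdir, f)))
      abort(sprintf("missing upstream artifact: %s", file.path(sdir, f)))
  }
  intensity <- tiff::readTIFF(file.path(sdir, "intensity.tif")) * 65535
  pages <- tiff::readTIFF(file.path(sdir, "probstack.tif"), all = TRUE)
  probstack <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) probstack[, , k] <- pages[[k]]
  # re-normalize 16-bit quantization so per-pixel sums are exactly 1
  s <- apply(probstack, c(1, 2), sum)
  probstack <- sweep(probstack, c(1, 2), s, "/")
  gj <- jsonlite::read_json(file.path(sdir, "root_geometry.json"),
                            simplifyVector = TRUE)
  geometry <- root_geometry(gj$centreline[c("x_um", "y_um")], gj$boundary,
                            s_offset_um = gj$s_offset_um %||% 0)
  cj <- jsonlite::read_json(file.path(sdir, "scene_config.json"),
                            simplifyVector = TRUE)
  config <- scene_config(
    tile_width_mm = cj$tile_width_mm, tile_height_mm = cj$tile_height_mm,
    pixel_size_um = cj$pixel_size_um,
    particle_diameter_range_um = cj$particle_diameter_range_um,
    particle_packing_fraction = cj$particle_packing_fraction,
    root_width_um = cj$root_width_um, root_curvature = cj$root_curvature,
    n_roots = cj$n_roots, timepoints_h = cj$timepoints_h,
    tiles_per_root = cj$tiles_per_root,
    calibration_slope = cj$calibration_slope,
    calibration_intercept = cj$calibration_intercept,
    background_level = cj$background_level, noise_sd = cj$noise_sd,
    label_flip_rate = cj$label_flip_rate)
  lab <- argmax_classify(probstack)
  root_mask <- rasterize_root(geometry, dim(lab), config$pixel_size_um)
  particle_mask <- (lab == class_code("PARTICLE")) & !root_mask
  truth_file <- file.path(sdir, "ground_truth_patches.csv")
  truth <- if (file.exists(truth_file)) as_tibble(read.csv(truth_file))
           else NULL
  structure(list(intensity = intensity, probstack = probstack,
                 masks = list(particle = particle_mask + 0L,
                              root = root_mask,
                              pore = !particle_mask & !root_mask),
                 geometry = geometry, truth = truth, config = config,
                 root_id = cj$root_id %||% NA_integer_,
                 tile_id = cj$tile_id %||% NA_integer_,
                 timepoint_h = cj$timepoint_h %||% NA_real_,
                 seed = cj$seed %||% NA_integer_),
            class = "rhizo_scene")
}

#' Write / read the patch interchange table
#'
#' `patches.csv` is the interchange contract between segmentation and the
#' density / metrics stages: one row per patch with the exact patch field
#' set.
#'
#' @param patches Patch tibble.
#' @param path File path.
#' @return `path` (write) or the patch tibble (read).
#' @export
write_patches <- function(patches, path) {
  write.csv(dplyr::select(patches, -dplyr::any_of("pixels")), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_patches
#' @export
read_patches <- function(path) {
  if (!file.exists(path)) abort(sprintf("missing upstream artifact: %s", path))
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a density field with its JSON sidecar
#'
#' Long-format CSV (one row per grid cell) plus a sidecar recording the
#' estimator metadata (M, N, R, Q_bar, grid, flag, integral).
#'
#' @param field A `density_field`.
#' @param path CSV path; the sidecar replaces the extension with `.json`.
#' @return `path`, invisibly.
#' @export
write_density_field <- function(field, path) {
  write.csv(as.data.frame(field), path, row.names = FALSE)
  meta <- list(covariates = attr(field, "covariates"),
               grid = attr(field, "grid"), M = attr(field, "M"),
               N = attr(field, "N"), flag = attr(field, "flag"),
               h_min_um = attr(field, "h_min_um"),
               integral = attr(field, "integral"),
               Q_bar = attr(field, "Q_bar"), R = attr(field, "R"))
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       sub("\\.csv$", ".json", path),
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}
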