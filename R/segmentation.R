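#' Maximum-probability classification of a probability stack
#'
#' Assigns each pixel the class with the highest probability. Ties are broken
#' by the fixed class order PARTICLE < PORE < MB < RB < PB.
#'
#' @param probstack Array `nx` x `ny` x 5 of per-pixel class probabilities,
#'   class order PARTICLE, PORE, MB, RB, PB; each pixel's probabilities must
#'   sum to 1 within 1e-6.
#' @return Integer matrix of class codes 1..5 (names in
#'   `c("PARTICLE","PORE","MB","RB","PB")`).
#' @export
argmax_classify <- function(probstack) {
  stopifnot(length(dim(probstack)) == 3, dim(probstack)[3] == 5)
  if (any(is.na(probstack))) abort("probability stack contains NaN/NA values")
  if (any(probstack < -1e-9 | probstack > 1 + 1e-9))
    abort("probabilities must lie in [0, 1]")
  sums <- rowSums(matrix(probstack, ncol = 5), na.rm = FALSE)
  if (any(abs(sums - 1) > 1e-6))
    abort("per-pixel class probabilities must sum to 1")
  m <- matrix(probstack, ncol = 5)
  lab <- max.col(m, ties.method = "first")
  matrix(as.integer(lab), dim(probstack)[1], dim(probstack)[2])
}

# Euclidean distance (um) to the nearest particle / root pixel, for every
# pixel of the grid; 0 on and inside the structure. Inf when the structure
# is absent from the tile.
distance_maps <- function(particle_mask, root_mask, pixel_size_um) {
  dp <- if (any(particle_mask > 0))
    EBImage::distmap(1 - (particle_mask > 0)) * pixel_size_um
  else matrix(Inf, nrow(particle_mask), ncol(particle_mask))
  dr <- if (any(root_mask > 0))
    EBImage::distmap(1 - (root_mask > 0)) * pixel_size_um
  else matrix(Inf, nrow(root_mask), ncol(root_mask))
  list(dp = as.matrix(dp), dr = as.matrix(dr))
}

#' Watershed decomposition of a class mask into patch regions
#'
#' Splits a binary bacterial-class mask into compact regions by flooding the
#' negated Euclidean distance transform from its regional maxima, the
#' standard shape-based splitting of merged blobs. Regions partition the
#' mask exactly; a component with a single maximum passes through unchanged.
#'
#' @param mask Logical/0-1 matrix.
#' @param intensity Optional intensity matrix of the same dimensions (only
#'   checked for shape; flooding is shape-based).
#' @param tolerance Minimum distance-transform depth (pixels) separating two
#'   regions.
#' @param min_seed_sep Neighbourhood radius (pixels) for regional-maximum
#'   detection; maxima closer than this merge into one seed.
#' @return Integer matrix labelling regions 1..k (0 = background).
#' @export
watershed_decompose <- function(mask, intensity = NULL, tolerance = 1,
                                min_seed_sep = 3) {
  if (!is.null(intensity) && !all(dim(intensity) == dim(mask)))
    abort("mask and intensity grids have different shapes")
  m <- mask > 0
  if (!any(m)) return(matrix(0L, nrow(mask), ncol(mask)))
  dm <- EBImage::distmap(m)
  ws <- EBImage::watershed(dm, tolerance = tolerance, ext = min_seed_sep)
  lab <- matrix(as.integer(ws), nrow(mask), ncol(mask))
  stopifnot(all((lab > 0) == m))
  lab
}

#' Distance-transform covariates at points
#'
#' For each point (um coordinates) returns the covariate vector
#' `x = (dp, dr, da)`: Euclidean distance to the nearest particle pixel,
#' to the nearest root pixel (both 0 on/inside the structure), and the
#' distance from the root tip, read as the cumulative arc length of the
#' nearest vertex of the centreline resampled to one-pixel spacing.
#'
#' @param points Data frame with `x_um`, `y_um`.
#' @param particle_mask,root_mask Binary matrices.
#' @param geometry A [root_geometry()].
#' @param pixel_size_um Pixel size in um.
#' @param covariates Which covariates to compute (default all three).
#' @return Tibble with the requested columns among `dp_um`, `dr_um`, `da_um`.
#' @export
compute_covariates <- function(points, particle_mask, root_mask, geometry,
                               pixel_size_um,
                               covariates = c("dp", "dr", "da")) {
  points <- as.data.frame(points)
  dims <- dim(particle_mask)
  ix <- point_to_index(points$x_um, dims[1], pixel_size_um)
  iy <- point_to_index(points$y_um, dims[2], pixel_size_um)
  at <- cbind(ix, iy)
  out <- tibble(.rows = nrow(points))
  if (any(c("dp", "dr") %in% covariates)) {
    dm <- distance_maps(particle_mask, root_mask, pixel_size_um)
    if ("dp" %in% covariates) out$dp_um <- dm$dp[at]
    if ("dr" %in% covariates) out$dr_um <- dm$dr[at]
  }
  if ("da" %in% covariates)
    out$da_um <- da_nearest(points, geometry, spacing_um = pixel_size_um)
  out
}

#' Extract bacterial patches from a labelled scene
#'
#' For each bacterial class (MB, RB, PB), decomposes the class mask into
#' watershed regions and summarises every region into a patch: area
#' `A = npx * pixel_size^2`, mean intensity `I` (optionally
#' background-subtracted), intensity-unweighted centroid of pixel centers,
#' and covariates `(dp, dr, da)` evaluated at the centroid. Regions smaller
#' than `min_area_px` pixels are discarded as sub-resolution noise.
#'
#' @param labelmap Integer class-code matrix including the `ROOT` overlay
#'   (see [argmax_classify()] and [overlay_root()]).
#' @param intensity Intensity matrix.
#' @param geometry A [root_geometry()].
#' @param pixel_size_um Pixel size in um.
#' @param timepoint_h,root_id,tile_id Identifiers attached to each patch.
#' @param min_area_px Minimum region size in pixels (default 4).
#' @param background_subtract Constant background subtracted from mean
#'   intensities (default 0: raw intensities).
#' @param tolerance,min_seed_sep Passed to [watershed_decompose()].
#' @return Tibble with one row per patch: `patch_id`, `class`, `area_um2`,
#'   `mean_intensity`, `total_intensity`, `npx`, `cx_um`, `cy_um`, `dp_um`,
#'   `dr_um`, `da_um`, `timepoint_h`, `root_id`, `tile_id`.
#' @export
extract_patches <- function(labelmap, intensity, geometry, pixel_size_um,
                            timepoint_h = NA_real_, root_id = NA_integer_,
                            tile_id = NA_integer_, min_area_px = 4,
                            background_subtract = 0,
                            tolerance = 1, min_seed_sep = 3) {
  if (!all(dim(labelmap) == dim(intensity)))
    abort("label map and intensity grids have different shapes")
  dims <- dim(labelmap)
  particle_mask <- labelmap == class_code("PARTICLE")
  root_mask <- labelmap == ROOT_CODE
  out <- list()
  for (cls in BACTERIA_CLASSES) {
    mask <- labelmap == class_code(cls)
    if (!any(mask)) next
    regions <- watershed_decompose(mask, intensity, tolerance, min_seed_sep)
    idx <- which(regions > 0)
    lab <- regions[idx]
    npx <- tabulate(lab)
    vals <- intensity[idx]
    mean_i <- as.numeric(tapply(vals, lab, mean)) - background_subtract
    mean_i[mean_i < 0] <- 0
    rc <- arrayInd(idx, dims)
    cx <- as.numeric(tapply((rc[, 1] - 0.5) * pixel_size_um, lab, mean))
    cy <- as.numeric(tapply((rc[, 2] - 0.5) * pixel_size_um, lab, mean))
    keep <- npx >= min_area_px
    if (!any(keep)) next
    out[[cls]] <- tibble(class = cls, npx = npx[keep],
                         area_um2 = npx[keep] * pixel_size_um^2,
                         mean_intensity = mean_i[keep],
                         cx_um = cx[keep], cy_um = cy[keep])
  }
  patches <- bind_rows(out)
  if (nrow(patches) == 0) {
    return(tibble(patch_id = integer(0), class = character(0),
                  area_um2 = numeric(0), mean_intensity = numeric(0),
                  total_intensity = numeric(0), npx = integer(0),
                  cx_um = numeric(0), cy_um = numeric(0), dp_um = numeric(0),
                  dr_um = numeric(0), da_um = numeric(0),
                  timepoint_h = numeric(0), root_id = integer(0),
                  tile_id = integer(0)))
  }
  cov <- compute_covariates(tibble(x_um = patches$cx_um, y_um = patches$cy_um),
                            particle_mask, root_mask, geometry, pixel_size_um)
  patches |>
    mutate(total_intensity = .data$mean_intensity * .data$npx,
           dp_um = cov$dp_um, dr_um = cov$dr_um, da_um = cov$da_um,
           timepoint_h = timepoint_h, root_id = root_id, tile_id = tile_id,
           patch_id = dplyr::row_number()) |>
    select("patch_id", "class", "area_um2", "mean_intensity",
           "total_intensity", "npx", "cx_um", "cy_um", "dp_um", "dr_um",
           "da_um", "timepoint_h", "root_id", "tile_id")
}

#' Segment a scene into its patch table
#'
#' Convenience wrapper chaining [argmax_classify()], [overlay_root()] and
#' [extract_patches()] for one scene (synthetic or ingested).
#'
#' @param scene A `rhizo_scene` from [simulate_scene()] or [read_scene()].
#' @param ... Passed to [extract_patches()].
#' @inheritParams extract_patches
#' @return Patch tibble (the `patches.csv` interchange contract).
#' @export
segment_scene <- function(scene, background_subtract = 0, ...) {
  lab <- argmax_classify(scene$probstack)
  lab <- overlay_root(lab, scene$geometry, scene$config$pixel_size_um)
  extract_patches(lab, scene$intensity, scene$geometry,
                  scene$config$pixel_size_um,
                  timepoint_h = scene$timepoint_h, root_id = scene$root_id,
                  tile_id = scene$tile_id,
                  background_subtract = background_subtract, ...)
}
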