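#' Render a planted scene to an intensity image and probability stack
#'
#' Paints every planted patch over its realized pixel set so that the
#' summed patch intensity equals `slope * cells + intercept` exactly (before
#' noise), adds constant background and additive Gaussian noise, and builds
#' a per-pixel class-probability stack that is one-hot in the ground-truth
#' labels with optional label-flip noise. Root pixels appear as pore space
#' in the stack: the root region is supplied by the traced geometry, not by
#' the classifier, mirroring how the real data are produced.
#'
#' @param patches Planted patch tibble from [place_patches()] (needs the
#'   `pixels` list-column).
#' @param masks List with `particle` and `root` masks.
#' @param config A [scene_config()] (calibration and noise parameters).
#' @param seed Integer seed for the noise sub-streams.
#' @return List with `intensity` (matrix) and `probstack`
#'   (array `nx` x `ny` x 5, class order PARTICLE, PORE, MB, RB, PB; rows sum
#'   to 1 per pixel).
#' @export
render_scene <- function(patches, masks, config, seed) {
  dims <- dim(masks$particle)
  if (nrow(patches) > 0 &&
      (!"pixels" %in% names(patches) || any(vapply(patches$pixels, is.null, logical(1)))))
    abort("patches lack realized pixel sets; re-run place_patches(paint = TRUE)")

  # ground-truth label map (no ROOT: the stack has the five classifier classes)
  labels <- matrix(2L, dims[1], dims[2])       # PORE
  labels[masks$particle > 0] <- 1L             # PARTICLE
  owner <- matrix(0L, dims[1], dims[2])        # patch id per pixel
  intensity <- matrix(config$background_level, dims[1], dims[2])
  for (i in seq_len(nrow(patches))) {
    idx <- patches$pixels[[i]]
    clash <- owner[idx] != 0L
    if (any(clash)) {
      other <- patches$class[owner[idx][clash][1]]
      if (any(patches$class[owner[idx][clash]] != patches$class[i]))
        abort(sprintf(
          "planted %s patch overlaps a %s patch; ground truth would be ambiguous",
          patches$class[i], other))
    }
    owner[idx] <- i
    labels[idx] <- class_code(patches$class[i])
    total <- config$calibration_slope * patches$cells[i] +
      config$calibration_intercept
    intensity[idx] <- intensity[idx] + total / length(idx)
  }

  if (config$noise_sd > 0) {
    with_seed(substream_seed(seed, "noise"), {
      intensity <- intensity + rnorm(length(intensity), 0, config$noise_sd)
    })
    intensity[intensity < 0] <- 0
  }

  if (config$label_flip_rate > 0) {
    with_seed(substream_seed(seed, "labelflip"), {
      nflip <- round(config$label_flip_rate * length(labels))
      if (nflip > 0) {
        at <- sample.int(length(labels), nflip)
        shift <- sample.int(4L, nflip, replace = TRUE)
        labels[at] <- ((labels[at] - 1L + shift) %% 5L) + 1L
      }
    })
  }

  probstack <- array(0, c(dims[1], dims[2], 5L))
  for (k in 1:5) probstack[, , k][labels == k] <- 1
  list(intensity = intensity, probstack = probstack)
}

#' Simulate one synthetic microcosm tile
#'
#' Assembles particles, root, planted patches and rendered images for one
#' (root, timepoint, tile) combination. Particle and root sub-streams are
#' keyed only by root/tile, so the same microcosm is imaged across
#' timepoints; patch and noise sub-streams are keyed by timepoint as well.
#'
#' @param config A [scene_config()].
#' @param seed Integer cohort seed.
#' @param root_id,tile_id Integers identifying the scene.
#' @param timepoint_h Timepoint in hours.
#' @return A `rhizo_scene` list: `intensity`, `probstack`, `masks`
#'   (`particle`, `root`, `pore`), `geometry`, `truth` (planted patches with
#'   ids), `config`, `root_id`, `tile_id`, `timepoint_h`, `seed`.
#' @export
simulate_scene <- function(config, seed, root_id = 1L, timepoint_h = 12,
                           tile_id = 1L) {
  scene_seed <- substream_seed(seed, "scene", root_id, tile_id)
  parts <- generate_particles(config, scene_seed)
  root <- generate_root(config, scene_seed, tile_index = tile_id)
  # the root overrides particles wherever the traced polygon covers them
  parts$mask[root$mask] <- 0L
  masks <- list(particle = parts$mask, root = root$mask,
                pore = !(parts$mask > 0) & !root$mask)
  patch_seed <- substream_seed(seed, "scene", root_id, tile_id, timepoint_h)
  truth <- place_patches(config, masks, root$geometry, timepoint_h, patch_seed)
  rendered <- render_scene(truth, masks, config, patch_seed)
  if (nrow(truth) > 0) {
    truth$root_id <- root_id
    truth$tile_id <- tile_id
    truth$patch_id <- seq_len(nrow(truth))
  } else {
    truth$root_id <- integer(0); truth$tile_id <- integer(0)
    truth$patch_id <- integer(0)
  }
  structure(list(intensity = rendered$intensity,
                 probstack = rendered$probstack,
                 masks = masks, geometry = root$geometry, truth = truth,
                 config = config, root_id = root_id, tile_id = tile_id,
                 timepoint_h = timepoint_h, seed = seed),
            class = "rhizo_scene")
}

#' @export
print.rhizo_scene <- function(x, ...) {
  cat(sprintf(
    "<rhizo_scene> root %d tile %d t=%g h: %d x %d px, %d planted patches\n",
    x$root_id, x$tile_id, x$timepoint_h, nrow(x$intensity), ncol(x$intensity),
    nrow(x$truth)))
  invisible(x)
}

#' Cohort layout for a simulated study
#'
#' One row per scene: every root is imaged at every timepoint over a number
#' of tiles drawn uniformly from `config$tiles_per_root` (the same tiles at
#' every timepoint, as in a tracked imaging study).
#'
#' @param config A [scene_config()].
#' @param seed Integer cohort seed.
#' @return Tibble with `root_id`, `timepoint_h`, `tile_id`.
#' @export
cohort_manifest <- function(config, seed) {
  n_tiles <- with_seed(substream_seed(seed, "cohort"), {
    lo <- config$tiles_per_root[1]; hi <- config$tiles_per_root[2]
    lo + sample.int(hi - lo + 1L, config$n_roots, replace = TRUE) - 1L
  })
  tidyr::expand_grid(root_id = seq_len(config$n_roots),
                     timepoint_h = config$timepoints_h) |>
    mutate(n = n_tiles[.data$root_id]) |>
    tidyr::uncount(.data$n, .id = "tile_id") |>
    mutate(tile_id = as.integer(.data$tile_id)) |>
    select("root_id", "timepoint_h", "tile_id")
}

#' Simulate a cohort and run segmentation scene by scene
#'
#' Streams over the cohort manifest, simulating each tile and immediately
#' extracting patches, so memory stays bounded by one scene. Returns the
#' combined recovered patch table, the combined planted ground truth, and
#' per-root centreline lengths.
#'
#' @param config A [scene_config()].
#' @param seed Integer cohort seed.
#' @param manifest Optional pre-computed [cohort_manifest()] subset.
#' @param background_subtract Constant subtracted from mean intensities at
#'   extraction (defaults to the configured background level).
#' @return List with `patches`, `truth` (tibbles) and `root_lengths_um`
#'   (named per root: total centreline length across its tiles).
#' @export
run_cohort <- function(config, seed, manifest = NULL,
                       background_subtract = config$background_level) {
  manifest <- manifest %||% cohort_manifest(config, seed)
  acc_p <- list(); acc_t <- list()
  root_len <- numeric(0)
  for (i in seq_len(nrow(manifest))) {
    sc <- simulate_scene(config, seed, root_id = manifest$root_id[i],
                         timepoint_h = manifest$timepoint_h[i],
                         tile_id = manifest$tile_id[i])
    p <- segment_scene(sc, background_subtract = background_subtract)
    acc_p[[i]] <- p
    acc_t[[i]] <- dplyr::select(sc$truth, -"pixels")
    key <- as.character(sc$root_id)
    root_len[key] <- max(c(root_len[key], root_length_um(sc$geometry)),
                         na.rm = TRUE)
  }
  list(patches = bind_rows(acc_p), truth = bind_rows(acc_t),
       root_lengths_um = root_len)
}
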