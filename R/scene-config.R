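#' Synthetic microcosm scene configuration
#'
#' Describes one simulated imaging study: tile geometry and resolution,
#' transparent-soil particle packing, root shape, cohort layout (roots,
#' timepoints, tiles per root), bacterial patch placement, the linear
#' fluorescence calibration used for rendering, and the noise model.
#'
#' Defaults mirror the structure of the imaging study the package targets:
#' 3.2 x 3.2 mm tiles at 6.21 um per pixel, soil particle diameters
#' 250-1250 um, 12 roots followed at 12, 24, 36 and 48 h post-inoculation
#' with 2-6 tiles per root.
#'
#' @param tile_width_mm,tile_height_mm Tile size in mm.
#' @param pixel_size_um Pixel size in um.
#' @param particle_diameter_range_um Length-2 numeric, min < max, in um.
#' @param particle_packing_fraction Target areal packing fraction in (0, 1).
#' @param root_width_um Root width in um (must exceed 2 pixels).
#' @param root_curvature Standard deviation (radians) of the per-step heading
#'   change of the simulated root centreline; 0 gives a straight root.
#' @param n_roots Number of roots in the cohort.
#' @param timepoints_h Strictly increasing imaging times in hours.
#' @param tiles_per_root Length-2 integer range; tiles per root are drawn
#'   uniformly from this range.
#' @param placement A [placement_model()].
#' @param calibration_slope,calibration_intercept Linear map from cell count
#'   to total patch fluorescence (intensity units per cell; intensity units).
#' @param background_level Constant background intensity added when rendering.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param label_flip_rate Fraction of pixels whose one-hot class probability
#'   is flipped to a random other class when rendering probability stacks.
#' @return A validated `scene_config` list.
#' @export
scene_config <- function(tile_width_mm = 3.2,
                         tile_height_mm = 3.2,
                         pixel_size_um = 6.21,
                         particle_diameter_range_um = c(250, 1250),
                         particle_packing_fraction = 0.35,
                         root_width_um = 250,
                         root_curvature = 0.15,
                         n_roots = 12,
                         timepoints_h = c(12, 24, 36, 48),
                         tiles_per_root = c(2L, 6L),
                         placement = placement_model(),
                         calibration_slope = 39,
                         calibration_intercept = 331,
                         background_level = 0,
                         noise_sd = 0,
                         label_flip_rate = 0) {
  cfg <- list(
    tile_width_mm = tile_width_mm, tile_height_mm = tile_height_mm,
    pixel_size_um = pixel_size_um,
    particle_diameter_range_um = particle_diameter_range_um,
    particle_packing_fraction = particle_packing_fraction,
    root_width_um = root_width_um, root_curvature = root_curvature,
    n_roots = n_roots, timepoints_h = timepoints_h,
    tiles_per_root = tiles_per_root, placement = placement,
    calibration_slope = calibration_slope,
    calibration_intercept = calibration_intercept,
    background_level = background_level, noise_sd = noise_sd,
    label_flip_rate = label_flip_rate)
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  stopifnot(cfg$tile_width_mm > 0, cfg$tile_height_mm > 0,
            cfg$pixel_size_um > 0, cfg$root_width_um > 0,
            cfg$n_roots >= 1, length(cfg$tiles_per_root) == 2,
            cfg$tiles_per_root[1] >= 1,
            cfg$tiles_per_root[2] >= cfg$tiles_per_root[1],
            cfg$background_level >= 0, cfg$noise_sd >= 0,
            cfg$label_flip_rate >= 0, cfg$label_flip_rate < 1)
  if (!(cfg$particle_packing_fraction >= 0 && cfg$particle_packing_fraction < 1))
    abort("particle_packing_fraction must lie in [0, 1)")
  r <- cfg$particle_diameter_range_um
  if (length(r) != 2 || any(r <= 0) || r[1] >= r[2])
    abort("particle_diameter_range_um must be positive with low < high")
  t <- cfg$timepoints_h
  if (length(t) < 1 || any(diff(t) <= 0))
    abort("timepoints_h must be strictly increasing")
  if (!inherits(cfg$placement, "placement_model"))
    abort("placement must be a placement_model()")
  invisible(cfg)
}

scene_dim <- function(config) {
  c(nx = round(config$tile_width_mm * 1000 / config$pixel_size_um),
    ny = round(config$tile_height_mm * 1000 / config$pixel_size_um))
}

#' Bacterial patch placement model
#'
#' Per-class placement rules for the synthetic generator. Each class carries a
#' Poisson mean patch count per tile and timepoint, log-normal patch area and
#' cells-per-patch distributions, and a spatial law:
#'
#' * `MB` (mobile bacteria): centroids in the pore space with probability
#'   proportional to `exp(-dr/lambda_r) * exp(-dp/lambda_p)`, optionally
#'   multiplied by `exp(-da/lambda_tip(t))` so early mobile populations
#'   concentrate near the root tip.
#' * `RB` (root biofilm): uniform on root-boundary pixels at distance from the
#'   tip `da >= d_min_tip_um`, from `onset_h` onwards.
#' * `PB` (particle biofilm): uniform on particle-perimeter pixels with
#'   distance to the root `dr <= max_dr_um`.
#'
#' Temporal count weights default to a mobile peak at 12-24 h and biofilm
#' classes increasing with time. These are generator knobs describing the
#' planted truth, not estimates.
#'
#' @param mb,rb,pb Per-class parameter lists; see Details via defaults.
#' @param attempt_cap_factor Rejection-sampling attempt cap, as a multiple of
#'   the requested patch count; on hitting the cap the generator warns and
#'   returns the patches placed so far.
#' @return A `placement_model` list.
#' @export
placement_model <- function(
    mb = list(count_mean = c(`12` = 12, `24` = 12, `36` = 6, `48` = 4),
              area_meanlog = log(1500), area_sdlog = 0.5,
              cells_meanlog = log(150), cells_sdlog = 0.5,
              lambda_r_um = 100, lambda_p_um = 100,
              lambda_tip_um = c(`12` = 1500, `24` = 1500, `36` = Inf, `48` = Inf)),
    rb = list(count_mean = c(`12` = 2, `24` = 3, `36` = 5, `48` = 7),
              area_meanlog = log(3000), area_sdlog = 0.5,
              cells_meanlog = log(400), cells_sdlog = 0.5,
              d_min_tip_um = 794, onset_h = 12),
    pb = list(count_mean = c(`12` = 1, `24` = 3, `36` = 5, `48` = 7),
              area_meanlog = log(2500), area_sdlog = 0.5,
              cells_meanlog = log(300), cells_sdlog = 0.5,
              max_dr_um = 100),
    attempt_cap_factor = 50) {
  stopifnot(mb$lambda_r_um > 0, mb$lambda_p_um > 0, all(mb$lambda_tip_um > 0),
            rb$d_min_tip_um >= 0, pb$max_dr_um > 0, attempt_cap_factor >= 1,
            all(mb$count_mean >= 0), all(rb$count_mean >= 0),
            all(pb$count_mean >= 0))
  structure(list(mb = mb, rb = rb, pb = pb,
                 attempt_cap_factor = attempt_cap_factor),
            class = "placement_model")
}

# Poisson mean for a class at a timepoint; names of count_mean are hours.
count_mean_at <- function(class_params, timepoint_h) {
  cm <- class_params$count_mean
  nm <- as.character(timepoint_h)
  if (!is.null(names(cm)) && nm %in% names(cm)) return(unname(cm[nm]))
  # unnamed or unknown timepoint: recycle the last value
  unname(cm[length(cm)])
}
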