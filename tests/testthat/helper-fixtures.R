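# Shared fixtures, generated once per test session and cached.

.fx <- new.env(parent = emptyenv())

# a full-size default tile with planted patches at 24 h
fixture_scene <- function() {
  if (is.null(.fx$scene))
    .fx$scene <- simulate_scene(scene_config(), seed = 7, root_id = 1,
                                timepoint_h = 24, tile_id = 1)
  .fx$scene
}

fixture_labelmap <- function() {
  if (is.null(.fx$labelmap)) {
    sc <- fixture_scene()
    .fx$labelmap <- overlay_root(argmax_classify(sc$probstack), sc$geometry,
                                 sc$config$pixel_size_um)
  }
  .fx$labelmap
}

# small noiseless cohort: 2 roots, 1-2 tiles, all four timepoints
fixture_cohort <- function() {
  if (is.null(.fx$cohort)) {
    cfg <- scene_config(n_roots = 2, tiles_per_root = c(1L, 2L))
    .fx$cohort <- suppressWarnings(run_cohort(cfg, seed = 5))
  }
  .fx$cohort
}

# quick-to-simulate configuration for I/O and pipeline tests
tiny_config <- function(...) {
  scene_config(tile_width_mm = 1.6, tile_height_mm = 1.6,
               particle_diameter_range_um = c(150, 400),
               particle_packing_fraction = 0.25,
               n_roots = 2, tiles_per_root = c(1L, 1L),
               timepoints_h = c(12, 24), ...)
}

# brute-force minimum center-to-center distance from a point to mask pixels
brute_min_dist <- function(x_um, y_um, mask, px) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(Inf)
  min(sqrt(((idx[, 1] - 0.5) * px - x_um)^2 + ((idx[, 2] - 0.5) * px - y_um)^2))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_enumerate <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  u_obs <- sum(rank(pool)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pool), n1)
  u_all <- apply(combos, 2, function(ix) {
    sum(rank(pool)[ix]) - n1 * (n1 + 1) / 2
  })
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# per-pixel exhaustive covariate histogram of a support class, normalized
# over all support pixels (the null-model oracle)
exhaustive_histogram <- function(labelmap, geometry, px, code, edges_dp, edges_dr) {
  idx <- which(labelmap == code)
  rc <- arrayInd(idx, dim(labelmap))
  pts <- tibble::tibble(x_um = (rc[, 1] - 0.5) * px, y_um = (rc[, 2] - 0.5) * px)
  cov <- compute_covariates(pts, labelmap == 1, labelmap == 6, geometry, px,
                            covariates = c("dp", "dr"))
  h <- table(cut(cov$dp_um, edges_dp, include.lowest = TRUE),
             cut(cov$dr_um, edges_dr, include.lowest = TRUE))
  as.vector(h) / length(idx) /
    (diff(edges_dp)[1] * diff(edges_dr)[1])
}
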