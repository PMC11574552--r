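#' Generate a transparent-soil particle mask
#'
#' Places non-overlapping discs with diameters drawn uniformly from the
#' configured range by rejection sampling until the target packing fraction
#' is reached or an attempt cap (50 times the expected particle count) is
#' exhausted, in which case it warns and returns the achieved packing.
#' Discs are kept fully inside the tile with at least a one-pixel gap so
#' every particle is a distinct connected component.
#'
#' @param config A [scene_config()].
#' @param seed Integer seed.
#' @return List with `mask` (integer 0/1 matrix), `particles` (tibble with
#'   `x_um`, `y_um`, `diameter_um`) and `achieved_fraction`.
#' @export
generate_particles <- function(config, seed) {
  d <- scene_dim(config)
  px <- config$pixel_size_um
  W <- d["nx"] * px; H <- d["ny"] * px
  target <- config$particle_packing_fraction
  rng <- config$particle_diameter_range_um
  mask <- matrix(0L, d["nx"], d["ny"])
  parts <- list()
  if (target > 0) {
    mean_area <- pi * mean(rng / 2)^2
    n_expected <- max(1, ceiling(target * W * H / mean_area))
    cap <- 50L * n_expected
    with_seed(substream_seed(seed, "particles"), {
      area_placed <- 0
      attempts <- 0L
      while (area_placed / (W * H) < target && attempts < cap) {
        attempts <- attempts + 1L
        dia <- runif(1, rng[1], rng[2])
        r <- dia / 2
        if (2 * r + 2 * px >= min(W, H)) next
        cx <- runif(1, r + px, W - r - px)
        cy <- runif(1, r + px, H - r - px)
        ok <- TRUE
        for (p in parts) {
          if (sqrt((p$x - cx)^2 + (p$y - cy)^2) < r + p$r + 2 * px) {
            ok <- FALSE; break
          }
        }
        if (!ok) next
        parts[[length(parts) + 1]] <- list(x = cx, y = cy, r = r)
        area_placed <- area_placed + pi * r^2
      }
      if (area_placed / (W * H) < target)
        warn(sprintf(
          "particle packing fraction %.3f not reachable; achieved %.3f after %d attempts",
          target, area_placed / (W * H), attempts))
    })
    for (p in parts) mask <- paint_disc(mask, p$x, p$y, p$r, px)
  }
  particles <- if (length(parts))
    tibble(x_um = map_dbl(parts, "x"), y_um = map_dbl(parts, "y"),
           diameter_um = 2 * map_dbl(parts, "r"))
  else tibble(x_um = numeric(0), y_um = numeric(0), diameter_um = numeric(0))
  list(mask = mask, particles = particles,
       achieved_fraction = sum(mask) / length(mask))
}

# set pixels whose centers fall inside the disc
paint_disc <- function(mask, cx, cy, r, px) {
  nx <- nrow(mask); ny <- ncol(mask)
  ix <- max(1L, floor((cx - r) / px)):min(nx, ceiling((cx + r) / px))
  iy <- max(1L, floor((cy - r) / px)):min(ny, ceiling((cy + r) / px))
  gx <- px_centers(nx, px)[ix]; gy <- px_centers(ny, px)[iy]
  inside <- outer(gx - cx, gy - cy, function(a, b) a^2 + b^2) <= r^2
  sub <- mask[ix, iy, drop = FALSE]
  sub[inside] <- 1L
  mask[ix, iy] <- sub
  mask
}

#' Generate a simulated root and its traced geometry
#'
#' Draws a smooth centreline entering from the bottom tile edge as a
#' mean-reverting random walk of headings, with the tip inside the tile
#' (for `tile_index = 1`) or crossing the whole tile (later tiles along a
#' mature root, with arc length offset accordingly). The boundary polygon is
#' the centreline offset by half the root width on each side; the mask is
#' its rasterization under the package's single even-odd rule.
#'
#' @param config A [scene_config()].
#' @param seed Integer seed.
#' @param tile_index 1 for the tip-containing tile; larger values generate a
#'   root segment crossing the tile with arc length offset by the previous
#'   tiles' spans.
#' @return List with `geometry` ([root_geometry()]) and `mask` (logical).
#' @export
generate_root <- function(config, seed, tile_index = 1L) {
  d <- scene_dim(config)
  px <- config$pixel_size_um
  W <- d["nx"] * px; H <- d["ny"] * px
  w <- config$root_width_um
  if (w >= W) abort("root width must be smaller than the tile width")
  if (w <= 2 * px) abort("root width must exceed 2 pixels at this resolution")
  with_seed(substream_seed(seed, "root", tile_index), {
    step <- 5 * px
    x <- runif(1, 0.35 * W, 0.65 * W); y <- 0
    theta <- pi / 2 + rnorm(1, 0, 0.05)
    frac <- if (tile_index == 1L) runif(1, 0.6, 0.85) else 1.05
    target_len <- frac * H
    pts <- list(c(x, y))
    len <- 0
    margin <- w / 2 + 2 * px
    while (len < target_len) {
      theta <- theta + rnorm(1, 0, config$root_curvature * step / (50 * px)) +
        0.02 * (pi / 2 - theta)  # mean reversion keeps the root heading up
      x2 <- x + step * cos(theta); y2 <- y + step * sin(theta)
      if (x2 < margin || x2 > W - margin) {
        theta <- pi - theta  # reflect off the side margins
        x2 <- x + step * cos(theta); y2 <- y + step * sin(theta)
      }
      if (y2 > H + step) break
      pts[[length(pts) + 1]] <- c(x2, y2)
      len <- len + step
      x <- x2; y <- y2
    }
    cl <- do.call(rbind, pts)
  })
  cl <- cl[rev(seq_len(nrow(cl))), , drop = FALSE]  # tip-first ordering
  boundary <- offset_polygon(cl, w / 2)
  offset_um <- if (tile_index > 1L) (tile_index - 1L) * H else 0
  geometry <- root_geometry(
    centreline = tibble(x_um = cl[, 1], y_um = cl[, 2]),
    boundary = tibble(x_um = boundary[, 1], y_um = boundary[, 2]),
    s_offset_um = offset_um)
  mask <- rasterize_root(geometry, d, px)
  list(geometry = geometry, mask = mask)
}

# Closed polygon from a polyline offset by +/- half-width along vertex normals.
offset_polygon <- function(cl, halfwidth) {
  n <- nrow(cl)
  tng <- matrix(0, n, 2)
  tng[1, ] <- cl[2, ] - cl[1, ]
  tng[n, ] <- cl[n, ] - cl[n - 1, ]
  if (n > 2)  # central differences for interior vertices
    tng[2:(n - 1), ] <- cl[3:n, , drop = FALSE] - cl[1:(n - 2), , drop = FALSE]
  nrm <- cbind(-tng[, 2], tng[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  left <- cl + halfwidth * nrm
  right <- cl - halfwidth * nrm
  rbind(left, right[rev(seq_len(n)), , drop = FALSE])
}
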