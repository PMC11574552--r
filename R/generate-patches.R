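#' Plant bacterial patches in a synthetic scene
#'
#' Samples patch centroids from each class's spatial law restricted to its
#' legal support (mobile bacteria in the pore space; root biofilm on the
#' root-boundary ring at `da >= d_min_tip_um`; particle biofilm on particle
#' perimeters within `max_dr_um` of the root), draws patch areas and
#' cells-per-patch from the placement model, and realizes each patch as the
#' set of nearest legal pixels of the drawn area so that stored ground truth
#' (centroid, area, covariates) is exactly recomputable from the rendered
#' masks.
#'
#' @param config A [scene_config()].
#' @param masks List with `particle` (0/1 matrix) and `root` (logical matrix).
#' @param geometry The scene's [root_geometry()].
#' @param timepoint_h Timepoint in hours (selects temporal count weights).
#' @param seed Integer seed.
#' @param paint Realize pixel sets and avoid any patch overlap (default).
#'   With `paint = FALSE` only centroids/areas/cells are sampled (fast path
#'   for distribution-level tests); such patches cannot be rendered.
#' @return Tibble of planted patches: `class`, `area_um2`, `cells`, `npx`,
#'   `cx_um`, `cy_um`, `dp_um`, `dr_um`, `da_um`, `timepoint_h`, plus a
#'   `pixels` list-column of linear pixel indices when `paint = TRUE`.
#' @export
place_patches <- function(config, masks, geometry, timepoint_h, seed,
                          paint = TRUE) {
  px <- config$pixel_size_um
  pm <- config$placement
  dm <- distance_maps(masks$particle, masks$root, px)
  pore <- !(masks$particle > 0) & !(masks$root > 0)
  dims <- dim(pore)
  centers_x <- px_centers(dims[1], px)
  centers_y <- px_centers(dims[2], px)

  taken <- matrix(FALSE, dims[1], dims[2])
  out <- list()

  sample_class <- function(class, n, support, weights, paint_support) {
    if (n == 0) return(NULL)
    sup_idx <- which(support)
    if (length(sup_idx) == 0) {
      warn(sprintf("no legal support for %s patches; placing none", class))
      return(NULL)
    }
    w <- weights[sup_idx]
    if (all(w <= 0)) {
      warn(sprintf("zero total placement weight for %s patches; placing none", class))
      return(NULL)
    }
    p <- pm[[tolower(class)]]
    cap <- ceiling(pm$attempt_cap_factor * n)
    placed <- list(); attempts <- 0L
    cumw <- cumsum(w)
    total_w <- cumw[length(cumw)]
    while (length(placed) < n && attempts < cap) {
      attempts <- attempts + 1L
      pick <- sup_idx[findInterval(runif(1) * total_w, cumw) + 1L]
      if (paint && taken[pick]) next
      rc <- arrayInd(pick, dims)
      cx <- centers_x[rc[1]]; cy <- centers_y[rc[2]]
      area <- min(max(rlnorm(1, p$area_meanlog, p$area_sdlog), 4 * px^2), 3e4)
      cells <- max(1, round(rlnorm(1, p$cells_meanlog, p$cells_sdlog)))
      npx <- max(4L, as.integer(round(area / px^2)))
      if (!paint) {
        placed[[length(placed) + 1]] <- list(
          cx = cx, cy = cy, npx = npx, pixels = NULL, cells = cells)
        next
      }
      pixels <- nearest_support_pixels(cx, cy, npx, paint_support & !taken,
                                       centers_x, centers_y, px)
      if (length(pixels) < 4L) next
      # realized centroid; ground truth must match the painted region
      rcs <- arrayInd(pixels, dims)
      placed[[length(placed) + 1]] <- list(
        cx = mean(centers_x[rcs[, 1]]), cy = mean(centers_y[rcs[, 2]]),
        npx = length(pixels), pixels = pixels, cells = cells)
      # reserve painted pixels plus a one-pixel ring so patches stay disjoint
      ring <- dilate_indices(pixels, dims)
      taken[ring] <<- TRUE
    }
    if (length(placed) < n)
      warn(sprintf("placed %d of %d requested %s patches after %d attempts",
                   length(placed), n, class, attempts))
    if (length(placed) == 0) return(NULL)
    tibble(
      class = class,
      area_um2 = map_dbl(placed, "npx") * px^2,
      cells = map_dbl(placed, "cells"),
      npx = as.integer(map_dbl(placed, "npx")),
      cx_um = map_dbl(placed, "cx"), cy_um = map_dbl(placed, "cy"),
      pixels = map(placed, "pixels"))
  }

  with_seed(substream_seed(seed, "patches", timepoint_h), {
    # MB: pore space, probability ~ exp(-dr/l_r) exp(-dp/l_p) [exp(-da/l_tip)]
    n_mb <- rpois(1, count_mean_at(pm$mb, timepoint_h))
    w_mb <- exp(-dm$dr / pm$mb$lambda_r_um)
    if (any(masks$particle > 0)) w_mb <- w_mb * exp(-dm$dp / pm$mb$lambda_p_um)
    w_mb[!pore] <- 0
    ltip <- count_mean_at(list(count_mean = pm$mb$lambda_tip_um), timepoint_h)
    if (is.finite(ltip)) {
      # tip weighting only matters where the dr/dp factors are non-negligible
      sig <- w_mb > max(w_mb) * 1e-6
      da_map <- da_map_for(sig, geometry, centers_x, centers_y,
                           coarse_um = 20 * px)
      w_mb[sig] <- w_mb[sig] * exp(-da_map[sig] / ltip)
      w_mb[!sig] <- 0
    }
    out$MB <- sample_class("MB", n_mb, pore, w_mb, pore)

    # RB: uniform on the root-boundary ring at da >= d_min_tip
    n_rb <- if (timepoint_h >= pm$rb$onset_h)
      rpois(1, count_mean_at(pm$rb, timepoint_h)) else 0L
    ring <- pore & dm$dr <= 1.5 * px & dm$dr > 0
    if (n_rb > 0 && any(ring)) {
      ring_idx <- which(ring)
      rcs <- arrayInd(ring_idx, dims)
      da_ring <- da_nearest(tibble(x_um = centers_x[rcs[, 1]],
                                   y_um = centers_y[rcs[, 2]]),
                            geometry, spacing_um = px)
      legal <- ring
      legal[ring_idx[da_ring < pm$rb$d_min_tip_um]] <- FALSE
      if (!any(legal)) {
        warn("no root boundary beyond d_min_tip; placing no RB patches")
      } else {
        w_rb <- matrix(0, dims[1], dims[2]); w_rb[legal] <- 1
        out$RB <- sample_class("RB", n_rb, legal, w_rb,
                               pore & dm$dr <= 2.5 * px)
      }
    } else if (n_rb > 0) {
      warn("no root boundary beyond d_min_tip; placing no RB patches")
    }

    # PB: uniform on particle-perimeter pixels within max_dr of the root
    n_pb <- rpois(1, count_mean_at(pm$pb, timepoint_h))
    if (n_pb > 0) {
      perim <- pore & dm$dp <= 1.5 * px & dm$dp > 0
      legal <- perim & dm$dr <= pm$pb$max_dr_um
      w_pb <- matrix(0, dims[1], dims[2]); w_pb[legal] <- 1
      out$PB <- sample_class("PB", n_pb, legal, w_pb,
                             pore & dm$dp <= 2.5 * px)
    }
  })

  patches <- bind_rows(out)
  if (nrow(patches) == 0) {
    return(tibble(class = character(0), area_um2 = numeric(0),
                  cells = numeric(0), npx = integer(0),
                  cx_um = numeric(0), cy_um = numeric(0),
                  dp_um = numeric(0), dr_um = numeric(0), da_um = numeric(0),
                  timepoint_h = numeric(0), pixels = list()))
  }
  cov <- compute_covariates(tibble(x_um = patches$cx_um, y_um = patches$cy_um),
                            masks$particle, masks$root, geometry, px)
  patches$dp_um <- cov$dp_um
  patches$dr_um <- cov$dr_um
  patches$da_um <- cov$da_um
  patches$timepoint_h <- timepoint_h
  patches[, c("class", "area_um2", "cells", "npx", "cx_um", "cy_um",
              "dp_um", "dr_um", "da_um", "timepoint_h", "pixels")]
}

# n nearest available support pixels around (cx, cy); grows the search
# window geometrically until enough pixels are found or support is exhausted.
nearest_support_pixels <- function(cx, cy, n, support, centers_x, centers_y, px) {
  dims <- dim(support)
  r <- max(3, ceiling(sqrt(n / pi))) + 2
  repeat {
    ix <- max(1, floor(cx / px) - r):min(dims[1], floor(cx / px) + r)
    iy <- max(1, floor(cy / px) - r):min(dims[2], floor(cy / px) + r)
    sub <- support[ix, iy, drop = FALSE]
    hits <- which(sub)
    full_window <- length(ix) == dims[1] && length(iy) == dims[2]
    if (length(hits) >= n || full_window) {
      if (length(hits) == 0) return(integer(0))
      rc <- arrayInd(hits, dim(sub))
      gx <- centers_x[ix[rc[, 1]]]; gy <- centers_y[iy[rc[, 2]]]
      d2 <- (gx - cx)^2 + (gy - cy)^2
      ord <- order(d2)[seq_len(min(n, length(hits)))]
      return((ix[rc[ord, 1]] - 1L) + (iy[rc[ord, 2]] - 1L) * dims[1] + 1L)
    }
    r <- r * 2L
  }
}

# linear indices of a pixel set plus its 8-neighbourhood (clipped to grid)
dilate_indices <- function(pixels, dims) {
  rc <- arrayInd(pixels, dims)
  off <- expand.grid(dx = -1:1, dy = -1:1)
  r <- pmin(pmax(rep(rc[, 1], each = 9) + off$dx, 1L), dims[1])
  c2 <- pmin(pmax(rep(rc[, 2], each = 9) + off$dy, 1L), dims[2])
  unique((r - 1L) + (c2 - 1L) * dims[1] + 1L)
}

# coarse distance-from-tip map over support pixels (um); used only as a
# placement weight, so nearest-vertex spacing can be coarse
da_map_for <- function(support, geometry, centers_x, centers_y, coarse_um) {
  dims <- dim(support)
  idx <- which(support)
  rc <- arrayInd(idx, dims)
  da <- da_nearest(tibble(x_um = centers_x[rc[, 1]], y_um = centers_y[rc[, 2]]),
                   geometry, spacing_um = coarse_um)
  m <- matrix(Inf, dims[1], dims[2])
  m[idx] <- da
  m
}
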