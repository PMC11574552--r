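#' Null model: equal-probability occupancy of a support class
#'
#' Builds the density expected if every pixel of a support class (normally
#' the pore space) were equally likely to be colonized: each support pixel
#' becomes a pseudo-patch of unit intensity and one-pixel area, and the same
#' weighted kernel estimator is applied. The pseudo-patch bandwidth is the
#' pixel radius `sqrt(pixel_area/pi)`, floored at half the evaluation-cell
#' diagonal so that every support pixel deposits its mass on at least one
#' grid-cell center (see the methods vignette).
#'
#' @param labelmap Class-code matrix including the `ROOT` overlay.
#' @param geometry A [root_geometry()] (needed when `da` is a covariate).
#' @param pixel_size_um Pixel size in um.
#' @param support Support class: `"PORE"`, `"ROOT"` or `"PARTICLE"`.
#' @param covariates,grid As in [estimate_density()].
#' @param subsample Fraction of support pixels used (uniform, seeded).
#' @param seed Seed for the subsampling stream.
#' @return A `density_field` with flag `"null"`.
#' @export
null_model <- function(labelmap, geometry, pixel_size_um,
                       support = "PORE", covariates = c("dp", "dr"),
                       grid = density_grid(covariates),
                       subsample = 1, seed = 1L) {
  stopifnot(support %in% c("PORE", "ROOT", "PARTICLE"), subsample > 0,
            subsample <= 1)
  code <- if (support == "ROOT") ROOT_CODE else class_code(support)
  idx <- which(labelmap == code)
  if (length(idx) == 0) abort(sprintf("support class %s is empty", support))
  if (subsample < 1) {
    idx <- with_seed(substream_seed(seed, "null-subsample"), {
      sort(sample(idx, max(1L, round(subsample * length(idx)))))
    })
  }
  dims <- dim(labelmap)
  rc <- arrayInd(idx, dims)
  pts <- tibble(x_um = (rc[, 1] - 0.5) * pixel_size_um,
                y_um = (rc[, 2] - 0.5) * pixel_size_um)
  particle_mask <- labelmap == class_code("PARTICLE")
  root_mask <- labelmap == ROOT_CODE
  cov <- compute_covariates(pts, particle_mask, root_mask, geometry,
                            pixel_size_um, covariates = covariates)
  pseudo <- dplyr::bind_cols(
    tibble(area_um2 = rep(pixel_size_um^2, nrow(cov)), mean_intensity = 1),
    cov)
  cols <- paste0(covariates, "_um")
  keep <- rowSums(!is.finite(as.matrix(pseudo[, cols]))) == 0
  pseudo <- pseudo[keep, ]
  if (nrow(pseudo) == 0) abort("no support pixel has finite covariates")
  half_diag <- sqrt(sum(vapply(grid_widths(grid),
                               function(wd) max(wd)^2 / 4, numeric(1))))
  estimate_density(pseudo, covariates, grid,
                   h_min_um = max(pixel_size_um / sqrt(pi), half_diag),
                   flag = "null")
}

#' Mean bacterial cell density field
#'
#' Converts a probability density into an expected cell density
#' `rho(x) = p~(x) * Q_bar`, where `Q_bar` is the average calibrated
#' bacterial quantity per root: the calibrated cell counts of all patches
#' divided by the number of roots `R`.
#'
#' @param field A `density_field` from [estimate_density()].
#' @param patches The patch tibble the field was estimated from (needs
#'   `total_intensity`).
#' @param calibration A [calibration_model()].
#' @param n_roots Number of roots `R` in the dataset.
#' @return The field with an added `rho` column (cells um^-n) and `Q_bar`
#'   attribute, classed `cell_density_field`.
#' @export
mean_cell_density <- function(field, patches, calibration, n_roots) {
  if (!is.numeric(n_roots) || n_roots <= 0) abort("n_roots must be positive")
  q_bar <- sum(intensity_to_cells(patches$total_intensity, calibration)) /
    n_roots
  field$rho <- field$p_tilde * q_bar
  attr(field, "Q_bar") <- q_bar
  attr(field, "R") <- n_roots
  class(field) <- unique(c("cell_density_field", class(field)))
  field
}

#' Per-timepoint density fields
#'
#' One independent density field per timepoint over a shared grid, each
#' normalized within its own timepoint. Timepoints with no patches yield an
#' all-zero field flagged `"empty"`.
#'
#' @param patches Patch tibble with a `timepoint_h` column.
#' @param timepoints Timepoints to produce (defaults to those present).
#' @inheritParams estimate_density
#' @return Named list of `density_field`s, one per timepoint.
#' @export
temporal_density <- function(patches, covariates = c("dp", "dr"),
                             grid = density_grid(covariates),
                             timepoints = sort(unique(patches$timepoint_h)),
                             h_min_um = 6.21) {
  fields <- lapply(timepoints, function(t) {
    sub <- patches[patches$timepoint_h == t, ]
    if (nrow(sub) == 0 || sum(sub$area_um2 * sub$mean_intensity) <= 0) {
      f <- empty_field(covariates, grid)
      return(f)
    }
    estimate_density(sub, covariates, grid, h_min_um = h_min_um)
  })
  setNames(fields, as.character(timepoints))
}

empty_field <- function(covariates, grid) {
  centers <- grid_centers(grid)
  cells <- do.call(tidyr::expand_grid, rev(setNames(centers, covariates)))
  cells <- cells[, covariates]
  cellvol <- Reduce(function(a, b) as.vector(outer(a, b)), grid_widths(grid))
  field <- as_tibble(cells)
  field$p_tilde <- 0
  field$cell_volume <- cellvol
  structure(field, class = c("density_field", class(field)),
            covariates = covariates, grid = grid, M = 0, N = 0L,
            flag = "empty", h_min_um = NA_real_, integral = 0)
}

#' Marginal of a density field over one covariate
#'
#' Integrates the field over all other axes, returning a one-dimensional
#' density in the chosen covariate.
#'
#' @param field A `density_field`.
#' @param covariate Axis to keep.
#' @return Tibble with the covariate centers, `density` (um^-1) and the bin
#'   `width`.
#' @export
field_marginal <- function(field, covariate) {
  covs <- attr(field, "covariates")
  stopifnot(covariate %in% covs)
  wd <- grid_widths(attr(field, "grid"))
  x <- field[[covariate]]
  centers <- sort(unique(x))
  width <- wd[[covariate]][match(centers, grid_centers(attr(field, "grid"))[[covariate]])]
  mass <- vapply(centers, function(cc) {
    rows <- x == cc
    sum(field$p_tilde[rows] * field$cell_volume[rows])
  }, numeric(1))
  out <- tibble(center = centers, width = width, density = mass / width)
  names(out)[1] <- covariate
  out
}

#' Recover exponential placement scales from a density field
#'
#' The synthetic generator plants mobile-bacteria centroids over pore pixels
#' with weight `exp(-dp/lambda_p) * exp(-dr/lambda_r)`. Relative to the
#' null (availability) field on the same grid, the log of the estimated
#' density is linear in every covariate with slope `-1/lambda`, so all
#' scales are recovered at once by weighted least squares on
#' `log(p_model / p_null)` against the covariate axes jointly. The joint fit
#' is the estimator consistent with the planted law: single-covariate
#' marginals are biased wherever covariates are correlated in the pore
#' space (e.g. particles are scarce right next to the root).
#'
#' @param field Model `density_field`.
#' @param reference Null-model field on the same grid ([null_model()]).
#' @param range Fit window (um) applied to every covariate; cells outside
#'   it (boundary-distorted or empty) are excluded.
#' @return Tibble with `covariate`, `lambda_um`, `slope`.
#' @export
recover_placement_scales <- function(field, reference, range = c(20, 300)) {
  covs <- attr(field, "covariates")
  stopifnot(identical(covs, attr(reference, "covariates")),
            nrow(field) == nrow(reference))
  y <- ifelse(reference$p_tilde > 0, field$p_tilde / reference$p_tilde,
              NA_real_)
  X <- as.matrix(field[, covs])
  ok <- is.finite(y) & y > 0
  for (j in seq_along(covs)) ok <- ok & X[, j] >= range[1] & X[, j] <= range[2]
  if (sum(ok) < length(covs) + 2)
    abort("too few informative cells to fit placement scales")
  w <- field$p_tilde[ok] * field$cell_volume[ok]
  fit <- lm(log(y[ok]) ~ X[ok, , drop = FALSE], weights = w)
  slopes <- coef(fit)[-1]
  tibble(covariate = covs, lambda_um = -1 / unname(slopes),
         slope = unname(slopes))
}

#' Recover an exponential placement scale from a one-dimensional marginal
#'
#' The synthetic generator plants mobile-bacteria centroids with probability
#' proportional to `exp(-d/lambda)` per unit available pore area. The
#' observable marginal of the estimated density over that covariate is the
#' exponential law multiplied by pore-space availability, so the scale is
#' recovered by weighted least squares on the log of the model marginal
#' divided by the null (availability) marginal. With `reference = NULL` the
#' raw marginal is fitted (availability-convolved).
#'
#' @param field Model `density_field`.
#' @param covariate Covariate carrying the exponential law (e.g. `"dr"`).
#' @param reference Optional null-model field on the same grid.
#' @param range Fit window (um) over the covariate.
#' @return List with `lambda_um`, `slope`, `n_bins`.
#' @export
recover_exponential_scale <- function(field, covariate = "dr",
                                      reference = NULL,
                                      range = c(10, 300)) {
  m <- field_marginal(field, covariate)
  y <- m$density
  if (!is.null(reference)) {
    r <- field_marginal(reference, covariate)
    stopifnot(nrow(r) == nrow(m))
    y <- ifelse(r$density > 0, y / r$density, NA_real_)
  }
  x <- m[[covariate]]
  ok <- is.finite(y) & y > 0 & x >= range[1] & x <= range[2]
  if (sum(ok) < 3) abort("too few informative bins to fit an exponential scale")
  fit <- lm(log(y[ok]) ~ x[ok], weights = m$density[ok])
  slope <- unname(coef(fit)[2])
  list(lambda_um = -1 / slope, slope = slope, n_bins = sum(ok))
}
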