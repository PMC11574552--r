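#' Top-hat (Parzen) kernel value
#'
#' The kernel is constant inside the ellipsoid `sum((u_j/h_j)^2) <= 1` and 0
#' outside; the constant `C = 1 / (V_n * prod(h))`, with `V_n` the
#' n-dimensional unit-ball volume (`V_1 = 2`, `V_2 = pi`, `V_3 = 4*pi/3`),
#' makes the kernel integrate to 1. The boundary counts as inside.
#'
#' @param u Offset vector (um), or a matrix with one offset per row.
#' @param h Bandwidth vector (um), one entry per dimension; `n = length(h)`
#'   must be 1, 2 or 3.
#' @return Density value(s) in um^-n.
#' @export
kernel_value <- function(u, h) {
  n <- length(h)
  if (!n %in% 1:3) abort("kernel dimensionality must be 1, 2 or 3")
  if (any(h <= 0)) abort("bandwidths must be strictly positive")
  C <- 1 / (unit_ball_volume(n) * prod(h))
  u <- if (is.matrix(u)) u else matrix(u, ncol = n)
  inside <- rowSums(sweep(u, 2, h, "/")^2) <= 1
  ifelse(inside, C, 0)
}

#' Evaluation grid for density fields
#'
#' Bin edges per covariate, in um (hours for `t`). Defaults: `dp`, `dr` over
#' 0-500 um in 10 um bins; `da` over 0-10 mm in 0.5 mm bins.
#'
#' @param covariates Character vector, subset of `c("dp", "dr", "da")`.
#' @param ... Named numeric vectors of bin edges overriding the defaults.
#' @return Named list of strictly increasing bin-edge vectors.
#' @export
density_grid <- function(covariates = c("dp", "dr"), ...) {
  defaults <- list(dp = seq(0, 500, by = 10), dr = seq(0, 500, by = 10),
                   da = seq(0, 10000, by = 500))
  over <- list(...)
  grid <- lapply(setNames(covariates, covariates), function(nm) {
    e <- over[[nm]] %||% defaults[[nm]]
    if (is.null(e)) abort(sprintf("no default bin edges for covariate '%s'", nm))
    stopifnot(all(diff(e) > 0), length(e) >= 2)
    e
  })
  grid
}

grid_centers <- function(edges) lapply(edges, function(e) (head(e, -1) + e[-1]) / 2)
grid_widths <- function(edges) lapply(edges, diff)

#' Weighted kernel density estimate of bacterial occupancy
#'
#' Estimates the probability density of bacterial position in covariate
#' space as `p~(x) = (1/M) * sum_i A_i I_i K(x - x_i; h_i)`, with
#' `M = sum_i A_i I_i` the total recorded fluorescence, `K` the top-hat
#' kernel of [kernel_value()], and the isotropic bandwidth
#' `h_i = sqrt(A_i / pi)` (the patch radius), floored at `h_min_um`. The
#' field is evaluated at grid-cell centers. Kernels overhanging the grid are
#' not renormalized; the resulting integral deficit is reported in the
#' field's metadata (`glance()`).
#'
#' @param patches Patch tibble with `area_um2`, `mean_intensity` (or a
#'   `weight` column used verbatim) and covariate columns `dp_um`, `dr_um`,
#'   `da_um` as requested.
#' @param covariates Character vector naming the covariate axes.
#' @param grid Bin-edge list from [density_grid()].
#' @param h_min_um Bandwidth floor in um (default one pixel-equivalent at
#'   the reference resolution, 6.21 um).
#' @param flag Field flag, `"model"` or `"null"`.
#' @return A `density_field`: tibble with one row per grid cell (covariate
#'   center columns and `p_tilde`, um^-n), with estimator metadata in
#'   attributes; see [glance.density_field()].
#' @export
estimate_density <- function(patches, covariates = c("dp", "dr"),
                             grid = density_grid(covariates),
                             h_min_um = 6.21, flag = "model") {
  stopifnot(nrow(patches) >= 1, all(covariates %in% c("dp", "dr", "da")))
  cols <- paste0(covariates, "_um")
  if (!all(cols %in% names(patches)))
    abort(sprintf("patches lack covariate columns: %s",
                  paste(setdiff(cols, names(patches)), collapse = ", ")))
  X <- as.matrix(patches[, cols])
  if (any(!is.finite(X)))
    abort("non-finite covariates; drop patches with unattainable covariates first")
  w <- if ("weight" %in% names(patches)) patches$weight
       else patches$area_um2 * patches$mean_intensity
  if (any(w < 0)) abort("negative patch weights")
  M <- sum(w)
  if (M <= 0)
    abort("total fluorescence weight M = sum(A_i * I_i) is zero; the weighted estimator is degenerate")
  h <- pmax(sqrt(patches$area_um2 / pi), h_min_um)

  # deterministic accumulation order, so permuting patch rows is a no-op
  ord <- order(X[, 1], if (ncol(X) > 1) X[, 2] else numeric(nrow(X)),
               if (ncol(X) > 2) X[, 3] else numeric(nrow(X)), h, w)
  X <- X[ord, , drop = FALSE]; w <- w[ord]; h <- h[ord]

  n <- length(covariates)
  centers <- grid_centers(grid)
  dims <- vapply(centers, length, integer(1))
  vol_axes <- grid_widths(grid)
  arr <- array(0, dims)
  Vn <- unit_ball_volume(n)
  for (i in seq_along(w)) {
    if (w[i] == 0) next
    C <- 1 / (Vn * h[i]^n)
    idx <- lapply(seq_len(n), function(j)
      which(abs(centers[[j]] - X[i, j]) <= h[i]))
    if (any(lengths(idx) == 0)) next
    local <- lapply(seq_len(n), function(j)
      (centers[[j]][idx[[j]]] - X[i, j]) / h[i])
    if (n == 1) {
      inside <- local[[1]]^2 <= 1
      arr[idx[[1]]] <- arr[idx[[1]]] + (w[i] / M) * C * inside
    } else if (n == 2) {
      q <- outer(local[[1]]^2, local[[2]]^2, "+")
      arr[idx[[1]], idx[[2]]] <- arr[idx[[1]], idx[[2]]] +
        (w[i] / M) * C * (q <= 1)
    } else {
      q2 <- outer(local[[1]]^2, local[[2]]^2, "+")
      for (k in seq_along(idx[[3]])) {
        q <- q2 + local[[3]][k]^2
        arr[idx[[1]], idx[[2]], idx[[3]][k]] <-
          arr[idx[[1]], idx[[2]], idx[[3]][k]] + (w[i] / M) * C * (q <= 1)
      }
    }
  }

  cells <- do.call(tidyr::expand_grid, rev(setNames(centers, covariates)))
  cells <- cells[, covariates]  # expand_grid varies last column fastest
  cellvol <- Reduce(function(a, b) as.vector(outer(a, b)),
                    lapply(vol_axes, identity))
  field <- as_tibble(cells)
  field$p_tilde <- as.vector(arr)
  field$cell_volume <- cellvol
  structure(field,
            class = c("density_field", class(field)),
            covariates = covariates, grid = grid, M = M,
            N = nrow(patches), flag = flag, h_min_um = h_min_um,
            integral = sum(as.vector(arr) * cellvol))
}
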