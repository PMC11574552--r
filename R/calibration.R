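#' Linear fluorescence-to-cell-count calibration
#'
#' A calibration model maps a cell count to the total pixel intensity of a
#' patch via `intensity = slope * cells + intercept`. The bundled default
#' (`slope = 39`, `intercept = 331`) is the line fitted on low-density
#' images where individual cells could be counted.
#'
#' @param slope Intensity units per cell (> 0).
#' @param intercept Intensity units (per-patch background).
#' @param fit Optional underlying `lm` fit.
#' @return A `calibration_model`.
#' @export
calibration_model <- function(slope = 39, intercept = 331, fit = NULL) {
  if (!is.numeric(slope) || slope <= 0) abort("calibration slope must be > 0")
  structure(list(slope = slope, intercept = intercept, fit = fit),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> intensity = %.4g * cells + %.4g\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Fit the calibration line by ordinary least squares
#'
#' Regresses total patch intensity on counted cells.
#'
#' @param data Data frame with columns `cells` and `total_intensity`
#'   (>= 2 distinct cell counts).
#' @return A [calibration_model()] carrying the `lm` fit.
#' @export
fit_calibration <- function(data) {
  stopifnot(all(c("cells", "total_intensity") %in% names(data)))
  if (length(unique(data$cells)) < 2)
    abort("calibration needs at least 2 distinct cell counts (design is rank-deficient)")
  fit <- lm(total_intensity ~ cells, data = data)
  calibration_model(slope = unname(coef(fit)[2]),
                    intercept = unname(coef(fit)[1]), fit = fit)
}

#' Predicted total intensity for a cell count
#' @param cal A [calibration_model()].
#' @param cells Cell count(s).
#' @return Total intensity (intensity units).
#' @export
predict_intensity <- function(cal, cells) cal$slope * cells + cal$intercept

#' Invert total patch intensity to a cell count
#'
#' `cells = max(0, (total_intensity - intercept) / slope)`; totals at or
#' below the intercept clamp to zero.
#'
#' @param total_intensity Total patch pixel intensity, `A_i * I_i` in pixel
#'   units (i.e. mean intensity times pixel count).
#' @param cal A [calibration_model()].
#' @return Non-negative cell count(s).
#' @export
intensity_to_cells <- function(total_intensity, cal) {
  if (cal$slope <= 0) abort("calibration slope must be > 0")
  pmax(0, (total_intensity - cal$intercept) / cal$slope)
}

#' Attach calibrated cell counts to a patch table
#'
#' @param patches Patch tibble with `total_intensity`.
#' @param cal A [calibration_model()].
#' @return The tibble with a `cells_est` column.
#' @export
add_cell_counts <- function(patches, cal) {
  mutate(patches, cells_est = intensity_to_cells(.data$total_intensity, cal))
}

#' @exportS3Method generics::tidy
tidy.calibration_model <- function(x, ...) {
  if (!is.null(x$fit)) {
    # summary.lm warns on an exactly collinear (zero-residual) fit; a
    # perfect calibration line is legitimate here
    s <- suppressWarnings(summary(x$fit))$coefficients
    tibble(term = c("intercept", "slope"), estimate = unname(s[, 1]),
           std.error = unname(s[, 2]), statistic = unname(s[, 3]),
           p.value = unname(s[, 4]))
  } else {
    tibble(term = c("intercept", "slope"),
           estimate = c(x$intercept, x$slope),
           std.error = NA_real_, statistic = NA_real_, p.value = NA_real_)
  }
}

#' @exportS3Method generics::glance
glance.calibration_model <- function(x, ...) {
  if (!is.null(x$fit)) {
    s <- suppressWarnings(summary(x$fit))
    tibble(n = length(s$residuals), r.squared = s$r.squared,
           sigma = s$sigma, slope = x$slope, intercept = x$intercept)
  } else {
    tibble(n = NA_integer_, r.squared = NA_real_, sigma = NA_real_,
           slope = x$slope, intercept = x$intercept)
  }
}
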