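#' Plot a density field
#'
#' One-dimensional fields are drawn as density curves; two-dimensional
#' fields as raster heat maps of `p_tilde` (or `rho` when present and
#' `value = "rho"`).
#'
#' @param object A `density_field`.
#' @param value Column to map: `"p_tilde"` or `"rho"`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.density_field <- function(object, value = "p_tilde", ...) {
  covs <- attr(object, "covariates")
  flag <- attr(object, "flag") %||% "model"
  lab_v <- if (value == "rho") "cells" else "probability density"
  if (length(covs) == 1) {
    ggplot(object, aes(x = .data[[covs[1]]], y = .data[[value]])) +
      geom_line() +
      labs(x = sprintf("%s (um)", covs[1]), y = lab_v,
           title = sprintf("%s field", flag)) +
      theme_minimal()
  } else {
    ggplot(object, aes(x = .data[[covs[1]]], y = .data[[covs[2]]],
                       fill = .data[[value]])) +
      geom_raster() +
      scale_fill_viridis_c() +
      labs(x = sprintf("%s (um)", covs[1]), y = sprintf("%s (um)", covs[2]),
           fill = lab_v, title = sprintf("%s field", flag)) +
      theme_minimal()
  }
}

#' Plot a cell-density profile along the root
#'
#' @param object A `density_profile` (possibly several bound together).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.density_profile <- function(object, ...) {
  autoplot_profile_df(object)
}

autoplot_profile_df <- function(df) {
  p <- ggplot(df, aes(x = .data$da_mid_mm, y = .data$cfu_per_mm)) +
    geom_col(width = df$bin_width_mm[1] * 0.9) +
    labs(x = "distance from root tip (mm)",
         y = expression(CFU ~ mm^-1)) +
    theme_minimal()
  if (length(unique(df$timepoint_h[!is.na(df$timepoint_h)])) > 1 &&
      length(unique(df$class)) > 1)
    p + facet_grid(class ~ timepoint_h)
  else if (length(unique(df$timepoint_h[!is.na(df$timepoint_h)])) > 1)
    p + facet_wrap(~timepoint_h)
  else p
}

#' Stacked-bar chart of colonization states per timepoint
#'
#' @param summary Output of [colonization_summary()].
#' @return A ggplot.
#' @export
plot_colonization <- function(summary) {
  ggplot(summary, aes(x = factor(.data$timepoint_h), y = .data$percent,
                      fill = .data$state)) +
    geom_col() +
    labs(x = "time post-inoculation (h)", y = "% of roots", fill = NULL) +
    theme_minimal()
}

#' @exportS3Method generics::tidy
tidy.density_field <- function(x, ...) {
  out <- as_tibble(as.data.frame(x))
  out$flag <- attr(x, "flag") %||% NA_character_
  out
}

#' Estimator metadata of a density field
#'
#' @param x A `density_field`.
#' @param ... Unused.
#' @return One-row tibble: patch count `N`, total fluorescence `M`, the
#'   field's Riemann-sum `integral` (1 minus boundary-truncation deficit),
#'   bandwidth floor, flag and, if present, `Q_bar` and `R`.
#' @exportS3Method generics::glance
glance.density_field <- function(x, ...) {
  tibble(N = attr(x, "N"), M = attr(x, "M"),
         integral = attr(x, "integral"),
         h_min_um = attr(x, "h_min_um"),
         flag = attr(x, "flag"),
         Q_bar = attr(x, "Q_bar") %||% NA_real_,
         R = attr(x, "R") %||% NA_real_)
}

#' @export
print.density_field <- function(x, ...) {
  g <- glance.density_field(x)
  cat(sprintf("<density_field (%s)> %s; N = %d patches, integral = %.4f\n",
              g$flag, paste(attr(x, "covariates"), collapse = " x "),
              g$N, g$integral))
  NextMethod()
}
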