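#' Colonization state of each root at each timepoint
#'
#' The state is a pure function of which bacterial classes are present:
#' `NONE` (no patches), `MOBILE_ONLY` (only MB), `BIOFILM_ONLY` (only
#' RB/PB), `MOBILE_AND_BIOFILM` otherwise.
#'
#' @param patches Patch tibble with `root_id`, `timepoint_h`, `class`.
#' @param manifest Optional tibble of all (root_id, timepoint_h)
#'   combinations observed, so roots without patches appear as `NONE`.
#' @return Tibble with `root_id`, `timepoint_h`, `state`.
#' @export
colonization_states <- function(patches, manifest = NULL) {
  base <- manifest %||%
    distinct(patches, .data$root_id, .data$timepoint_h)
  base <- distinct(base, .data$root_id, .data$timepoint_h)
  obs <- patches |>
    group_by(.data$root_id, .data$timepoint_h) |>
    summarise(state = classify_state(.data$class), .groups = "drop")
  base |>
    left_join(obs, by = c("root_id", "timepoint_h")) |>
    mutate(state = ifelse(is.na(.data$state), "NONE", .data$state)) |>
    arrange(.data$root_id, .data$timepoint_h)
}

classify_state <- function(classes) {
  mobile <- any(classes == "MB")
  biofilm <- any(classes %in% c("RB", "PB"))
  if (!mobile && !biofilm) "NONE"
  else if (mobile && !biofilm) "MOBILE_ONLY"
  else if (!mobile) "BIOFILM_ONLY"
  else "MOBILE_AND_BIOFILM"
}

#' Cohort-level colonization percentages per timepoint
#'
#' @param states Output of [colonization_states()].
#' @param collapse_biofilm_only Fold `BIOFILM_ONLY` into
#'   `MOBILE_AND_BIOFILM` (three-category presentation).
#' @return Tibble with `timepoint_h`, `state`, `n`, `percent`.
#' @export
colonization_summary <- function(states, collapse_biofilm_only = FALSE) {
  if (collapse_biofilm_only)
    states <- mutate(states, state = ifelse(.data$state == "BIOFILM_ONLY",
                                            "MOBILE_AND_BIOFILM", .data$state))
  states |>
    group_by(.data$timepoint_h, .data$state) |>
    summarise(n = n(), .groups = "drop_last") |>
    mutate(percent = 100 * .data$n / sum(.data$n)) |>
    ungroup()
}

#' Cell density profile along the root
#'
#' Bins calibrated cell counts of one class by distance from the root tip
#' and normalizes to colony-forming-unit-equivalents per mm of root:
#' `sum(cells in bin) / (bin width * R)`. Bins beyond every contributing
#' root's length are masked (`NA`).
#'
#' @param patches Patch tibble (needs `class`, `da_um`, `total_intensity`).
#' @param class Bacterial class (`"MB"`, `"RB"` or `"PB"`).
#' @param cal A [calibration_model()].
#' @param n_roots Number of roots `R`.
#' @param bin_width_mm Bin width in mm (> 0).
#' @param max_da_mm Profile extent; defaults to the largest patch `da`
#'   rounded up to a bin edge.
#' @param root_lengths_um Optional per-root lengths used to mask bins beyond
#'   every root.
#' @param timepoint Optional timepoint filter.
#' @return A `density_profile` tibble: `class`, `timepoint_h`, `da_mid_mm`,
#'   `cfu_per_mm`, `n_roots_in_bin`.
#' @export
density_profile <- function(patches, class, cal, n_roots, bin_width_mm = 0.5,
                            max_da_mm = NULL, root_lengths_um = NULL,
                            timepoint = NULL) {
  if (bin_width_mm <= 0) abort("bin width must be > 0")
  if (n_roots <= 0) abort("n_roots must be positive")
  sub <- patches[patches$class == class, ]
  if (!is.null(timepoint)) sub <- sub[sub$timepoint_h %in% timepoint, ]
  da_mm <- sub$da_um / 1000
  max_da_mm <- max_da_mm %||%
    (if (nrow(sub)) bin_width_mm * ceiling(max(da_mm) / bin_width_mm + 1e-9)
     else bin_width_mm)
  edges <- seq(0, max_da_mm, by = bin_width_mm)
  if (max(edges) < max_da_mm) edges <- c(edges, max(edges) + bin_width_mm)
  cells <- intensity_to_cells(sub$total_intensity, cal)
  bin <- pmin(findInterval(da_mm, edges, rightmost.closed = TRUE),
              length(edges) - 1)
  total <- rep(0, length(edges) - 1)
  nroots_bin <- rep(0L, length(edges) - 1)
  if (nrow(sub)) {
    agg <- tapply(cells, bin, sum)
    total[as.integer(names(agg))] <- as.numeric(agg)
    nr <- tapply(sub$root_id, bin, function(r) length(unique(r)))
    nroots_bin[as.integer(names(nr))] <- as.integer(nr)
  }
  value <- total / (bin_width_mm * n_roots)
  mids <- (head(edges, -1) + edges[-1]) / 2
  if (!is.null(root_lengths_um)) {
    reach <- max(root_lengths_um) / 1000
    value[head(edges, -1) >= reach] <- NA_real_
  }
  structure(tibble(class = class,
                   timepoint_h = if (!is.null(timepoint)) timepoint[1]
                   else NA_real_,
                   da_mid_mm = mids, cfu_per_mm = value,
                   n_roots_in_bin = nroots_bin,
                   bin_width_mm = bin_width_mm),
            class = c("density_profile", class(tibble())),
            n_roots = n_roots)
}

#' Minimum biofilm-to-tip distance per root and timepoint
#'
#' For each (root, timepoint), the minimum distance from the root tip among
#' root-biofilm (RB) patches; roots without RB at that time are excluded.
#'
#' @param patches Patch tibble.
#' @return Tibble with `root_id`, `timepoint_h`, `min_da_um`.
#' @export
min_biofilm_tip_distance <- function(patches) {
  sub <- patches[patches$class == "RB", ]
  if (nrow(sub) == 0)
    return(tibble(root_id = integer(0), timepoint_h = numeric(0),
                  min_da_um = numeric(0)))
  sub |>
    group_by(.data$root_id, .data$timepoint_h) |>
    summarise(min_da_um = min(.data$da_um), .groups = "drop")
}

#' Cohort summary of biofilm-to-tip distances
#' @param tip_distances Output of [min_biofilm_tip_distance()].
#' @return Tibble with `n`, `mean_um`, `sd_um`.
#' @export
tip_distance_summary <- function(tip_distances) {
  tibble(n = nrow(tip_distances),
         mean_um = mean(tip_distances$min_da_um),
         sd_um = sd(tip_distances$min_da_um))
}

#' Compare biofilm-to-tip distances at the last timepoint against earlier ones
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test of the reference
#' timepoint's per-root minimum distances against all earlier timepoints
#' pooled. The exact null distribution is used when both groups have at most
#' 20 observations and there are no ties; otherwise the normal approximation
#' with continuity correction.
#'
#' @param tip_distances Output of [min_biofilm_tip_distance()], or a data
#'   frame with `timepoint_h` and `min_da_um`.
#' @param ref_timepoint Timepoint forming the first group (default the
#'   largest present).
#' @param method `"mann-whitney"` (default) or `"welch"` (Welch's t-test).
#' @return List with `statistic` (U for Mann-Whitney), `n_ref`, `n_other`,
#'   `p_value`, `method`, `exact`.
#' @export
compare_tip_distance_groups <- function(tip_distances,
                                        ref_timepoint = NULL,
                                        method = c("mann-whitney", "welch")) {
  method <- match.arg(method)
  ref_timepoint <- ref_timepoint %||% max(tip_distances$timepoint_h)
  x <- tip_distances$min_da_um[tip_distances$timepoint_h == ref_timepoint]
  y <- tip_distances$min_da_um[tip_distances$timepoint_h != ref_timepoint]
  if (length(x) < 2 || length(y) < 2)
    abort("each group needs at least 2 observations")
  if (method == "welch") {
    ht <- stats::t.test(x, y)
    return(list(statistic = unname(ht$statistic), n_ref = length(x),
                n_other = length(y), p_value = ht$p.value,
                method = "welch", exact = FALSE))
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 20 && length(y) <= 20 && !ties
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), n_ref = length(x),
       n_other = length(y), p_value = ht$p.value,
       method = "mann-whitney", exact = exact)
}
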