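#' Run pipeline stages over a scene directory tree
#'
#' Single entry point wiring the stages into reproducible runs. Each command
#' reads only upstream artifacts and writes its stage's declared files; a
#' `manifest.json` in the output directory records the package version,
#' seed, a fingerprint of the configuration and the artifacts written.
#'
#' * `simulate`: generate the synthetic cohort under `out_dir` (one
#'   directory per scene: `root_<k>/t<hours>/tile_<j>/`).
#' * `segment`: read every scene directory under `in_dir`, write per-scene
#'   `patches.csv` and a combined `patches.csv` at the top level.
#' * `density`: read the combined `patches.csv`, write per-class density
#'   fields `density_<class>_<covariates>_t<t>.csv` (+ JSON sidecars) and
#'   their shared null model `density_null_<covariates>.csv`.
#' * `metrics`: read `patches.csv` (and `calibration.csv` if present, else
#'   the bundled default line), write `states.csv`, `profiles_<class>.csv`,
#'   `tip_distances.csv` and `tests.json`.
#' * `report`: aggregate stage outputs into `report/` summary tables and
#'   figures.
#'
#' @param command One of `"simulate"`, `"segment"`, `"density"`,
#'   `"metrics"`, `"report"`.
#' @param config A [scene_config()] (used by `simulate`; carried for grid
#'   and calibration defaults elsewhere).
#' @param in_dir Input directory (the previous stage's output).
#' @param out_dir Output directory (defaults to `in_dir`).
#' @param seed Integer seed recorded in the manifest and used by `simulate`.
#' @param covariates Covariate axes for the density stage.
#' @param calibration Optional [calibration_model()]; `metrics` otherwise
#'   reads `calibration.csv` from `in_dir` or falls back to the default.
#' @return Invisible list of artifact paths written.
#' @export
run_pipeline <- function(command = c("simulate", "segment", "density",
                                     "metrics", "report"),
                         config = scene_config(), in_dir = NULL,
                         out_dir = NULL, seed = 1L,
                         covariates = c("dp", "dr"), calibration = NULL) {
  command <- match.arg(command)
  out_dir <- out_dir %||% in_dir
  if (is.null(out_dir)) abort("out_dir (or in_dir) is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- switch(command,
    simulate = stage_simulate(config, out_dir, seed),
    segment = stage_segment(in_dir, out_dir),
    density = stage_density(in_dir, out_dir, config, covariates),
    metrics = stage_metrics(in_dir, out_dir, config, calibration),
    report = stage_report(in_dir, out_dir))
  manifest <- list(
    package = "rhizokde",
    version = as.character(utils::packageVersion("rhizokde")),
    command = command, seed = seed,
    config_hash = string_hash(jsonlite::toJSON(unclass(config),
                                               auto_unbox = TRUE,
                                               force = TRUE, digits = NA)),
    artifacts = written, time = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest,
                       file.path(out_dir, sprintf("manifest_%s.json", command)),
                       auto_unbox = TRUE, digits = NA)
  invisible(written)
}

stage_simulate <- function(config, out_dir, seed) {
  manifest <- cohort_manifest(config, seed)
  paths <- character(0)
  for (i in seq_len(nrow(manifest))) {
    sc <- simulate_scene(config, seed, root_id = manifest$root_id[i],
                         timepoint_h = manifest$timepoint_h[i],
                         tile_id = manifest$tile_id[i])
    paths <- c(paths, write_scene(sc, out_dir))
  }
  paths
}

scene_dirs <- function(dir) {
  d <- list.dirs(dir, recursive = TRUE)
  d[grepl("root_[0-9]+/t[0-9.]+/tile_[0-9]+$", d)]
}

stage_segment <- function(in_dir, out_dir) {
  if (is.null(in_dir)) abort("segment needs in_dir")
  dirs <- scene_dirs(in_dir)
  if (length(dirs) == 0) abort(sprintf("no scene directories under %s", in_dir))
  all_p <- list()
  paths <- character(0)
  for (sdir in dirs) {
    sc <- read_scene(sdir)
    p <- segment_scene(sc, background_subtract = sc$config$background_level)
    rel <- file.path(out_dir, substring(sdir, nchar(in_dir) + 2))
    dir.create(rel, recursive = TRUE, showWarnings = FALSE)
    paths <- c(paths, write_patches(p, file.path(rel, "patches.csv")))
    all_p[[sdir]] <- p
  }
  combined <- file.path(out_dir, "patches.csv")
  write_patches(bind_rows(all_p), combined)
  c(paths, combined)
}

stage_density <- function(in_dir, out_dir, config, covariates) {
  patches <- read_patches(file.path(in_dir, "patches.csv"))
  grid <- density_grid(covariates)
  paths <- character(0)
  cal <- calibration_model(config$calibration_slope,
                           config$calibration_intercept)
  n_roots <- length(unique(patches$root_id))
  for (cls in intersect(BACTERIA_CLASSES, unique(patches$class))) {
    sub <- patches[patches$class == cls, ]
    fields <- temporal_density(sub, covariates, grid,
                               h_min_um = config$pixel_size_um)
    for (t in names(fields)) {
      f <- fields[[t]]
      if (attr(f, "flag") != "empty")
        f <- mean_cell_density(f, sub[sub$timepoint_h == as.numeric(t), ],
                               cal, n_roots)
      p <- file.path(out_dir, sprintf("density_%s_%s_t%s.csv", cls,
                                      paste(covariates, collapse = "-"), t))
      paths <- c(paths, write_density_field(f, p))
    }
  }
  # null model from the first scene's pore space (all scenes share the
  # generator's support statistics); falls back silently if no scene dirs
  dirs <- scene_dirs(in_dir)
  if (length(dirs) > 0) {
    sc <- read_scene(dirs[1])
    lab <- overlay_root(argmax_classify(sc$probstack), sc$geometry,
                        sc$config$pixel_size_um)
    nf <- null_model(lab, sc$geometry, sc$config$pixel_size_um,
                     covariates = covariates, grid = grid, subsample = 0.25)
    p <- file.path(out_dir, sprintf("density_null_%s.csv",
                                    paste(covariates, collapse = "-")))
    paths <- c(paths, write_density_field(nf, p))
  }
  paths
}

stage_metrics <- function(in_dir, out_dir, config, calibration = NULL) {
  patches <- read_patches(file.path(in_dir, "patches.csv"))
  cal_file <- file.path(in_dir, "calibration.csv")
  cal <- calibration %||%
    (if (file.exists(cal_file)) fit_calibration(read.csv(cal_file))
     else calibration_model(config$calibration_slope,
                            config$calibration_intercept))
  n_roots <- length(unique(patches$root_id))
  paths <- character(0)
  states <- colonization_states(patches)
  p <- file.path(out_dir, "states.csv")
  write.csv(states, p, row.names = FALSE); paths <- c(paths, p)
  for (cls in intersect(BACTERIA_CLASSES, unique(patches$class))) {
    prof <- bind_rows(lapply(sort(unique(patches$timepoint_h)), function(t)
      density_profile(patches, cls, cal, n_roots, timepoint = t)))
    p <- file.path(out_dir, sprintf("profiles_%s.csv", cls))
    write.csv(prof, p, row.names = FALSE); paths <- c(paths, p)
  }
  tips <- min_biofilm_tip_distance(patches)
  p <- file.path(out_dir, "tip_distances.csv")
  write.csv(tips, p, row.names = FALSE); paths <- c(paths, p)
  tests <- list(tip_distance_summary = as.list(tip_distance_summary(tips)))
  grp <- table(tips$timepoint_h)
  if (length(grp) >= 2 && max(tips$timepoint_h) %in% names(grp) &&
      grp[as.character(max(tips$timepoint_h))] >= 2 &&
      sum(grp) - grp[as.character(max(tips$timepoint_h))] >= 2) {
    tests$tip_distance_test <- compare_tip_distance_groups(tips)
  }
  p <- file.path(out_dir, "tests.json")
  jsonlite::write_json(tests, p, auto_unbox = TRUE, digits = NA)
  c(paths, p)
}

stage_report <- function(in_dir, out_dir) {
  states <- read.csv(file.path(in_dir, "states.csv"))
  rep_dir <- file.path(out_dir, "report")
  dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
  summ <- colonization_summary(as_tibble(states))
  p1 <- file.path(rep_dir, "state_percentages.csv")
  write.csv(summ, p1, row.names = FALSE)
  paths <- p1
  pl <- plot_colonization(summ)
  p2 <- file.path(rep_dir, "state_percentages.png")
  try(ggplot2::ggsave(p2, pl, width = 6, height = 4, dpi = 150), silent = TRUE)
  if (file.exists(p2)) paths <- c(paths, p2)
  prof_files <- list.files(in_dir, pattern = "^profiles_.*\\.csv$",
                           full.names = TRUE)
  if (length(prof_files)) {
    prof <- bind_rows(lapply(prof_files, read.csv))
    pl2 <- autoplot_profile_df(as_tibble(prof))
    p3 <- file.path(rep_dir, "profiles.png")
    try(ggplot2::ggsave(p3, pl2, width = 7, height = 5, dpi = 150),
        silent = TRUE)
    if (file.exists(p3)) paths <- c(paths, p3)
  }
  paths
}
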