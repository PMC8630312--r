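#' Default run configuration
#'
#' Nested parameter list mirroring the module structure. Any subset can be
#' overridden via `overrides` (or a JSON config file through the command
#' line); unknown keys are rejected to catch typos.
#'
#' @param overrides Named nested list of overrides.
#' @return Configuration list.
#' @export
default_config <- function(overrides = list()) {
  cfg <- list(
    pixel_size_um = 0.5,
    frame_interval_min = 10,
    seed = 1,
    preprocess = list(gaussian_px = 2, clahe_tiles = c(8, 8),
                      clahe_clip = 0.01, use_clahe = TRUE),
    register = list(pyramid_levels = 3, mi_bins = 50, max_samples = 60000,
                    block_px = 32, search_px = 8, grid_step = 8,
                    corr_threshold = 0.5),
    segment = list(min_area_um2 = 30, max_area_um2 = 1500,
                   min_solidity = 0.8, max_eccentricity = 0.95,
                   border_exclusion = TRUE, min_seed_px = 9),
    piv = list(window = c(96, 48), overlap = 0.5, snr_min = 1.3,
               frames_per_hour = 6),
    myosin = list(band_um = 1.5, threshold = 1.5))
  merge_config(cfg, overrides)
}

merge_config <- function(base, over, path = "") {
  for (nm in names(over)) {
    if (!nm %in% names(base))
      stop("unknown config key: ", paste0(path, nm))
    if (is.list(base[[nm]]) && is.list(over[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], over[[nm]], paste0(path, nm, "."))
    else base[[nm]] <- over[[nm]]
  }
  base
}

seg_params_from_config <- function(cfg) {
  s <- cfg$segment
  segmentation_params(s$min_area_um2, s$max_area_um2, s$min_solidity,
                      s$max_eccentricity, s$border_exclusion, s$min_seed_px)
}

as_input_image <- function(x, cfg, with_dt = FALSE) {
  if (is_raster_image(x)) return(x)
  load_image(x, cfg$pixel_size_um,
             if (with_dt) cfg$frame_interval_min else NULL)
}

#' Run the full per-cell strain pipeline on a before/after pair
#'
#' Preprocesses the pair identically, registers the deformed image onto the
#' reference (affine, mutual information), segments cells on the reference
#' frame, refines the registration into a dense displacement field, fits a
#' per-cell strain tensor, computes shape metrics in both frames (the
#' deformed-frame masks come from mapping the reference masks through the
#' recovered transform) and their percent changes, and optionally writes
#' the per-cell CSV, strain-map overlays, and a summary + metadata JSON.
#'
#' @param reference,deformed [raster_image()] objects or TIFF paths.
#' @param config Configuration from [default_config()].
#' @param out_dir Output directory (created); `NULL` for no files.
#' @return List with `records` (per-cell data frame), `transform`,
#'   `metric`, `global_strain`, `shape` (from [shape_change()]),
#'   `labels`, `excluded`, and `summary` (named list of scalars).
#' @export
run_strain <- function(reference, deformed, config = default_config(),
                       out_dir = NULL) {
  reference <- as_input_image(reference, config)
  deformed <- as_input_image(deformed, config)
  if (reference$pixel_size_um != deformed$pixel_size_um)
    stop("stage preprocess: pixel sizes differ between the pair")
  pp <- config$preprocess
  pair <- preprocess_pair(reference, deformed, pp$gaussian_px,
                          pp$clahe_tiles, pp$clahe_clip, pp$use_clahe)

  rg <- config$register
  reg <- register_affine(pair$reference, pair$deformed,
                         pyramid_levels = rg$pyramid_levels,
                         mi_bins = rg$mi_bins, max_samples = rg$max_samples)
  global_strain <- affine_to_strain(reg$transform)

  lmap_all <- segment_cells(pair$reference, seg_params_from_config(config))
  filt <- filter_cells(lmap_all, seg_params_from_config(config),
                       reference$pixel_size_um)
  lmap <- filt$labels
  if (max(lmap) == 0L) stop("stage segment: no cells retained")

  field <- dense_displacement(pair$reference, pair$deformed, reg$transform,
                              block_px = rg$block_px,
                              search_px = rg$search_px,
                              grid_step = rg$grid_step,
                              corr_threshold = rg$corr_threshold)
  strains <- per_cell_strain(field, lmap)

  shapes_before <- shape_metrics(lmap, reference$pixel_size_um)
  lmap_after <- map_labels(lmap, reg$transform, expand = TRUE)
  shapes_after <- shape_metrics(lmap_after, reference$pixel_size_um)
  shp <- shape_change(shapes_before, shapes_after)

  records <- merge(shapes_before, strains, by = "cell_id", all.x = TRUE)
  records$included_flag <- records$included_flag %in% TRUE
  inc <- records$included_flag
  summary <- list(
    n_cells = nrow(records),
    n_included = sum(inc),
    n_excluded_filter = length(filt$excluded_ids),
    mean_e_xx = mean(records$e_xx[inc]),
    sd_e_xx = stats::sd(records$e_xx[inc]),
    mean_e_yy = mean(records$e_yy[inc]),
    mean_e_xy = mean(records$e_xy[inc]),
    mean_abs_e_yy = mean(abs(records$e_yy[inc])),
    mean_abs_e_xy = mean(abs(records$e_xy[inc])),
    global_e_xx = global_strain$e_xx,
    global_e_yy = global_strain$e_yy,
    global_e_xy = global_strain$e_xy,
    registration_mi = reg$metric,
    mean_area_change_pct =
      shp$summary$mean_pct[shp$summary$metric == "area"],
    mean_perimeter_change_pct =
      shp$summary$mean_pct[shp$summary$metric == "perimeter"],
    mean_eccentricity_change_pct =
      shp$summary$mean_pct[shp$summary$metric == "eccentricity"],
    n_invalid_vectors = sum(!field$valid))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cell_table(records, file.path(out_dir, "cells.csv"))
    for (comp in c("e_xx", "e_yy", "e_xy"))
      plot_strain_map(lmap, records, comp,
                      file.path(out_dir, paste0("strain_map_", comp, ".png")),
                      excluded_labels = filt$excluded_labels)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_run_metadata(file.path(out_dir, "run_metadata.json"), config,
                       config$seed)
  }
  list(records = records, transform = reg$transform, metric = reg$metric,
       global_strain = global_strain, shape = shp, labels = lmap,
       excluded = filt, field = field, summary = summary)
}

#' Run the collective-kinetics (PIV) pipeline on a time-lapse
#'
#' PIV over consecutive frame pairs, hourly mean-speed aggregation, and
#' baseline normalization to the first hour.
#'
#' @param frames List of [raster_image()] frames (or a multi-page TIFF
#'   path) in temporal order; at least `frames_per_hour + 1` frames.
#' @param config Configuration from [default_config()].
#' @param out_dir Output directory or `NULL`.
#' @return List with `fields`, `series` (normalized `speed_series`).
#' @export
run_kinetics <- function(frames, config = default_config(), out_dir = NULL) {
  if (is.character(frames)) frames <- as_input_image(frames, config, TRUE)
  if (is_raster_image(frames) || length(frames) < 2L)
    stop("stage piv: a time-lapse of at least 2 frames is required")
  if (length(frames) < config$piv$frames_per_hour + 1L)
    stop("stage piv: need at least one full hour of frames")
  pv <- config$piv
  fields <- lapply(seq_len(length(frames) - 1L), function(k) {
    piv_pair(frames[[k]], frames[[k + 1L]], window = pv$window,
             overlap_fraction = pv$overlap, snr_min = pv$snr_min)
  })
  series <- mean_speed_per_hour(fields, pv$frames_per_hour)
  series <- normalize_speeds(series)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(series, file.path(out_dir, "hourly_speeds.csv"),
                     row.names = FALSE)
    write_run_metadata(file.path(out_dir, "run_metadata.json"), config,
                       config$seed)
  }
  list(fields = fields, series = series)
}

#' Run the cortical-marker classification pipeline
#'
#' Segments cells (or uses supplied labels), computes the per-cell
#' cortical enrichment index, and summarises the fraction of cortical
#' cells.
#'
#' @param image [raster_image()] or TIFF path of the cortical marker.
#' @param config Configuration from [default_config()].
#' @param labels Optional precomputed label matrix.
#' @param out_dir Output directory or `NULL`.
#' @return List with `results` (per-cell data frame), `fraction` (from
#'   [fraction_cortical()]), `labels`.
#' @export
run_myosin <- function(image, config = default_config(), labels = NULL,
                       out_dir = NULL) {
  image <- as_input_image(image, config)
  if (is.null(labels)) {
    labels <- segment_cells(image, seg_params_from_config(config))
  }
  if (max(labels) == 0L) stop("stage myosin: empty label map")
  res <- cortical_index(image, labels, config$myosin$band_um)
  frac <- fraction_cortical(res, config$myosin$threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    res_out <- res
    res_out$is_cortical <- res$defined &
      res$cortical_index >= config$myosin$threshold
    utils::write.csv(res_out, file.path(out_dir, "cortical_cells.csv"),
                     row.names = FALSE)
    jsonlite::write_json(frac, file.path(out_dir, "cortical_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_run_metadata(file.path(out_dir, "run_metadata.json"), config,
                       config$seed)
  }
  list(results = res, fraction = frac, labels = labels)
}

#' Emit a synthetic fixture directory
#'
#' Writes ground-truthed synthetic inputs (TIFF images plus truth CSV/JSON)
#' for each pipeline: a before/after stretch pair, a drifting time-lapse
#' movie, and a cortical-marker image.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param field_px Field size in pixels (default 256 for compact fixtures).
#' @param e_xx Imposed uniform stretch for the pair (default 0.15).
#' @param speeds_um_per_h Speed schedule for the movie.
#' @param fraction_cortical,enrichment_ratio Cortical fixture parameters.
#' @return `out_dir`, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1, field_px = 256, e_xx = 0.15,
                          speeds_um_per_h = c(12, 9.6, 9.6, 12),
                          fraction_cortical = 0.4, enrichment_ratio = 2) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- monolayer_spec(field_px = field_px, seed = seed)
  mono <- generate_monolayer(spec)
  def <- apply_deformation(mono$image, mono$labels,
                           deformation_spec("uniform", e_xx = e_xx))
  save_image(list(quantize16(mono$image), quantize16(def$image)),
             file.path(out_dir, "stretch_pair.tif"))
  utils::write.csv(def$truth, file.path(out_dir, "stretch_truth.csv"),
                   row.names = FALSE)

  tl <- generate_timelapse(spec, speeds_um_per_h)
  save_image(lapply(tl$frames, quantize16),
             file.path(out_dir, "timelapse.tif"))
  utils::write.csv(tl$truth, file.path(out_dir, "timelapse_truth.csv"),
                   row.names = FALSE)

  cor <- generate_cortical(spec, fraction_cortical, enrichment_ratio)
  save_image(quantize16(cor$image), file.path(out_dir, "cortical.tif"))
  utils::write.csv(cor$truth, file.path(out_dir, "cortical_truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, field_px = field_px, e_xx = e_xx,
         speeds_um_per_h = speeds_um_per_h,
         fraction_cortical = fraction_cortical,
         enrichment_ratio = enrichment_ratio,
         pixel_size_um = spec$pixel_size_um),
    file.path(out_dir, "fixture_spec.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out_dir)
}

# Round to 16-bit range for TIFF export.
quantize16 <- function(img) {
  img$pixels <- pmin(pmax(round(img$pixels), 0), 65535)
  img
}
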