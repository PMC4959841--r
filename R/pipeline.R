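# End-to-end orchestration: an in-memory section-stack segmenter used by the
# file-based pipeline stages (simulate, segment, link, evaluate, roi), a
# validated YAML configuration, and per-stage provenance records.

#' Segment a stack of serial sections
#'
#' Runs the 2D portion of the pipeline on each section independently:
#' optional histogram equalization, clustering-based global threshold with
#' marker modulation, dark-foreground binarization, 8-connected component
#' extraction and the area/major-axis filters. Sections whose histogram is
#' degenerate (constant image) fall back to the fixed threshold
#' `cutoff * factor_low`. Afterwards segments receive volume-unique labels
#' and artifact pruning is applied.
#'
#' @param images Named list of intensity matrices on \[0, 1\].
#' @param z_index Integer 0-based section indices (gaps allowed).
#' @param voxel_nm Pixel pitch and section spacing, `c(x, y, z)` in nm.
#' @param threshold A [threshold_params()].
#' @param filter A [filter_params()].
#' @param link A [link_params()] (neighbourhood used by artifact pruning).
#' @param equalize Apply per-section histogram equalization first? Meant
#'   for acquisitions whose brightness varies across sections; sections
#'   generated or normalized on a common scale do not need it.
#' @return A list with `$table` (pruned [segment_table()]), `$label_stack`
#'   (named list of per-section global-segment-label matrices) and
#'   `$thresholds` (tibble: z_index, tau, tau_prime — the per-section
#'   applied thresholds).
#' @export
segment_stack <- function(images, z_index, voxel_nm,
                          threshold = threshold_params(),
                          filter = filter_params(),
                          link = link_params(),
                          equalize = FALSE) {
  stopifnot(length(images) == length(z_index))
  seg_list <- vector("list", length(images))
  lab_list <- vector("list", length(images))
  taus <- numeric(length(images)); taups <- numeric(length(images))
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (equalize) img <- equalize_histogram(img, threshold$n_bins)
    tau <- tryCatch(cluster_threshold(img, threshold),
                    error = function(e) NA_real_)
    if (is.na(tau)) {  # degenerate histogram: fixed fallback threshold
      tau <- threshold$cutoff
      taup <- threshold$cutoff * threshold$factor_low
    } else {
      taup <- modulate_threshold(tau, threshold)
    }
    mask <- binarize(img, taup)
    segs <- extract_segments(mask, img, z_index[i])
    lab <- attr(segs, "label_matrix")
    kept <- filter_segments(segs, filter)
    # restrict the label matrix to kept segments
    keep_ids <- kept$seg_id
    lut <- integer(max(lab, 1L))
    lut[keep_ids] <- keep_ids
    lab[lab > 0L] <- lut[lab[lab > 0L]]
    seg_list[[i]] <- kept
    lab_list[[i]] <- lab
    taus[i] <- tau; taups[i] <- taup
  }
  table <- segment_table(seg_list, voxel_nm, z_index,
                         shape = dim(images[[1]]),
                         params = list(threshold = unclass(threshold),
                                       filter = unclass(filter),
                                       equalize = equalize))
  # remap per-section component ids to volume-unique labels
  seg_map <- split(table$segments, table$segments$z_index)
  for (i in seq_along(lab_list)) {
    sz <- seg_map[[as.character(z_index[i])]]
    out <- matrix(0L, nrow(lab_list[[i]]), ncol(lab_list[[i]]))
    if (!is.null(sz) && nrow(sz) > 0L) {
      lut <- integer(max(sz$seg_id))
      lut[sz$seg_id] <- sz$label
      pos <- lab_list[[i]] > 0L
      out[pos] <- lut[lab_list[[i]][pos]]
    }
    lab_list[[i]] <- out
  }
  names(lab_list) <- names(images)
  table <- prune_artifacts(table, filter, link)
  list(table = table,
       label_stack = lab_list,
       thresholds = tibble(z_index = as.integer(z_index),
                           tau = taus, tau_prime = taups))
}

#' Reconstruct a segmented stack in 3D
#'
#' Convenience wrapper chaining [build_link_graph()], [bridge_gaps()] and
#' [merge_components()].
#'
#' @param table A [segment_table()].
#' @param link A [link_params()].
#' @param min_overlap Same-section overlap fraction for the final
#'   consistency merge.
#' @return An `em_reconstruction`.
#' @export
reconstruct_stack <- function(table, link = link_params(), min_overlap = 0.5) {
  graph <- build_link_graph(table, link)
  graph <- bridge_gaps(graph, table, link)
  merge_components(graph, table, min_overlap = min_overlap)
}

# ---- configuration ---------------------------------------------------------

default_config <- function() {
  list(
    seed = 1L,
    voxel = list(x_nm = 20, y_nm = 20, z_nm = 30),
    io = list(workdir = "emtracer_run"),
    phantom = unclass(phantom_spec())[
      c("n_sections", "section_shape", "n_processes", "tube_radius_px",
        "stained_intensity", "background_intensity",
        "background_texture_scale", "noise_sd", "n_distractors",
        "distractor_radius_px", "dropout_sections", "jitter_px")],
    threshold = list(cutoff = 0.6, factor_low = 0.82, factor_high = 0.86,
                     n_bins = 256L, equalize = FALSE),
    filter = list(min_area = 3, max_area = 130000, max_major_axis = 900,
                  prune_area_ratio = 10),
    link = list(k = 2L, radius_nm = 2000, max_gap_sections = 3L,
                max_distance_nm = 2000),
    eval = list(min_overlap = 0.5)
  )
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) {
      abort(sprintf("unknown configuration key `%s`", full))
    }
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Pipeline configuration
#'
#' Loads a YAML configuration (or an in-memory list) over the package
#' defaults, rejecting unknown keys and validating parameter constraints
#' before any computation runs. Every printed pipeline parameter keeps its
#' stated default: threshold cutoff 0.6 with modulation factors 0.82/0.86,
#' segment filters 3/130000 px area and 900 px major axis, linking k = 2.
#'
#' @param config Path to a YAML file, a named list of overrides, or `NULL`
#'   for the defaults.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = NULL) {
  cfg <- default_config()
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("no config file at `%s`", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.null(config)) cfg <- merge_config(cfg, config)
  # validation before any stage runs
  thr <- threshold_params(cfg$threshold$cutoff, cfg$threshold$factor_low,
                          cfg$threshold$factor_high, cfg$threshold$n_bins)
  flt <- filter_params(cfg$filter$min_area, cfg$filter$max_area,
                       cfg$filter$max_major_axis, cfg$filter$prune_area_ratio)
  lnk <- link_params(cfg$link$k, cfg$link$radius_nm,
                     cfg$link$max_gap_sections, cfg$link$max_distance_nm)
  check_scalar(cfg$eval$min_overlap, "eval.min_overlap", 0, 1,
               strict_lower = TRUE)
  if (any(unlist(cfg$voxel) <= 0)) abort("voxel pitches must be positive")
  cfg$threshold_params <- thr
  cfg$filter_params <- flt
  cfg$link_params <- lnk
  structure(cfg, class = "pipeline_config")
}

as_pipeline_config <- function(config) {
  if (inherits(config, "pipeline_config")) config else pipeline_config(config)
}

config_voxel <- function(cfg) {
  c(x = cfg$voxel$x_nm, y = cfg$voxel$y_nm, z = cfg$voxel$z_nm)
}

write_provenance <- function(dir, stage, cfg, inputs = character(0)) {
  prov <- list(
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("emtracer")),
    seed = cfg$seed,
    parameters = unclass(cfg)[setdiff(names(cfg), c("threshold_params",
                                                    "filter_params",
                                                    "link_params"))],
    input_checksums = as.list(vapply(inputs, function(f) {
      unname(tools::md5sum(f))
    }, character(1))))
  yaml::write_yaml(prov, file.path(dir, sprintf("provenance_%s.yaml", stage)))
}

# ---- file-based stages -----------------------------------------------------

#' Pipeline stages
#'
#' File-based stages chaining the whole pipeline under one configuration:
#' `run_simulate()` writes a phantom volume, `run_segment()` segments the
#' sections into a labeled table, `run_link()` reconstructs in 3D,
#' `run_evaluate()` scores against the phantom ground truth, and
#' `run_roi()` proposes re-imaging boxes. Each stage writes its outputs
#' plus a provenance record (parameter snapshot, input checksums, package
#' version, seed) under the configured working directory and is
#' deterministic given identical inputs and configuration.
#'
#' @param config A [pipeline_config()], or anything it accepts.
#' @return Each stage invisibly returns its primary in-memory result.
#' @name pipeline-stages
NULL

#' @rdname pipeline-stages
#' @export
run_simulate <- function(config = NULL) {
  cfg <- as_pipeline_config(config)
  dir.create(cfg$io$workdir, showWarnings = FALSE, recursive = TRUE)
  ph_dir <- file.path(cfg$io$workdir, "phantom")
  spec <- phantom_spec(
    n_sections = cfg$phantom$n_sections,
    section_shape = unlist(cfg$phantom$section_shape),
    voxel_nm = config_voxel(cfg),
    n_processes = cfg$phantom$n_processes,
    tube_radius_px = unlist(cfg$phantom$tube_radius_px),
    stained_intensity = unlist(cfg$phantom$stained_intensity),
    background_intensity = unlist(cfg$phantom$background_intensity),
    background_texture_scale = cfg$phantom$background_texture_scale,
    noise_sd = cfg$phantom$noise_sd,
    n_distractors = cfg$phantom$n_distractors,
    distractor_radius_px = unlist(cfg$phantom$distractor_radius_px),
    dropout_sections = unlist(cfg$phantom$dropout_sections),
    jitter_px = cfg$phantom$jitter_px,
    seed = cfg$seed)
  ph <- generate_phantom(spec)
  write_phantom(ph, ph_dir)
  write_provenance(cfg$io$workdir, "simulate", cfg)
  invisible(ph)
}

#' @rdname pipeline-stages
#' @export
run_segment <- function(config = NULL) {
  cfg <- as_pipeline_config(config)
  ph_dir <- file.path(cfg$io$workdir, "phantom")
  ph <- read_phantom(ph_dir)
  seg <- segment_stack(ph$images, ph$z_index, config_voxel(cfg),
                       threshold = cfg$threshold_params,
                       filter = cfg$filter_params,
                       link = cfg$link_params,
                       equalize = isTRUE(cfg$threshold$equalize))
  out <- file.path(cfg$io$workdir, "segments")
  write_segment_table(seg$table, out)
  tiff::writeTIFF(lapply(seg$label_stack, function(m) m / 65535),
                  file.path(cfg$io$workdir, "segment_labels.tif"),
                  bits.per.sample = 16L)
  write.csv(seg$thresholds, file.path(cfg$io$workdir, "thresholds.csv"),
            row.names = FALSE)
  write_provenance(cfg$io$workdir, "segment", cfg,
                   inputs = file.path(ph_dir, "sections.tif"))
  invisible(seg)
}

#' @rdname pipeline-stages
#' @export
run_link <- function(config = NULL) {
  cfg <- as_pipeline_config(config)
  table <- read_segment_table(file.path(cfg$io$workdir, "segments"))
  recon <- reconstruct_stack(table, cfg$link_params,
                             min_overlap = cfg$eval$min_overlap)
  labs <- read_label_tiff(file.path(cfg$io$workdir, "segment_labels.tif"),
                          table$meta$sections)
  export_reconstruction(recon, labs, file.path(cfg$io$workdir, "reconstruction"))
  write_provenance(cfg$io$workdir, "link", cfg,
                   inputs = file.path(cfg$io$workdir, "segments.csv"))
  invisible(recon)
}

#' @rdname pipeline-stages
#' @export
run_evaluate <- function(config = NULL) {
  cfg <- as_pipeline_config(config)
  table <- read_segment_table(file.path(cfg$io$workdir, "segments"))
  ph <- read_phantom(file.path(cfg$io$workdir, "phantom"))
  labs <- read_label_tiff(file.path(cfg$io$workdir, "segment_labels.tif"),
                          table$meta$sections)
  match <- match_segments(labs, ph$truth$label_stack,
                          min_overlap = cfg$eval$min_overlap)
  recon <- reconstruct_stack(table, cfg$link_params,
                             min_overlap = cfg$eval$min_overlap)
  report <- density_report(recon, labs, ph$truth$label_stack)
  out <- file.path(cfg$io$workdir, "evaluation")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write.csv(match$summary, file.path(out, "match_summary.csv"), row.names = FALSE)
  write.csv(match$per_truth, file.path(out, "match_per_truth.csv"), row.names = FALSE)
  write.csv(cbind(report$volume, report$errors),
            file.path(out, "reconstruction_report.csv"), row.names = FALSE)
  writeLines(c(
    sprintf("recall: %.4f (%d / %d truth segments matched)",
            match$summary$recall, match$summary$n_matched, match$summary$n_truth),
    sprintf("precision: %.4f", match$summary$precision),
    sprintf("components: %d; split errors: %d; merge errors: %d; spurious: %d",
            report$volume$n_components, report$errors$split_errors,
            report$errors$merge_errors, report$errors$spurious_components)),
    file.path(out, "report.txt"))
  write_provenance(cfg$io$workdir, "evaluate", cfg)
  invisible(list(match = match, report = report, recon = recon))
}

#' @rdname pipeline-stages
#' @export
run_roi <- function(config = NULL) {
  cfg <- as_pipeline_config(config)
  table <- read_segment_table(file.path(cfg$io$workdir, "segments"))
  recon <- reconstruct_stack(table, cfg$link_params,
                             min_overlap = cfg$eval$min_overlap)
  roi <- propose_roi(recon, selector = "all")
  out <- file.path(cfg$io$workdir, "roi")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write.csv(roi$boxes, file.path(out, "roi_boxes.csv"), row.names = FALSE)
  writeLines(sprintf("total %.4g um^3, roi %.4g um^3, reduction factor %.4g",
                     roi$total_volume_um3, roi$roi_volume_um3,
                     roi$reduction_factor),
             file.path(out, "roi.txt"))
  write_provenance(cfg$io$workdir, "roi", cfg)
  invisible(roi)
}

read_label_tiff <- function(path, sections) {
  labs <- lapply(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                 function(m) { storage.mode(m) <- "integer"; m })
  names(labs) <- sprintf("z%04d", sections)
  labs
}
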