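# Internal helpers shared across modules.

#' @importFrom rlang abort
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange bind_rows desc distinct filter group_by left_join
#'   mutate n rename row_number select slice summarise ungroup
#' @importFrom stats median rnorm runif sd setNames var
#' @importFrom utils head read.csv write.csv
NULL

# quiet R CMD check notes for NSE column names
utils::globalVariables(c(
  "area_px", "bbox_x_max", "bbox_x_min", "bbox_y_max", "bbox_y_min",
  "centroid_x", "centroid_y", "component", "dist_nm", "dz", "from", "label",
  "label_a", "label_b", "major_axis_px", "matched", "mean_intensity",
  "n_segments", "overlap_px", "process", "pruned_flag", "reason", "seg_id",
  "to", "total_area_px", "truth_area", "z", "z_index", "z_max", "z_min",
  "height_px", "width_px", "n_px", "x", "y", "tau", "tau_prime", "intensity",
  "radius_px", "n_components", "n_processes", "best_overlap", "side",
  "med_area", "both_sides", "nb", "rank", "min_label", "z_nm", "y_nm", "x_nm",
  "volume_um3", "y_min_nm", "y_max_nm", "x_min_nm", "x_max_nm", "nc", "np"
))

check_image <- function(img, arg = "image") {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L) {
    abort(sprintf("`%s` must be a nonempty numeric matrix", arg))
  }
  rng <- range(img)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1) {
    abort(sprintf("`%s` intensities must lie in [0, 1] with no NAs", arg))
  }
  invisible(img)
}

check_scalar <- function(x, arg, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict_lower) x > lower else x >= lower) &&
    (if (strict_upper) x < upper else x <= upper)
  if (!ok) {
    abort(sprintf("`%s` must be a scalar in %s%s, %s%s",
                  arg, if (strict_lower) "(" else "[", format(lower),
                  format(upper), if (strict_upper) ")" else "]"))
  }
  invisible(x)
}

# Bin index on [0, 1] into n_bins bins; the top edge belongs to the last bin.
intensity_bin <- function(v, n_bins) {
  pmin(floor(v * n_bins) + 1L, n_bins)
}

# Evaluate an expression under a seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Shift point coordinates by an integer per-section jitter, clamped to bounds.
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
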