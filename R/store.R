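# Durable, queryable table of labeled segments plus volume metadata.
# Backend: a CSV of rows plus a YAML meta sidecar; the contract is the
# lossless round trip, not the storage engine.

#' Assemble a segment table with volume-unique labels
#'
#' Stacks per-section segment tibbles and assigns each segment a unique
#' label: consecutive positive integers in (z_index, discovery order), so
#' identical input always yields identical labeling.
#'
#' @param segments Segment tibble(s) from [extract_segments()] (a single
#'   tibble covering any number of sections, or a list of them).
#' @param voxel_nm Pixel pitch and section spacing, `c(x, y, z)` in nm.
#' @param sections Integer 0-based indices of all imaged sections
#'   (including those with no segments; gaps in the indexing are preserved).
#' @param shape Section height and width in pixels.
#' @param params Optional named list snapshotting the parameters that
#'   produced the rows (stored verbatim in the metadata).
#' @return A `segment_table`: list with `$segments` (tibble, `label` first)
#'   and `$meta` (voxel geometry, section list, shape, parameter snapshot).
#' @export
segment_table <- function(segments, voxel_nm, sections, shape,
                          params = list()) {
  if (is.list(segments) && !is.data.frame(segments)) {
    segments <- bind_rows(segments)
  }
  if (length(voxel_nm) != 3L || any(voxel_nm <= 0))
    abort("`voxel_nm` must be three positive lengths c(x, y, z)")
  sections <- sort(unique(as.integer(sections)))
  if (nrow(segments) > 0L) {
    if (!all(segments$z_index %in% sections))
      abort("every segment z_index must appear in `sections`")
    segments <- arrange(segments, z_index, seg_id)
    segments <- mutate(segments, label = row_number(), .before = 1)
  } else {
    segments <- mutate(segments, label = integer(0), .before = 1)
  }
  structure(list(
    segments = segments,
    meta = list(voxel_nm = setNames(as.numeric(voxel_nm), c("x", "y", "z")),
                sections = sections,
                shape = as.integer(shape),
                params = params)
  ), class = "segment_table")
}

#' @export
print.segment_table <- function(x, ...) {
  cat(sprintf("<segment_table> %d segments over %d sections (%d pruned)\n",
              nrow(x$segments), length(x$meta$sections),
              sum(x$segments$pruned_flag)))
  print(x$segments, n = 5)
  invisible(x)
}

#' Persist / load a segment table
#'
#' `write_segment_table()` writes `<path>.csv` (rows, fixed column order)
#' and `<path>.yaml` (volume metadata and parameter snapshot);
#' `read_segment_table()` reproduces the table exactly. A missing or
#' truncated file raises an error rather than returning a partial table.
#'
#' @param table A [segment_table()].
#' @param path Base path (no extension).
#' @return `write_segment_table()`: the paths, invisibly.
#'   `read_segment_table()`: the restored `segment_table`.
#' @export
write_segment_table <- function(table, path) {
  stopifnot(inherits(table, "segment_table"))
  p_csv <- paste0(path, ".csv"); p_yml <- paste0(path, ".yaml")
  write.csv(table$segments, p_csv, row.names = FALSE)
  meta <- table$meta
  meta$voxel_nm <- as.list(meta$voxel_nm)
  yaml::write_yaml(meta, p_yml)
  invisible(c(p_csv, p_yml))
}

segment_columns <- c("label", "z_index", "seg_id", "area_px", "centroid_y",
                     "centroid_x", "major_axis_px", "bbox_y_min", "bbox_x_min",
                     "bbox_y_max", "bbox_x_max", "mean_intensity",
                     "pruned_flag", "reason")

#' @rdname write_segment_table
#' @export
read_segment_table <- function(path) {
  p_csv <- paste0(path, ".csv"); p_yml <- paste0(path, ".yaml")
  if (!file.exists(p_csv) || !file.exists(p_yml))
    abort(sprintf("no segment table at `%s`", path))
  rows <- tryCatch(suppressWarnings(read.csv(p_csv)),
                   error = function(e) abort(sprintf(
                     "corrupt segment table `%s`: %s", p_csv, conditionMessage(e))))
  if (!identical(names(rows), segment_columns))
    abort(sprintf("corrupt segment table `%s`: unexpected columns", p_csv))
  rows$reason <- as.character(rows$reason)
  rows$reason[rows$reason == "" | is.na(rows$reason)] <- NA_character_
  meta <- yaml::read_yaml(p_yml)
  meta$voxel_nm <- setNames(as.numeric(unlist(meta$voxel_nm)), c("x", "y", "z"))
  meta$sections <- as.integer(unlist(meta$sections))
  meta$shape <- as.integer(unlist(meta$shape))
  structure(list(segments = as_tibble(rows), meta = meta),
            class = "segment_table")
}

# All candidate cross-section pairs: z-offset in [1, max_gap] and in-plane
# centroid distance (nm) within radius. Returned once per unordered pair
# with label_a on the lower section. In-plane distance only: with 30-270 nm
# section spacing a z term would swamp in-plane proximity.
candidate_pairs <- function(segs, voxel_nm, radius_nm, max_gap) {
  if (nrow(segs) < 2L) {
    return(tibble(label_a = integer(), label_b = integer(),
                  dist_nm = numeric(), dz = integer()))
  }
  by_z <- split(segs, segs$z_index)
  zs <- as.integer(names(by_z))
  out <- list()
  for (i in seq_along(zs)) {
    for (j in seq_along(zs)) {
      gap <- zs[j] - zs[i]
      if (gap < 1L || gap > max_gap) next
      a <- by_z[[i]]; b <- by_z[[j]]
      dx <- outer(a$centroid_x, b$centroid_x, "-") * voxel_nm["x"]
      dy <- outer(a$centroid_y, b$centroid_y, "-") * voxel_nm["y"]
      d <- sqrt(dx^2 + dy^2)
      hit <- which(d <= radius_nm, arr.ind = TRUE)
      if (nrow(hit) > 0L) {
        out[[length(out) + 1L]] <- tibble(
          label_a = a$label[hit[, 1]], label_b = b$label[hit[, 2]],
          dist_nm = d[hit], dz = gap)
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(label_a = integer(), label_b = integer(),
                  dist_nm = numeric(), dz = integer()))
  }
  bind_rows(out)
}

#' Query the local neighbourhood of a segment
#'
#' Returns the segments on nearby sections whose centroid lies within
#' `radius_nm` of the query centroid, measured in physical in-plane
#' nanometres. `direction = "up"` restricts to sections with z-offset in
#' `[1, max_gap_sections]` (the linking direction); `"both"` (screening
#' mode, used by artifact pruning) also includes `[-max_gap_sections, -1]`.
#'
#' @param table A [segment_table()].
#' @param label Query segment label.
#' @param radius_nm Neighbourhood radius in nm.
#' @param max_gap_sections Maximum section-index offset.
#' @param direction `"up"` or `"both"`.
#' @return Tibble of candidate segments with `dist_nm` and `dz` columns.
#' @export
query_neighborhood <- function(table, label, radius_nm, max_gap_sections,
                               direction = c("up", "both")) {
  stopifnot(inherits(table, "segment_table"))
  direction <- match.arg(direction)
  segs <- table$segments
  q <- segs[segs$label == label, ]
  if (nrow(q) != 1L) abort(sprintf("unknown segment label %s", label))
  dz <- segs$z_index - q$z_index
  keep <- if (direction == "up") dz >= 1L & dz <= max_gap_sections
          else abs(dz) >= 1L & abs(dz) <= max_gap_sections
  cand <- segs[keep, ]
  if (nrow(cand) == 0L) return(mutate(cand, dist_nm = numeric(0), dz = integer(0)))
  v <- table$meta$voxel_nm
  d <- sqrt(((cand$centroid_x - q$centroid_x) * v["x"])^2 +
              ((cand$centroid_y - q$centroid_y) * v["y"])^2)
  cand <- mutate(cand, dist_nm = d, dz = cand$z_index - q$z_index)
  arrange(dplyr::filter(cand, dist_nm <= radius_nm), dist_nm, label)
}
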