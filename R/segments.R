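# 2D candidate segments: extraction from binary masks (8-connected
# components), geometric measurement from pixel moments, the printed
# area/major-axis filters, and artifact pruning by morphological progression.

#' Segment filter parameters
#'
#' Bounds on 2D candidate segments. All comparisons are strict, exactly as
#' the bounds are stated: a segment is kept iff
#' `min_area_px < area < max_area_px` and `major_axis_px < max_major_axis_px`.
#' The defaults (3 px < area < 130000 px, major axis < 900 px) remove
#' speckle noise at the low end and tissue holes / staining artifacts at the
#' high end.
#'
#' @param min_area_px,max_area_px Exclusive area bounds in pixels.
#' @param max_major_axis_px Exclusive bound on the moment-ellipse major axis.
#' @param prune_area_ratio A segment sandwiched between cross-section
#'   neighbours is pruned when its area exceeds this multiple of the median
#'   neighbour area (see [prune_artifacts()]).
#' @return A `filter_params` list.
#' @export
filter_params <- function(min_area_px = 3, max_area_px = 130000,
                          max_major_axis_px = 900, prune_area_ratio = 10) {
  check_scalar(min_area_px, "min_area_px", 0)
  check_scalar(max_area_px, "max_area_px", min_area_px, strict_lower = TRUE)
  check_scalar(max_major_axis_px, "max_major_axis_px", 0, strict_lower = TRUE)
  check_scalar(prune_area_ratio, "prune_area_ratio", 1, strict_lower = TRUE)
  structure(list(min_area_px = min_area_px, max_area_px = max_area_px,
                 max_major_axis_px = max_major_axis_px,
                 prune_area_ratio = prune_area_ratio),
            class = "filter_params")
}

# 8-connected integer labeling. EBImage::bwlabel is 4-connected; diagonal
# adjacencies between distinct 4-connected labels are merged with a label
# union, then labels are compacted in order of first pixel (column-major).
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab > 1L) {
    m <- nrow(lab); n <- ncol(lab)
    a1 <- lab[-m, -n]; b1 <- lab[-1, -1]   # down-right diagonal
    a2 <- lab[-1, -n]; b2 <- lab[-m, -1]   # up-right diagonal
    sel1 <- a1 > 0L & b1 > 0L & a1 != b1
    sel2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
    if (nrow(pairs) > 0L) {
      g <- igraph::graph_from_edgelist(matrix(as.character(pairs), ncol = 2),
                                       directed = FALSE)
      comp <- igraph::components(g)
      remap <- seq_len(nlab)
      ids <- as.integer(igraph::V(g)$name)
      # map every member to the smallest label of its 8-connected group
      for (cc in seq_len(comp$no)) {
        members <- ids[comp$membership == cc]
        remap[members] <- min(members)
      }
      lab[lab > 0L] <- remap[lab[lab > 0L]]
    }
  }
  # compact to 1..K in order of first occurrence (column-major scan)
  pos <- lab > 0L
  if (any(pos)) {
    u <- unique(lab[pos])
    remap2 <- integer(max(u))
    remap2[u] <- seq_along(u)
    lab[pos] <- remap2[lab[pos]]
  }
  lab
}

# Moment features for every labeled component, vectorized with rowsum().
# Coordinates use the 0-based pixel-center convention; the major axis is
# 4 * sqrt(largest eigenvalue of the pixel-coordinate covariance), with the
# covariance normalized by n (no +1/12 discrete-pixel correction).
component_features <- function(lab, img) {
  idx <- which(lab > 0L)
  if (length(idx) == 0L) {
    return(tibble(seg_id = integer(), area_px = integer(),
                  centroid_y = numeric(), centroid_x = numeric(),
                  major_axis_px = numeric(),
                  bbox_y_min = integer(), bbox_x_min = integer(),
                  bbox_y_max = integer(), bbox_x_max = integer(),
                  mean_intensity = numeric()))
  }
  l <- lab[idx]
  m <- nrow(lab)
  row0 <- (idx - 1L) %% m            # 0-based y
  col0 <- (idx - 1L) %/% m           # 0-based x
  ids <- sort(unique(l))
  area <- as.vector(rowsum(rep(1L, length(l)), l)[, 1])
  sy <- as.vector(rowsum(row0, l)[, 1]); sx <- as.vector(rowsum(col0, l)[, 1])
  cy <- sy / area; cx <- sx / area
  syy <- as.vector(rowsum(row0^2, l)[, 1]) / area - cy^2
  sxx <- as.vector(rowsum(col0^2, l)[, 1]) / area - cx^2
  sxy <- as.vector(rowsum(row0 * col0, l)[, 1]) / area - cy * cx
  lam <- (syy + sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / 2
  major <- 4 * sqrt(pmax(lam, 0))
  sp <- split(seq_along(l), l)
  bym <- vapply(sp, function(i) min(row0[i]), numeric(1))
  byM <- vapply(sp, function(i) max(row0[i]), numeric(1))
  bxm <- vapply(sp, function(i) min(col0[i]), numeric(1))
  bxM <- vapply(sp, function(i) max(col0[i]), numeric(1))
  mi <- as.vector(rowsum(img[idx], l)[, 1]) / area
  tibble(seg_id = ids, area_px = as.integer(area),
         centroid_y = cy, centroid_x = cx, major_axis_px = major,
         bbox_y_min = as.integer(bym), bbox_x_min = as.integer(bxm),
         bbox_y_max = as.integer(byM) + 1L, bbox_x_max = as.integer(bxM) + 1L,
         mean_intensity = mi)
}

#' Extract 2D candidate segments from a binary mask
#'
#' Decomposes the dark-foreground mask of one section into 8-connected
#' components and measures each: area, sub-pixel centroid (0-based
#' pixel-center convention), major axis of the moment-equivalent ellipse
#' (`4 * sqrt` of the largest pixel-coordinate covariance eigenvalue),
#' half-open 0-based bounding box, and mean original intensity.
#'
#' @param mask Logical (or 0/1) matrix, `TRUE` = candidate foreground.
#' @param img The originating intensity matrix (same shape).
#' @param z_index 0-based section index recorded on each segment.
#' @return A tibble with one row per segment (`seg_id` is the per-section
#'   component id; volume-unique labels are assigned by [segment_table()]),
#'   with attribute `"label_matrix"` holding the per-section integer
#'   component labeling.
#' @export
extract_segments <- function(mask, img, z_index = 0L) {
  if (!is.matrix(mask)) abort("`mask` must be a matrix")
  check_image(img)
  if (!all(dim(mask) == dim(img))) abort("`mask` and `img` must be congruent")
  lab <- label_components(mask)
  feats <- component_features(lab, img)
  out <- mutate(feats, z_index = as.integer(z_index),
                pruned_flag = FALSE, reason = NA_character_)
  out <- select(out, z_index, seg_id, area_px, centroid_y, centroid_x,
                major_axis_px, bbox_y_min, bbox_x_min, bbox_y_max,
                bbox_x_max, mean_intensity, pruned_flag, reason)
  attr(out, "label_matrix") <- lab
  out
}

#' Filter segments by area and major-axis bounds
#'
#' Keeps exactly the segments with
#' `min_area_px < area_px < max_area_px` and
#' `major_axis_px < max_major_axis_px` (all strict). Order is preserved and
#' the operation is idempotent.
#'
#' @param segments Segment tibble (from [extract_segments()] or a
#'   [segment_table()]'s `$segments`).
#' @param params A [filter_params()].
#' @return The kept rows.
#' @export
filter_segments <- function(segments, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  dplyr::filter(segments,
                area_px > params$min_area_px,
                area_px < params$max_area_px,
                major_axis_px < params$max_major_axis_px)
}

#' Flag irregularly large artifacts between adjacent segments
#'
#' A labeled process progresses smoothly through the volume, so its
#' cross-sections on neighbouring sections have similar areas. A segment is
#' flagged as an artifact when (a) it has candidate-linked neighbours on
#' adjacent sections both above and below (it "appears between adjacent
#' segments"), and (b) its area exceeds `prune_area_ratio` times the median
#' area of those neighbours. Flagged segments are excluded from linking but
#' retained with a reason code for audit; segments whose progression cannot
#' be assessed (no neighbour on one side) are never flagged.
#'
#' @param table A [segment_table()].
#' @param params A [filter_params()] (supplies `prune_area_ratio`).
#' @param link A [link_params()] defining the candidate neighbourhood
#'   (radius and maximum section gap), evaluated two-sided.
#' @return The table with `pruned_flag`/`reason` updated.
#' @export
prune_artifacts <- function(table, params = filter_params(),
                            link = link_params()) {
  stopifnot(inherits(table, "segment_table"), inherits(params, "filter_params"),
            inherits(link, "link_params"))
  segs <- table$segments
  if (nrow(segs) == 0L) return(table)
  cand <- candidate_pairs(segs, table$meta$voxel, link$radius_nm,
                          link$max_gap_sections)
  if (nrow(cand) > 0L) {
    # neighbours of each segment, in both directions
    nb <- bind_rows(
      tibble(label = cand$label_a, nb = cand$label_b, side = sign(cand$dz)),
      tibble(label = cand$label_b, nb = cand$label_a, side = -sign(cand$dz)))
    area_of <- setNames(segs$area_px, segs$label)
    stats <- nb |>
      group_by(label) |>
      summarise(both_sides = any(side > 0) && any(side < 0),
                med_area = median(area_of[as.character(nb)]),
                .groups = "drop")
    flagged <- stats$label[stats$both_sides &
                             area_of[as.character(stats$label)] >
                               params$prune_area_ratio * stats$med_area]
    if (length(flagged) > 0L) {
      hit <- segs$label %in% flagged
      segs$pruned_flag[hit] <- TRUE
      segs$reason[hit] <- "area_progression"
    }
  }
  table$segments <- segs
  table$meta$params$filter <- unclass(params)
  table
}
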