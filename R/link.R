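# Graph-based linking of 2D segments across sections (k-nearest-neighbour
# centroid search, k = 2 by default), gap bridging across missing sections,
# and merging of graph components into labeled 3D reconstructions.

#' Linking parameters
#'
#' @param k Number of nearest cross-section candidates each segment links
#'   to. `k = 2` supports branching: a bifurcating dendrite needs two links.
#' @param radius_nm Candidate-search radius in in-plane nanometres
#'   (default 2000 nm, several dendrite diameters).
#' @param max_gap_sections Maximum section-index offset a link may span;
#'   offsets of 2 or more bridge missing or subsampled sections.
#' @param max_link_distance_nm Hard cap on an accepted link's distance
#'   (defaults to `radius_nm`).
#' @return A `link_params` list.
#' @export
link_params <- function(k = 2L, radius_nm = 2000, max_gap_sections = 3L,
                        max_link_distance_nm = radius_nm) {
  check_scalar(k, "k", 1)
  check_scalar(radius_nm, "radius_nm", 0, strict_lower = TRUE)
  check_scalar(max_gap_sections, "max_gap_sections", 1)
  check_scalar(max_link_distance_nm, "max_link_distance_nm", 0, strict_lower = TRUE)
  structure(list(k = as.integer(k), radius_nm = radius_nm,
                 max_gap_sections = as.integer(max_gap_sections),
                 max_link_distance_nm = max_link_distance_nm),
            class = "link_params")
}

# k nearest upward candidates per query segment, pooled over all allowed
# z-offsets; ties in distance break toward the smaller candidate label.
knn_edges <- function(cand, k, max_dist) {
  if (nrow(cand) == 0L) return(cand)
  cand <- dplyr::filter(cand, dist_nm <= max_dist)
  cand <- arrange(cand, label_a, dist_nm, label_b)
  cand <- mutate(group_by(cand, label_a), rank = row_number())
  ungroup(dplyr::filter(cand, rank <= k))[, c("label_a", "label_b", "dist_nm", "dz")]
}

dedup_edges <- function(edges) {
  edges <- mutate(edges,
                  from = pmin(label_a, label_b),
                  to = pmax(label_a, label_b))
  edges <- distinct(select(edges, from, to, dist_nm, dz))
  arrange(edges, from, to)
}

#' Build the cross-section link graph
#'
#' For each non-pruned segment, all candidates on sections with z-offset in
#' `[1, max_gap_sections]` whose centroid lies within `radius_nm` (in-plane
#' physical distance) are pooled, and undirected edges are added to the `k`
#' nearest (ties toward the smaller label), provided the distance does not
#' exceed `max_link_distance_nm`. Edges are deduplicated. Because
#' candidates are pooled across all allowed z-offsets, a continuing process
#' fills its own k slots with its next cross-sections before any
#' neighbouring process can compete.
#'
#' @param table A [segment_table()].
#' @param params A [link_params()].
#' @return An `em_link_graph`: list with `$edges` (tibble `from`, `to`,
#'   `dist_nm`, `dz`), `$nodes` (non-pruned labels) and `$params`.
#' @export
build_link_graph <- function(table, params = link_params()) {
  stopifnot(inherits(table, "segment_table"), inherits(params, "link_params"))
  segs <- dplyr::filter(table$segments, !pruned_flag)
  cand <- candidate_pairs(segs, table$meta$voxel_nm, params$radius_nm,
                          params$max_gap_sections)
  edges <- dedup_edges(knn_edges(cand, params$k, params$max_link_distance_nm))
  structure(list(edges = edges, nodes = segs$label, params = params),
            class = "em_link_graph")
}

#' @export
print.em_link_graph <- function(x, ...) {
  cat(sprintf("<em_link_graph> %d nodes, %d edges (%d gap edges)\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$dz >= 2L)))
  invisible(x)
}

#' Bridge gaps across missing sections
#'
#' Re-runs the candidate search of [build_link_graph()] and adds to the
#' graph only those resulting edges whose z-gap is at least 2 — the links
#' that jump a missing, dropped or subsampled section. On a graph already
#' built with the same parameters this is a no-op; it exists as an
#' explicit, separately testable pass.
#'
#' @param graph An `em_link_graph`.
#' @param table The [segment_table()] the graph was built from.
#' @param params A [link_params()].
#' @return The graph with gap edges added (deduplicated).
#' @export
bridge_gaps <- function(graph, table, params = link_params()) {
  stopifnot(inherits(graph, "em_link_graph"), inherits(table, "segment_table"))
  full <- build_link_graph(table, params)
  gap_edges <- dplyr::filter(full$edges, dz >= 2L)
  graph$edges <- dedup_edges(mutate(bind_rows(graph$edges, gap_edges),
                                    label_a = from, label_b = to))
  graph
}

#' Merge linked segments into a 3D reconstruction
#'
#' Components of the link graph become numbered 3D processes (disjoint-set
#' union over edges). A final consistency pass merges any two components
#' that contain same-section segments whose bounding boxes overlap by at
#' least `min_overlap` of the smaller segment's box area — duplicate
#' detections of one structure. Components are numbered deterministically
#' by descending total segment area, ties toward the smallest member label.
#'
#' @param graph An `em_link_graph`.
#' @param table The [segment_table()] the graph was built from.
#' @param min_overlap Same-section box-overlap fraction that forces a merge.
#' @return An `em_reconstruction`: list with `$components` (tibble `label`,
#'   `component`), `$summary` (per-component segment count, z-extent, total
#'   area) and `$table`.
#' @export
merge_components <- function(graph, table, min_overlap = 0.5) {
  stopifnot(inherits(graph, "em_link_graph"), inherits(table, "segment_table"))
  segs <- dplyr::filter(table$segments, !pruned_flag)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(segs), name = as.character(segs$label))
  if (nrow(graph$edges) > 0L) {
    g <- igraph::add_edges(g, as.character(t(as.matrix(
      graph$edges[, c("from", "to")]))))
  }
  memb <- igraph::components(g)$membership
  comp_of <- setNames(memb[as.character(segs$label)], segs$label)

  # consistency pass: same-section bbox overlap >= min_overlap of the
  # smaller segment's box merges the two components
  if (nrow(segs) > 1L && min_overlap <= 1) {
    merge_pairs <- overlap_merge_pairs(segs, comp_of, min_overlap)
    if (nrow(merge_pairs) > 0L) {
      parent <- seq_len(max(comp_of))
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (r in seq_len(nrow(merge_pairs))) {
        ra <- find(merge_pairs$a[r]); rb <- find(merge_pairs$b[r])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      comp_of[] <- vapply(comp_of, find, numeric(1))
    }
  }

  comp_tbl <- tibble(label = segs$label, component = as.integer(comp_of))
  comp_tbl <- left_join(comp_tbl,
                        segs[, c("label", "z_index", "area_px")], by = "label")
  if (nrow(comp_tbl) == 0L) {
    return(structure(list(
      components = tibble(label = integer(), component = integer()),
      summary = tibble(component = integer(), n_segments = integer(),
                       z_min = integer(), z_max = integer(),
                       total_area_px = integer()),
      table = table
    ), class = "em_reconstruction"))
  }
  summary <- comp_tbl |>
    group_by(component) |>
    summarise(n_segments = n(), z_min = min(z_index), z_max = max(z_index),
              total_area_px = sum(area_px), min_label = min(label),
              .groups = "drop") |>
    arrange(desc(total_area_px), min_label)
  renum <- setNames(seq_len(nrow(summary)), summary$component)
  comp_tbl$component <- as.integer(renum[as.character(comp_tbl$component)])
  summary$component <- as.integer(renum[as.character(summary$component)])
  summary <- arrange(summary, component)

  structure(list(
    components = select(comp_tbl, label, component),
    summary = select(summary, component, n_segments, z_min, z_max, total_area_px),
    table = table
  ), class = "em_reconstruction")
}

# Pairs of components owning same-section segments with bbox overlap >=
# min_overlap of the smaller box.
overlap_merge_pairs <- function(segs, comp_of, min_overlap) {
  out <- list()
  for (sz in split(segs, segs$z_index)) {
    n <- nrow(sz)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ci <- comp_of[as.character(sz$label[i])]
      cj <- comp_of[as.character(sz$label[j])]
      if (ci == cj) next
      oy <- min(sz$bbox_y_max[i], sz$bbox_y_max[j]) -
        max(sz$bbox_y_min[i], sz$bbox_y_min[j])
      ox <- min(sz$bbox_x_max[i], sz$bbox_x_max[j]) -
        max(sz$bbox_x_min[i], sz$bbox_x_min[j])
      if (oy <= 0 || ox <= 0) next
      ai <- (sz$bbox_y_max[i] - sz$bbox_y_min[i]) * (sz$bbox_x_max[i] - sz$bbox_x_min[i])
      aj <- (sz$bbox_y_max[j] - sz$bbox_y_min[j]) * (sz$bbox_x_max[j] - sz$bbox_x_min[j])
      if (oy * ox >= min_overlap * min(ai, aj)) {
        out[[length(out) + 1L]] <- c(ci, cj)
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(a = integer(), b = integer()))
  }
  as_tibble(unique(do.call(rbind, out)), .name_repair = ~c("a", "b"))
}

#' @export
print.em_reconstruction <- function(x, ...) {
  cat(sprintf("<em_reconstruction> %d components over %d segments\n",
              nrow(x$summary), nrow(x$components)))
  print(x$summary, n = 10)
  invisible(x)
}

#' Export a reconstruction to disk
#'
#' Writes a per-component 16-bit label TIFF stack (pixels carry the 3D
#' component id of their segment), a per-component CSV summary, and a
#' per-component centroid-chain point list (z, y, x in nm) usable for 3D
#' rendering.
#'
#' @param recon An `em_reconstruction`.
#' @param label_stack Named list of per-section global-segment-label
#'   matrices (as produced by [segment_stack()]).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
export_reconstruction <- function(recon, label_stack, dir) {
  stopifnot(inherits(recon, "em_reconstruction"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  map <- integer(0)
  if (nrow(recon$components) > 0L) {
    map <- integer(max(recon$components$label))
    map[recon$components$label] <- recon$components$component
  }
  comp_stack <- lapply(label_stack, function(lab) {
    out <- matrix(0L, nrow(lab), ncol(lab))
    pos <- lab > 0L & lab <= length(map)
    out[pos] <- map[lab[pos]]
    out
  })
  p_tif <- file.path(dir, "components.tif")
  if (length(comp_stack) > 0L) {
    tiff::writeTIFF(lapply(comp_stack, function(m) m / 65535), p_tif,
                    bits.per.sample = 16L)
  } else {
    tiff::writeTIFF(list(matrix(0, 1, 1)), p_tif, bits.per.sample = 16L)
  }
  p_sum <- file.path(dir, "components.csv")
  write.csv(recon$summary, p_sum, row.names = FALSE)
  v <- recon$table$meta$voxel_nm
  chains <- recon$components |>
    left_join(recon$table$segments, by = "label") |>
    mutate(z_nm = z_index * v["z"], y_nm = centroid_y * v["y"],
           x_nm = centroid_x * v["x"]) |>
    arrange(component, z_index, label)
  p_chain <- file.path(dir, "centroid_chains.csv")
  write.csv(chains[, c("component", "label", "z_index", "z_nm", "y_nm", "x_nm")],
            p_chain, row.names = FALSE)
  invisible(c(p_tif, p_sum, p_chain))
}
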