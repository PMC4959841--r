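# Evaluation against ground truth (recall, missed-segment sizes, split/merge
# errors) and ROI proposal for targeted high-resolution re-imaging.

#' Match predicted segments against ground-truth masks
#'
#' A ground-truth segment — the per-section cross-section of one true
#' process — counts as matched when a single predicted segment on the same
#' section covers at least `min_overlap` of its pixels. Recall is the
#' matched fraction; missed-segment size is summarised as the mean
#' bounding-box height and width. Precision (fraction of predicted
#' segments covering at least `min_overlap` of their own area with some
#' true process) is reported alongside for diagnostics.
#'
#' @param pred_stack Named list of per-section predicted label matrices
#'   (global segment labels; from [segment_stack()]).
#' @param truth_stack Named list of per-section ground-truth label matrices
#'   over the same sections (0 = background, p = process id).
#' @param min_overlap Matched fraction threshold on the truth segment's
#'   area (default 0.5).
#' @return An `em_match`: list with `$summary` (tibble: `n_truth`,
#'   `n_matched`, `recall`, `precision`, `mean_missed_height_px`,
#'   `mean_missed_width_px`) and `$per_truth` (tibble with one row per
#'   truth segment: section, process, area, best overlap, matched flag,
#'   bbox height/width).
#' @export
match_segments <- function(pred_stack, truth_stack, min_overlap = 0.5) {
  if (length(pred_stack) != length(truth_stack))
    abort("`pred_stack` and `truth_stack` must cover the same sections")
  check_scalar(min_overlap, "min_overlap", 0, 1, strict_lower = TRUE)
  zs <- names(truth_stack)
  rows <- vector("list", length(zs))
  n_pred_total <- 0L; n_pred_matched <- 0L
  for (i in seq_along(zs)) {
    tl <- truth_stack[[i]]; pl <- pred_stack[[i]]
    if (!all(dim(tl) == dim(pl)))
      abort(sprintf("section %s: predicted and truth masks are not congruent", zs[i]))
    tidx <- which(tl > 0L)
    if (length(tidx) > 0L) {
      tt <- tl[tidx]; pp <- pl[tidx]
      m <- nrow(tl)
      row0 <- (tidx - 1L) %% m; col0 <- (tidx - 1L) %/% m
      sp <- split(seq_along(tt), tt)
      rows[[i]] <- bind_rows(lapply(names(sp), function(pid) {
        ii <- sp[[pid]]
        area <- length(ii)
        ov <- table(pp[ii][pp[ii] > 0L])
        best <- if (length(ov) > 0L) max(ov) else 0L
        tibble(z = zs[i], process = as.integer(pid), truth_area = area,
               best_overlap = as.integer(best),
               matched = best >= min_overlap * area,
               height_px = diff(range(row0[ii])) + 1L,
               width_px = diff(range(col0[ii])) + 1L)
      }))
    }
    # precision bookkeeping: predicted segments covered by true label
    pidx <- which(pl > 0L)
    if (length(pidx) > 0L) {
      psp <- split(tl[pidx] > 0L, pl[pidx])
      n_pred_total <- n_pred_total + length(psp)
      n_pred_matched <- n_pred_matched +
        sum(vapply(psp, function(v) mean(v) >= min_overlap, logical(1)))
    }
  }
  per_truth <- bind_rows(rows)
  if (nrow(per_truth) == 0L) abort("ground truth contains no segments")
  missed <- dplyr::filter(per_truth, !matched)
  summary <- tibble(
    n_truth = nrow(per_truth),
    n_matched = sum(per_truth$matched),
    recall = sum(per_truth$matched) / nrow(per_truth),
    precision = if (n_pred_total > 0L) n_pred_matched / n_pred_total else NA_real_,
    mean_missed_height_px = if (nrow(missed) > 0L) mean(missed$height_px) else NA_real_,
    mean_missed_width_px = if (nrow(missed) > 0L) mean(missed$width_px) else NA_real_)
  structure(list(summary = summary, per_truth = per_truth,
                 min_overlap = min_overlap), class = "em_match")
}

#' @export
print.em_match <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<em_match> recall %.3f (%d/%d truth segments), precision %.3f\n",
              s$recall, s$n_matched, s$n_truth, s$precision))
  if (!is.na(s$mean_missed_height_px))
    cat(sprintf("  missed segments average %.1f x %.1f px (h x w)\n",
                s$mean_missed_height_px, s$mean_missed_width_px))
  invisible(x)
}

#' Propose regions of interest for high-resolution re-imaging
#'
#' From an overview-resolution reconstruction, proposes padded 3D physical
#' boxes around selected components and reports how much smaller the
#' proposed imaging volume is than the full overview volume
#' (`reduction_factor = total_volume / roi_volume`) — the factor by which
#' targeted re-imaging reduces imaging time.
#'
#' @param recon An `em_reconstruction` (ignored when `box_um3` is given).
#' @param selector `"all"` for every component, or an integer vector of
#'   component ids.
#' @param margin_nm Padding added to each side of a component's bounding
#'   box, in nm.
#' @param total_um3,box_um3 Explicit total and ROI volumes in cubic
#'   micrometres; when both are given the proposal is the stated box and no
#'   reconstruction is consulted.
#' @return An `em_roi`: list with `$boxes` (tibble of physical boxes:
#'   z-range in sections, y/x ranges in nm), `$total_volume_um3`,
#'   `$roi_volume_um3` and `$reduction_factor`.
#' @export
#' @examples
#' propose_roi(total_um3 = 2e7, box_um3 = 5e5)$reduction_factor  # 40
propose_roi <- function(recon = NULL, selector = "all", margin_nm = 500,
                        total_um3 = NULL, box_um3 = NULL) {
  if (!is.null(total_um3) && !is.null(box_um3)) {
    check_scalar(total_um3, "total_um3", 0, strict_lower = TRUE)
    check_scalar(box_um3, "box_um3", 0, strict_lower = TRUE)
    if (box_um3 > total_um3) abort("ROI volume cannot exceed the total volume")
    return(structure(list(boxes = tibble(volume_um3 = box_um3),
                          total_volume_um3 = total_um3,
                          roi_volume_um3 = box_um3,
                          reduction_factor = total_um3 / box_um3),
                     class = "em_roi"))
  }
  stopifnot(inherits(recon, "em_reconstruction"))
  check_scalar(margin_nm, "margin_nm", 0)
  meta <- recon$table$meta
  v <- meta$voxel_nm
  h <- meta$shape[1]; w <- meta$shape[2]
  z_lo <- min(meta$sections); z_hi <- max(meta$sections)
  total_nm3 <- (h * v["y"]) * (w * v["x"]) * ((z_hi - z_lo + 1) * v["z"])

  comps <- if (identical(selector, "all")) recon$summary$component
           else intersect(as.integer(selector), recon$summary$component)
  if (length(comps) == 0L) abort("empty component selection")
  segs <- left_join(recon$components, recon$table$segments, by = "label")
  boxes <- segs |>
    dplyr::filter(component %in% comps) |>
    group_by(component) |>
    summarise(z_min = min(z_index), z_max = max(z_index),
              y_min_nm = max(min(bbox_y_min) * v["y"] - margin_nm, 0),
              y_max_nm = min(max(bbox_y_max) * v["y"] + margin_nm, h * v["y"]),
              x_min_nm = max(min(bbox_x_min) * v["x"] - margin_nm, 0),
              x_max_nm = min(max(bbox_x_max) * v["x"] + margin_nm, w * v["x"]),
              .groups = "drop") |>
    mutate(volume_um3 = (y_max_nm - y_min_nm) * (x_max_nm - x_min_nm) *
             ((z_max - z_min + 1) * v["z"]) / 1e9)
  roi_nm3 <- sum(boxes$volume_um3) * 1e9
  structure(list(boxes = boxes,
                 total_volume_um3 = as.numeric(total_nm3) / 1e9,
                 roi_volume_um3 = as.numeric(roi_nm3) / 1e9,
                 reduction_factor = as.numeric(total_nm3 / roi_nm3)),
            class = "em_roi")
}

#' @export
print.em_roi <- function(x, ...) {
  cat(sprintf(
    "<em_roi> %d box(es): %.3g of %.3g um^3 -> %.3g-fold imaging reduction\n",
    nrow(x$boxes), x$roi_volume_um3, x$total_volume_um3, x$reduction_factor))
  invisible(x)
}

#' Per-component and per-volume reconstruction statistics
#'
#' Reports component counts, z-extents and the labeled-pixel fraction.
#' With ground truth, each predicted segment is assigned to the true
#' process covering the majority of its pixels (or none), and split/merge
#' errors are counted: a truth process fragmented over c components
#' contributes c - 1 split errors; a component containing t truth
#' processes contributes t - 1 merge errors.
#'
#' @param recon An `em_reconstruction`.
#' @param pred_stack Named list of per-section predicted label matrices
#'   (required for the labeled fraction and for truth comparison).
#' @param truth_stack Optional ground-truth label matrices (same sections).
#' @return A list with `$volume` (tibble: n_components, n_segments,
#'   labeled_fraction), `$components` (the reconstruction summary) and,
#'   with truth, `$errors` (tibble: split_errors, merge_errors,
#'   spurious_components) plus `$assignment` (label, component, process).
#' @export
density_report <- function(recon, pred_stack = NULL, truth_stack = NULL) {
  stopifnot(inherits(recon, "em_reconstruction"))
  labeled_fraction <- NA_real_
  if (!is.null(pred_stack)) {
    tot <- sum(vapply(pred_stack, length, numeric(1)))
    fg <- sum(vapply(pred_stack, function(m) sum(m > 0L), numeric(1)))
    labeled_fraction <- fg / tot
  }
  out <- list(
    volume = tibble(n_components = nrow(recon$summary),
                    n_segments = nrow(recon$components),
                    labeled_fraction = labeled_fraction),
    components = recon$summary)
  if (!is.null(truth_stack) && !is.null(pred_stack)) {
    # majority-truth-process assignment per predicted segment
    votes <- list()
    for (i in seq_along(pred_stack)) {
      pl <- pred_stack[[i]]; tl <- truth_stack[[i]]
      idx <- which(pl > 0L)
      if (length(idx) == 0L) next
      votes[[length(votes) + 1L]] <-
        tibble(label = pl[idx], process = tl[idx])
    }
    assign <- bind_rows(votes) |>
      group_by(label, process) |>
      summarise(n_px = n(), .groups = "drop_last") |>
      arrange(desc(n_px), process) |>
      slice(1) |>
      ungroup() |>
      mutate(process = ifelse(process == 0L, NA_integer_, process))
    assign <- left_join(assign, recon$components, by = "label")
    with_truth <- dplyr::filter(assign, !is.na(process), !is.na(component))
    split_errors <- with_truth |>
      group_by(process) |>
      summarise(nc = dplyr::n_distinct(component), .groups = "drop")
    merge_errors <- with_truth |>
      group_by(component) |>
      summarise(np = dplyr::n_distinct(process), .groups = "drop")
    spurious <- setdiff(recon$summary$component, with_truth$component)
    out$errors <- tibble(
      split_errors = sum(pmax(split_errors$nc - 1L, 0L)),
      merge_errors = sum(pmax(merge_errors$np - 1L, 0L)),
      spurious_components = length(spurious))
    out$assignment <- select(assign, label, component, process, n_px)
  }
  out
}
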