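two_section_masks <- function() {
  t1 <- matrix(0L, 20, 20); t1[3:6, 3:6] <- 1L; t1[12:15, 12:15] <- 2L
  t2 <- matrix(0L, 20, 20); t2[4:7, 3:6] <- 1L
  list(z0000 = t1, z0001 = t2)
}

test_that("recall is 1 on perfect predictions and 0 on disjoint ones", {
  truth <- two_section_masks()
  perfect <- lapply(truth, function(m) { m[m > 0L] <- m[m > 0L] + 10L; m })
  m <- match_segments(perfect, truth)
  expect_equal(m$summary$recall, 1)
  expect_equal(m$summary$n_truth, 3)
  disjoint <- lapply(truth, function(m) {
    out <- matrix(0L, nrow(m), ncol(m)); out[18:20, 1:3] <- 1L; out
  })
  m0 <- match_segments(disjoint, truth)
  expect_equal(m0$summary$recall, 0)
  expect_equal(m0$summary$n_matched, 0)
  # missed-segment statistics are mean bbox height and width
  expect_equal(m0$summary$mean_missed_height_px, 4)
  expect_equal(m0$summary$mean_missed_width_px, 4)
  # empty truth is an error
  empty <- lapply(truth, function(m) matrix(0L, nrow(m), ncol(m)))
  expect_error(match_segments(disjoint, empty), "no segments")
})

test_that("a single predicted segment must supply the overlap", {
  truth <- list(z0000 = matrix(0L, 10, 10))
  truth$z0000[2:5, 2:5] <- 1L          # area 16
  # two predicted segments covering 8 px each: neither reaches 75% alone,
  # and the two may not pool their overlap
  pred <- list(z0000 = matrix(0L, 10, 10))
  pred$z0000[2:5, 2:3] <- 1L
  pred$z0000[2:5, 4:5] <- 2L
  expect_equal(match_segments(pred, truth, 0.75)$summary$recall, 0)
  expect_equal(match_segments(pred, truth, 0.75)$per_truth$best_overlap, 8L)
  # the overlap bound is closed: exactly half coverage matches at 0.5
  expect_equal(match_segments(pred, truth, 0.5)$summary$recall, 1)
  # a single segment covering 12/16 px matches at 0.75
  pred2 <- list(z0000 = matrix(0L, 10, 10))
  pred2$z0000[2:4, 2:5] <- 1L
  expect_equal(match_segments(pred2, truth, 0.75)$summary$recall, 1)
})

test_that("recall is monotone as min_overlap decreases and matches brute force", {
  set.seed(17)
  truth <- list(); pred <- list()
  for (z in 1:3) {
    t <- matrix(0L, 40, 40)
    for (p in 1:4) {
      y <- sample(3:30, 1); x <- sample(3:30, 1)
      t[y:(y + 4), x:(x + 4)] <- p
    }
    pmask <- matrix(0L, 40, 40)
    sel <- which(t > 0L & matrix(runif(1600) < 0.7, 40, 40))
    pmask[sel] <- t[sel] + 7L
    truth[[sprintf("z%04d", z)]] <- t
    pred[[sprintf("z%04d", z)]] <- pmask
  }
  r_strict <- match_segments(pred, truth, 0.9)$summary$recall
  r_mid <- match_segments(pred, truth, 0.5)$summary$recall
  r_loose <- match_segments(pred, truth, 0.1)$summary$recall
  expect_true(r_strict <= r_mid && r_mid <= r_loose)
  for (mo in c(0.3, 0.5, 0.8)) {
    expect_equal(match_segments(pred, truth, mo)$summary$recall,
                 recall_oracle(pred, truth, mo)$recall, info = paste("mo", mo))
  }
})

test_that("ROI proposals reproduce the printed volume arithmetic", {
  # overview volume 2e7 um^3, selected ROI 5e5 um^3 -> 40-fold reduction
  roi <- propose_roi(total_um3 = 2e7, box_um3 = 5e5)
  expect_equal(roi$reduction_factor, 40)
  expect_equal(propose_roi(total_um3 = 1e6, box_um3 = 1e6)$reduction_factor, 1)
  expect_equal(propose_roi(total_um3 = 1e6, box_um3 = 5e5)$reduction_factor, 2)
  expect_error(propose_roi(total_um3 = 1, box_um3 = 2), "exceed")
})

test_that("component-derived ROI boxes stay in bounds and scale consistently", {
  segs <- dplyr::bind_rows(
    seg_row(0, 1, area = 50, cy = 100, cx = 100, bbox = c(95L, 95L, 106L, 106L)),
    seg_row(1, 1, area = 50, cy = 101, cx = 101, bbox = c(96L, 96L, 107L, 107L)))
  tb <- segment_table(segs, voxel_nm = c(20, 20, 30), sections = 0:1,
                      shape = c(512, 512))
  recon <- merge_components(build_link_graph(tb), tb)
  roi <- propose_roi(recon, margin_nm = 200)
  expect_equal(nrow(roi$boxes), 1)
  expect_gte(roi$reduction_factor, 1)
  expect_true(all(roi$boxes$y_min_nm >= 0 & roi$boxes$x_min_nm >= 0))
  expect_true(all(roi$boxes$y_max_nm <= 512 * 20))
  # expressing the same geometry in different units leaves the factor unchanged
  segs2 <- segs
  segs2[, c("centroid_y", "centroid_x")] <- segs[, c("centroid_y", "centroid_x")] / 2
  segs2[, c("bbox_y_min", "bbox_x_min", "bbox_y_max", "bbox_x_max")] <-
    lapply(segs[, c("bbox_y_min", "bbox_x_min", "bbox_y_max", "bbox_x_max")],
           function(v) as.integer(v / 2))
  tb2 <- segment_table(segs2, voxel_nm = c(40, 40, 30), sections = 0:1,
                       shape = c(256, 256))
  recon2 <- merge_components(build_link_graph(tb2), tb2)
  roi2 <- propose_roi(recon2, margin_nm = 200)
  expect_equal(roi2$reduction_factor, roi$reduction_factor, tolerance = 0.05)
  expect_error(propose_roi(recon, selector = 99L), "empty")
})

test_that("density report counts split and merge errors against truth", {
  truth <- list(z0000 = matrix(0L, 20, 20), z0001 = matrix(0L, 20, 20))
  truth$z0000[2:5, 2:5] <- 1L;  truth$z0001[2:5, 2:5] <- 1L
  truth$z0000[12:15, 12:15] <- 2L; truth$z0001[12:15, 12:15] <- 2L

  # 500 nm pixels keep the two processes farther apart than the link radius
  run_case <- function(segs, pred) {
    tb <- segment_table(segs, voxel_nm = c(500, 500, 30), sections = 0:1,
                        shape = c(20, 20))
    recon <- merge_components(build_link_graph(tb), tb)
    density_report(recon, pred, truth)
  }
  lab_of <- function(fill) {
    l1 <- matrix(0L, 20, 20); l2 <- matrix(0L, 20, 20)
    l1[2:5, 2:5] <- fill[1]; l1[12:15, 12:15] <- fill[2]
    l2[2:5, 2:5] <- fill[3]; l2[12:15, 12:15] <- fill[4]
    list(z0000 = l1, z0001 = l2)
  }
  # perfect: both processes linked section-to-section
  segs <- dplyr::bind_rows(
    seg_row(0, 1, area = 16, cy = 2.5, cx = 2.5), seg_row(0, 2, area = 16, cy = 12.5, cx = 12.5),
    seg_row(1, 1, area = 16, cy = 2.5, cx = 2.5), seg_row(1, 2, area = 16, cy = 12.5, cx = 12.5))
  rep0 <- run_case(segs, lab_of(c(1L, 2L, 3L, 4L)))
  expect_equal(rep0$volume$n_components, 2)
  expect_equal(rep0$errors$split_errors, 0)
  expect_equal(rep0$errors$merge_errors, 0)
  # one truth process split into two unlinked components -> 1 split error
  segs_split <- dplyr::bind_rows(
    seg_row(0, 1, area = 16, cy = 2.5, cx = 2.5),
    seg_row(1, 1, area = 16, cy = 17, cx = 17))  # far: no link
  truth_s <- list(z0000 = matrix(0L, 20, 20), z0001 = matrix(0L, 20, 20))
  truth_s$z0000[2:5, 2:5] <- 1L; truth_s$z0001[16:19, 16:19] <- 1L
  tb <- segment_table(segs_split, voxel_nm = c(500, 500, 30), sections = 0:1,
                      shape = c(20, 20))
  recon <- merge_components(build_link_graph(tb, link_params(radius_nm = 100)), tb)
  pred_s <- lab_of(c(1L, 0L, 0L, 0L)); pred_s$z0001[16:19, 16:19] <- 2L
  rep1 <- density_report(recon, pred_s, truth_s)
  expect_equal(rep1$errors$split_errors, 1)
  # two truth processes joined in one component -> 1 merge error
  segs_merge <- dplyr::bind_rows(
    seg_row(0, 1, area = 16, cy = 2.5, cx = 2.5),
    seg_row(1, 1, area = 16, cy = 12.5, cx = 12.5))
  tbm <- segment_table(segs_merge, voxel_nm = c(500, 500, 30), sections = 0:1,
                       shape = c(20, 20))
  reconm <- merge_components(build_link_graph(tbm, link_params(radius_nm = 1e5)), tbm)
  repm <- density_report(reconm, lab_of(c(1L, 0L, 0L, 2L)), truth)
  expect_equal(repm$errors$merge_errors, 1)
})

test_that("tidy/glance/autoplot methods expose results in standard forms", {
  run <- phantom_pipeline_run(1)
  td <- tidy(run$recon)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("label", "component", "area_px") %in% names(td)))
  gl <- glance(run$recon)
  expect_equal(gl$n_components, nrow(run$recon$summary))
  expect_s3_class(glance(run$match), "tbl_df")
  expect_s3_class(tidy(run$match), "tbl_df")
  roi <- propose_roi(total_um3 = 2e7, box_um3 = 5e5)
  expect_equal(glance(roi)$reduction_factor, 40)
  p1 <- ggplot2::autoplot(run$recon)
  p2 <- ggplot2::autoplot(run$match)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
  p3 <- plot_section(run$phantom$images[[1]],
                     dplyr::filter(run$seg$table$segments, z_index == 0))
  expect_s3_class(p3, "ggplot")
})
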