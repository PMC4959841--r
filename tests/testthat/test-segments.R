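test_that("segment extraction uses 8-connectivity and handles empty masks", {
  img <- matrix(0.5, 6, 6)
  expect_equal(nrow(extract_segments(matrix(FALSE, 6, 6), img)), 0)
  # two pixels touching only diagonally form one segment
  m <- matrix(FALSE, 6, 6); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  segs <- extract_segments(m, img)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$area_px, 2L)
  # a 4-connectivity break: pixels two apart stay separate
  m2 <- matrix(FALSE, 6, 6); m2[2, 2] <- TRUE; m2[2, 5] <- TRUE
  expect_equal(nrow(extract_segments(m2, img)), 2)
})

test_that("moment geometry of a filled square matches the stated convention", {
  img <- matrix(0.5, 9, 9)
  m <- matrix(FALSE, 9, 9); m[3:7, 3:7] <- TRUE
  segs <- extract_segments(m, img, z_index = 4L)
  expect_equal(segs$area_px, 25L)
  expect_equal(segs$centroid_y, 4)     # 0-based pixel centers: rows 3..7 -> 2..6
  expect_equal(segs$centroid_x, 4)
  expect_equal(segs$major_axis_px, 4 * sqrt(2))
  expect_equal(c(segs$bbox_y_min, segs$bbox_x_min, segs$bbox_y_max, segs$bbox_x_max),
               c(2L, 2L, 7L, 7L))     # half-open, 0-based
  expect_equal(segs$z_index, 4L)
})

test_that("moment properties equal a per-pixel brute-force computation", {
  set.seed(7)
  for (rep in 1:5) {
    m <- matrix(runif(900) < 0.35, 30, 30)
    img <- matrix(runif(900), 30, 30)
    segs <- extract_segments(m, img)
    lab <- attr(segs, "label_matrix")
    expect_equal(sum(segs$area_px), sum(m))  # areas partition the foreground
    for (i in seq_len(nrow(segs))) {
      o <- moments_oracle(lab, segs$seg_id[i])
      expect_equal(segs$area_px[i], o$area)
      expect_equal(c(segs$centroid_y[i], segs$centroid_x[i]), o$centroid)
      expect_equal(segs$major_axis_px[i], o$major, tolerance = 1e-10)
      expect_equal(segs$mean_intensity[i], mean(img[lab == segs$seg_id[i]]))
    }
  }
})

test_that("segment filters apply the printed strict bounds", {
  segs <- dplyr::bind_rows(
    seg_row(0, 1, area = 2, cy = 1, cx = 1),
    seg_row(0, 2, area = 3, cy = 1, cx = 5),
    seg_row(0, 3, area = 4, cy = 1, cx = 9),
    seg_row(0, 4, area = 25, cy = 5, cx = 1),
    seg_row(0, 5, area = 129999, cy = 5, cx = 5),
    seg_row(0, 6, area = 130000, cy = 5, cx = 9),
    seg_row(0, 7, area = 25, cy = 9, cx = 1, major = 900))
  kept <- filter_segments(segs)
  expect_equal(nrow(kept), 3)
  expect_equal(kept$area_px, c(4L, 25L, 129999L))
  expect_true(all(kept$major_axis_px < 900))
  # order preserved, idempotent
  expect_identical(filter_segments(kept), kept)
})

test_that("artifact pruning flags irregularly large sandwiched segments only", {
  # areas 100 / 5000 / 100 on consecutive sections, mutually within radius
  base <- dplyr::bind_rows(
    seg_row(0, 1, area = 100, cy = 10, cx = 10),
    seg_row(1, 1, area = 5000, cy = 10, cx = 10),
    seg_row(2, 1, area = 100, cy = 10, cx = 10))
  tb <- segment_table(base, voxel_nm = c(20, 20, 30), sections = 0:2,
                      shape = c(64, 64))
  pruned <- prune_artifacts(tb)$segments
  expect_identical(pruned$pruned_flag, c(FALSE, TRUE, FALSE))
  expect_equal(pruned$reason[2], "area_progression")

  # same-size segment sandwiched: kept
  even <- base; even$area_px <- c(100L, 100L, 100L)
  tb2 <- segment_table(even, voxel_nm = c(20, 20, 30), sections = 0:2,
                       shape = c(64, 64))
  expect_false(any(prune_artifacts(tb2)$segments$pruned_flag))

  # no neighbour below: progression cannot be assessed, kept even if huge
  top <- dplyr::bind_rows(
    seg_row(0, 1, area = 5000, cy = 10, cx = 10),
    seg_row(1, 1, area = 100, cy = 10, cx = 10))
  tb3 <- segment_table(top, voxel_nm = c(20, 20, 30), sections = 0:1,
                       shape = c(64, 64))
  expect_false(any(prune_artifacts(tb3)$segments$pruned_flag))
})

test_that("noise-free phantom cross-sections give one kept segment each", {
  spec <- phantom_spec(n_sections = 6, section_shape = c(256, 256),
                       n_processes = 4, n_distractors = 0, noise_sd = 0,
                       jitter_px = 0, seed = 13)
  ph <- generate_phantom(spec)
  # binarize at the stained/background midpoint and check geometry
  for (i in seq_along(ph$images)) {
    img <- ph$images[[i]]
    segs <- filter_segments(extract_segments(binarize(img, 0.4), img,
                                             ph$z_index[i]))
    expect_equal(nrow(segs), 4)
    tl <- ph$truth$label_stack[[i]]
    for (j in seq_len(nrow(segs))) {
      ctr <- tl[round(segs$centroid_y[j]) + 1L, round(segs$centroid_x[j]) + 1L]
      expect_gt(ctr, 0L)  # centroid lies inside the true mask
    }
  }
})
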