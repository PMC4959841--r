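make_table <- function(segs, sections = NULL, voxel = c(20, 20, 30)) {
  if (is.null(sections)) sections <- sort(unique(segs$z_index))
  segment_table(segs, voxel_nm = voxel, sections = sections, shape = c(512, 512))
}

test_that("link graph connects aligned cross-sections and respects the radius", {
  tb <- make_table(dplyr::bind_rows(
    seg_row(0, 1, area = 50, cy = 10, cx = 10),
    seg_row(1, 1, area = 50, cy = 10, cx = 10.5)))   # 10 nm in-plane
  g <- build_link_graph(tb)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$dist_nm, 10)
  # candidate beyond the radius gets no edge regardless of k
  tb2 <- make_table(dplyr::bind_rows(
    seg_row(0, 1, area = 50, cy = 10, cx = 10),
    seg_row(1, 1, area = 50, cy = 10, cx = 200)))    # 3800 nm
  expect_equal(nrow(build_link_graph(tb2)$edges), 0)
})

test_that("k = 2 picks the two nearest candidates pooled across z-offsets", {
  # candidates at in-plane 5 and 7 px on z+1 and 6 px on z+2 (20 nm/px)
  tb <- make_table(dplyr::bind_rows(
    seg_row(0, 1, area = 50, cy = 100, cx = 100),
    seg_row(1, 1, area = 50, cy = 100, cx = 105),
    seg_row(1, 2, area = 50, cy = 100, cx = 107),
    seg_row(2, 1, area = 50, cy = 100, cx = 106)))
  g <- build_link_graph(tb)
  from1 <- g$edges[g$edges$from == 1L, ]
  expect_setequal(from1$to, c(2L, 4L))  # the 5 px (z+1) and 6 px (z+2) candidates
})

test_that("each query contributes at most k edges", {
  set.seed(21)
  segs <- dplyr::bind_rows(lapply(1:60, function(i) {
    seg_row(sample(0:5, 1), i, area = 20,
            cy = runif(1, 0, 100), cx = runif(1, 0, 100))
  }))
  segs$seg_id <- ave(segs$z_index, segs$z_index, FUN = seq_along)
  tb <- make_table(segs, sections = 0:5)
  p <- link_params(k = 2)
  cand <- emtracer:::candidate_pairs(tb$segments, tb$meta$voxel_nm,
                                     p$radius_nm, p$max_gap_sections)
  per_query <- emtracer:::knn_edges(cand, p$k, p$max_link_distance_nm)
  expect_true(all(table(per_query$label_a) <= 2))
})

test_that("link graph equals the exhaustive all-pairs oracle", {
  for (s in 1:6) {
    set.seed(s)
    n <- sample(30:120, 1)
    segs <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      seg_row(sample(0:9, 1), i, area = 20,
              cy = runif(1, 0, 300), cx = runif(1, 0, 300))
    }))
    segs$seg_id <- ave(segs$z_index, segs$z_index, FUN = seq_along)
    tb <- make_table(segs, sections = 0:9)
    p <- link_params(k = 2, radius_nm = 2000, max_gap_sections = 3)
    got <- as.data.frame(build_link_graph(tb, p)$edges[, c("from", "to")])
    want <- link_oracle(tb$segments, tb$meta$voxel_nm, p$k, p$radius_nm,
                        p$max_gap_sections, p$max_link_distance_nm)
    rownames(got) <- NULL
    expect_equal(got, want, info = paste("seed", s))
  }
})

test_that("gap bridging reconnects across missing sections up to the limit", {
  # a vertical tube with section 2 missing: bridged by one z-gap-2 edge
  segs <- dplyr::bind_rows(lapply(c(0, 1, 3, 4), function(z)
    seg_row(z, 1, area = 50, cy = 10, cx = 10 + 0.1 * z)))
  tb <- make_table(segs, sections = c(0, 1, 3, 4))
  g1 <- build_link_graph(tb, link_params(max_gap_sections = 1))
  expect_equal(sort(unique(g1$edges$dz)), 1L)
  g2 <- bridge_gaps(g1, tb, link_params(max_gap_sections = 3))
  expect_true(any(g2$edges$dz == 2L))
  comp <- merge_components(g2, tb)
  expect_equal(nrow(comp$summary), 1)
  # a gap wider than max_gap_sections is not bridged
  far <- make_table(dplyr::bind_rows(
    seg_row(0, 1, area = 50, cy = 10, cx = 10),
    seg_row(4, 1, area = 50, cy = 10, cx = 10)), sections = c(0, 4))
  gf <- build_link_graph(far, link_params(max_gap_sections = 3))
  gf <- bridge_gaps(gf, far, link_params(max_gap_sections = 3))
  expect_equal(nrow(gf$edges), 0)
  # with no gaps the pass leaves the graph unchanged
  g3 <- build_link_graph(tb, link_params(max_gap_sections = 3))
  g4 <- bridge_gaps(g3, tb, link_params(max_gap_sections = 3))
  expect_identical(g3$edges, g4$edges)
})

test_that("components partition segments with deterministic numbering", {
  chain <- dplyr::bind_rows(lapply(0:9, function(z)
    seg_row(z, 1, area = 50, cy = 10, cx = 10)))
  second <- dplyr::bind_rows(lapply(0:4, function(z)
    seg_row(z, 2, area = 500, cy = 400, cx = 400)))
  tb <- make_table(dplyr::bind_rows(chain, second), sections = 0:9)
  recon <- merge_components(build_link_graph(tb), tb)
  expect_equal(nrow(recon$summary), 2)
  # every non-pruned segment in exactly one component
  expect_setequal(recon$components$label, tb$segments$label)
  expect_equal(anyDuplicated(recon$components$label), 0)
  # numbering by descending total area: the thick short chain is component 1
  expect_equal(recon$summary$total_area_px, sort(recon$summary$total_area_px,
                                                 decreasing = TRUE))
  expect_equal(recon$summary$n_segments[recon$summary$component == 1], 5)
})

test_that("the consistency pass merges duplicate same-section detections", {
  # two single-segment components whose boxes overlap 90% on one section
  a <- seg_row(0, 1, area = 100, cy = 10, cx = 10, bbox = c(0L, 0L, 10L, 10L))
  b <- seg_row(0, 2, area = 100, cy = 10, cx = 11, bbox = c(0L, 1L, 10L, 11L))
  tb <- make_table(dplyr::bind_rows(a, b), sections = 0L)
  recon <- merge_components(build_link_graph(tb), tb)
  expect_equal(nrow(recon$summary), 1)
  # disjoint boxes stay separate
  b2 <- seg_row(0, 2, area = 100, cy = 40, cx = 40, bbox = c(30L, 30L, 40L, 40L))
  tb2 <- make_table(dplyr::bind_rows(a, b2), sections = 0L)
  expect_equal(nrow(merge_components(build_link_graph(tb2), tb2)$summary), 2)
})

test_that("linking is invariant under consistent metadata/coordinate rescaling", {
  set.seed(31)
  segs <- dplyr::bind_rows(lapply(1:40, function(i) {
    seg_row(sample(0:4, 1), i, area = 20,
            cy = runif(1, 0, 200), cx = runif(1, 0, 200))
  }))
  segs$seg_id <- ave(segs$z_index, segs$z_index, FUN = seq_along)
  tb1 <- make_table(segs, sections = 0:4, voxel = c(20, 20, 30))
  segs2 <- segs
  segs2$centroid_y <- segs$centroid_y * 4
  segs2$centroid_x <- segs$centroid_x * 4
  tb2 <- make_table(segs2, sections = 0:4, voxel = c(5, 5, 30))
  e1 <- build_link_graph(tb1)$edges
  e2 <- build_link_graph(tb2)$edges
  expect_equal(e1$from, e2$from)
  expect_equal(e1$to, e2$to)
  expect_equal(e1$dist_nm, e2$dist_nm)
})

test_that("exported reconstructions round-trip component ids", {
  dir <- withr::local_tempdir()
  segs <- dplyr::bind_rows(
    seg_row(0, 1, area = 4, cy = 1.5, cx = 1.5, bbox = c(0L, 0L, 3L, 3L)),
    seg_row(1, 1, area = 4, cy = 1.5, cx = 1.5, bbox = c(0L, 0L, 3L, 3L)))
  tb <- segment_table(segs, voxel_nm = c(20, 20, 30), sections = 0:1,
                      shape = c(8, 8))
  recon <- merge_components(build_link_graph(tb), tb)
  lab <- matrix(0L, 8, 8); lab[1:2, 1:2] <- 1L
  lab2 <- matrix(0L, 8, 8); lab2[1:2, 1:2] <- 2L
  paths <- export_reconstruction(recon, list(z0000 = lab, z0001 = lab2), dir)
  stack <- tiff::readTIFF(file.path(dir, "components.tif"), all = TRUE, as.is = TRUE)
  expect_equal(unique(stack[[1]][stack[[1]] > 0]), 1)
  expect_equal(unique(stack[[2]][stack[[2]] > 0]), 1)  # same 3D component
  sum_csv <- read.csv(file.path(dir, "components.csv"))
  expect_equal(sum(sum_csv$n_segments), nrow(tb$segments))
  chains <- read.csv(file.path(dir, "centroid_chains.csv"))
  expect_equal(nrow(chains), 2)
  expect_equal(chains$z_nm, c(0, 30))
  # empty reconstruction still exports valid files
  tb0 <- segment_table(segs[0, ], voxel_nm = c(20, 20, 30), sections = 0L,
                       shape = c(8, 8))
  recon0 <- merge_components(build_link_graph(tb0), tb0)
  expect_no_error(export_reconstruction(recon0, list(), file.path(dir, "empty")))
})
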