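regions_of <- function(m, conn = 8) label_components(m, conn)

test_that("component distances reproduce hand geometry", {
  nm <- matrix(FALSE, 8, 8); nm[1, 1] <- TRUE
  tm <- matrix(FALSE, 8, 8); tm[4, 5] <- TRUE
  p <- component_min_distances(regions_of(nm), regions_of(tm))
  expect_equal(p$min_distance, 5)  # 3-4-5 triangle
  expect_equal(c(p$nerve_row, p$nerve_col, p$tumor_row, p$tumor_col),
               c(1, 1, 4, 5))
  # overlapping predictions share a pixel: distance 0
  ov <- matrix(FALSE, 5, 5); ov[3, 3] <- TRUE
  p0 <- component_min_distances(regions_of(ov), regions_of(ov))
  expect_equal(p0$min_distance, 0)
  # no tumor components -> empty result
  expect_equal(nrow(component_min_distances(regions_of(nm),
                                            regions_of(matrix(FALSE, 8, 8)))), 0)
  expect_error(component_min_distances(regions_of(nm),
                                       regions_of(matrix(FALSE, 4, 4))),
               "shape")
})

test_that("component distances equal exhaustive pairwise minima on random rasters", {
  set.seed(31)
  for (i in 1:60) {
    H <- sample(8:48, 1); W <- sample(8:48, 1)
    nm <- random_blob_mask(H, W, sample(0:3, 1))
    tm <- random_blob_mask(H, W, sample(0:3, 1))
    got <- component_min_distances(regions_of(nm), regions_of(tm))
    want <- bf_pair_distances(bf_label(nm, 8), bf_label(tm, 8))
    got <- got[order(got$nerve_id, got$tumor_id), ]
    expect_equal(nrow(got), nrow(want))
    expect_identical(got$min_distance, want$min_distance)
    # the reported closest pair realizes the reported distance
    if (nrow(got)) {
      d <- sqrt((got$nerve_row - got$tumor_row)^2 +
                  (got$nerve_col - got$tumor_col)^2)
      expect_equal(d, got$min_distance)
    }
  }
})

test_that("component distances are invariant under raster transposition", {
  set.seed(32)
  for (i in 1:10) {
    nm <- random_blob_mask(30, 44, 2)
    tm <- random_blob_mask(30, 44, 2)
    a <- component_min_distances(regions_of(nm), regions_of(tm))
    b <- component_min_distances(regions_of(t(nm)), regions_of(t(tm)))
    expect_equal(sort(a$min_distance), sort(b$min_distance))
  }
})

test_that("encirclement measures annulus coverage", {
  H <- W <- 81
  rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  d <- sqrt((rr - 41)^2 + (cc - 41)^2)
  nerve <- d <= 12
  # tumor annulus fully surrounding the nerve, 1-px gap
  tum_full <- d > 13 & d <= 22
  nreg <- regions_of(nerve)
  expect_equal(measure_encirclement(1, nreg, tum_full, epsilon = 3), 1.0)
  expect_equal(measure_encirclement(1, nreg, matrix(FALSE, H, W)), 0.0)
  # tumor filling the half plane beside the nerve, gap within epsilon
  tum_half2 <- (cc >= 41) & !(d <= 13)
  enc2 <- measure_encirclement(1, nreg, tum_half2, epsilon = 3)
  expect_equal(enc2, 0.5, tolerance = 0.1)
  expect_error(measure_encirclement(4, nreg, tum_full), "component")
  expect_error(measure_encirclement(1, nreg, tum_full, epsilon = 0), "epsilon")
})

test_that("candidate building filters by distance and measures contact encirclement", {
  gt <- two_bar_gt(gap = 0)
  nreg <- regions_of(gt$class_mask == 2)
  treg <- regions_of(gt$class_mask == 1)
  pairs <- component_min_distances(nreg, treg)
  cfg <- ranking_config(field_size = 32, max_distance = 100)
  cands <- build_candidates(pairs, nreg, treg, gt$class_mask == 1, cfg, "s1")
  expect_equal(nrow(cands), 1)
  expect_equal(cands$min_distance, 1)
  expect_gt(cands$encirclement, 0)     # contact pair gets measured
  expect_equal(cands$height, 32)
  # far pair is excluded
  cfg2 <- ranking_config(max_distance = 0.5)
  expect_equal(nrow(build_candidates(pairs, nreg, treg, gt$class_mask == 1,
                                     cfg2, "s1")), 0)
  # empty pair list
  empty <- component_min_distances(nreg, regions_of(matrix(FALSE, 40, 40)))
  expect_equal(nrow(build_candidates(empty, nreg, treg, gt$class_mask == 1,
                                     cfg, "s1")), 0)
  # distance-positive pair has encirclement exactly 0
  gt5 <- two_bar_gt(gap = 4)
  nreg5 <- regions_of(gt5$class_mask == 2)
  treg5 <- regions_of(gt5$class_mask == 1)
  p5 <- component_min_distances(nreg5, treg5)
  c5 <- build_candidates(p5, nreg5, treg5, gt5$class_mask == 1, cfg, "s1")
  expect_equal(c5$min_distance, 5)
  expect_equal(c5$encirclement, 0)
})

test_that("overlap suppression keeps the best of duplicate windows", {
  cand <- function(d, row0, col0, slide = "s1") {
    data.frame(slide_id = slide, nerve_id = 1L, tumor_id = 1L,
               min_distance = d, nerve_row = 1L, nerve_col = 1L,
               tumor_row = 2L, tumor_col = 2L, encirclement = 0,
               row0 = row0, col0 = col0, height = 64L, width = 64L,
               nerve_area = 100L, tumor_area = 100L)
  }
  two <- rbind(cand(3, 1, 1), cand(2, 1, 1))
  class(two) <- c("pni_candidates", "data.frame")
  kept <- suppress_overlaps(two, 0.5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$min_distance, 2)
  disjoint <- rbind(cand(3, 1, 1), cand(2, 200, 200))
  class(disjoint) <- c("pni_candidates", "data.frame")
  expect_equal(nrow(suppress_overlaps(disjoint, 0.5)), 2)
  # same window on different slides is never suppressed
  slides <- rbind(cand(3, 1, 1, "s1"), cand(2, 1, 1, "s2"))
  class(slides) <- c("pni_candidates", "data.frame")
  expect_equal(nrow(suppress_overlaps(slides, 0.5)), 2)
  expect_equal(nrow(suppress_overlaps(two[0, ], 0.5)), 0)
})

test_that("ranking is ascending by distance with deterministic tie-breaks", {
  cand <- function(d, area = 100L, slide = "s1", row0 = 1L) {
    data.frame(slide_id = slide, nerve_id = 1L, tumor_id = 1L,
               min_distance = d, nerve_row = 1L, nerve_col = 1L,
               tumor_row = 2L, tumor_col = 2L, encirclement = 0,
               row0 = row0, col0 = 1L, height = 64L, width = 64L,
               nerve_area = area, tumor_area = area)
  }
  cands <- rbind(cand(3), cand(0), cand(12.5))
  class(cands) <- c("pni_candidates", "data.frame")
  top2 <- rank_top_k(cands, 2)
  expect_equal(top2$min_distance, c(0, 3))
  expect_equal(nrow(rank_top_k(cands, 40)), 3)
  # ties: larger combined area first, then slide/window order
  ties <- rbind(cand(1, 50L, "s2"), cand(1, 900L, "s1"), cand(1, 50L, "s1"))
  class(ties) <- c("pni_candidates", "data.frame")
  r <- rank_top_k(ties, 3)
  expect_equal(r$nerve_area, c(900L, 50L, 50L))
  expect_equal(r$slide_id[2:3], c("s1", "s2"))
  # permutation invariance
  set.seed(41)
  for (i in 1:5) {
    perm <- ties[sample(3), ]
    class(perm) <- c("pni_candidates", "data.frame")
    expect_equal(rank_top_k(perm, 3), r)
  }
})

test_that("field crops are pixel-exact, clamped, and restorable", {
  set.seed(51)
  tile <- array(runif(64 * 64 * 3), c(64, 64, 3))
  cand <- data.frame(slide_id = "s", nerve_id = 1L, tumor_id = 1L,
                     min_distance = 0, nerve_row = 1L, nerve_col = 1L,
                     tumor_row = 1L, tumor_col = 1L, encirclement = 0,
                     row0 = 1L, col0 = 1L, height = 64L, width = 64L,
                     nerve_area = 1L, tumor_area = 1L)
  whole <- crop_field(tile, cand)
  expect_identical(whole$image, tile)
  # corner event: window must be clamped but keep its size
  gt <- two_bar_gt()
  nreg <- label_components(gt$class_mask == 2)
  treg <- label_components(gt$class_mask == 1)
  pairs <- component_min_distances(nreg, treg)
  cands <- build_candidates(pairs, nreg, treg, gt$class_mask == 1,
                            ranking_config(field_size = 32), "s")
  expect_true(all(cands$row0 >= 1 & cands$row0 + cands$height - 1 <= 40))
  tile40 <- array(runif(40 * 40 * 3), c(40, 40, 3))
  crop <- crop_field(tile40, cands[1, ])
  expect_equal(dim(crop$image), c(32, 32, 3))
  # paste back restores the original
  restored <- tile40
  rows <- crop$window["row0"]:(crop$window["row0"] + 31)
  cols <- crop$window["col0"]:(crop$window["col0"] + 31)
  restored[rows, cols, ] <- crop$image
  expect_identical(restored, tile40)
  bad <- cand; bad$height <- 0L
  expect_error(crop_field(tile, bad), "degenerate")
})
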