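test_that("probability maps are validated and bounded", {
  v <- array(runif(8 * 8 * 2), c(8, 8, 2))
  pm <- probability_map(v, "test")
  expect_s3_class(pm, "probability_map")
  v[1] <- 1.5
  expect_error(probability_map(v), "\\[0, 1\\]")
  expect_error(probability_map(array(0, c(8, 8, 3))), "== 2L")
})

test_that("augmentation applies one transform identically to tile and mask", {
  g <- generate_tile(tile_spec(height = 64, width = 64, n_nerves = 1,
                               n_malignant_glands = 3, n_benign_glands = 0,
                               nerve_thickness_range = c(6, 8),
                               gland_radius_range = c(6, 9),
                               min_component_area = 0, rng_seed = 2))
  tile <- g$tile; mask <- g$gt$class_mask
  seen <- character(0)
  for (seed in 1:40) {
    a <- augment_tile(tile, mask, seed)
    seen <- union(seen, a$op)
    # class-code pixel counts survive every geometric transform
    expect_identical(tabulate(a$mask + 1L, 4L), tabulate(mask + 1L, 4L))
    expect_equal(dim(a$tile)[1:2], dim(a$mask))
    if (a$op == "identity") {
      expect_identical(a$tile, tile)
      expect_identical(a$mask, mask)
    }
    if (a$op == "flip_h") {
      b <- augment_tile(a$tile, a$mask, seed)  # same seed -> same op
      expect_identical(b$mask, mask)           # involution
      expect_identical(b$tile, tile)
    }
    if (a$op %in% c("brightness", "hue")) {
      expect_identical(a$mask, mask)           # photometric leaves mask alone
    }
  }
  expect_gte(length(seen), 6)
  expect_error(augment_tile(tile, mask[1:10, 1:10], 1), "shape")
})

test_that("geometric transforms move marker pixels with their tile", {
  mask <- matrix(0L, 12, 12); mask[2, 3] <- 2L
  tile <- array(0, c(12, 12, 3)); tile[2, 3, 1] <- 1
  for (seed in 1:20) {
    a <- augment_tile(tile, mask, seed)
    expect_identical(which(a$mask == 2L), which(a$tile[, , 1] > 0))
  }
})

test_that("zero-noise oracle reproduces ground truth exactly at threshold 0.5", {
  g <- generate_tile(tile_spec(height = 128, width = 128, n_nerves = 1,
                               n_malignant_glands = 4, n_benign_glands = 1,
                               nerve_thickness_range = c(8, 12),
                               gland_radius_range = c(8, 12),
                               min_component_area = 0, rng_seed = 6),
                     render = FALSE)
  map <- oracle_noise_segment(g$gt)
  expect_identical(binarize(map, "tumor", 0.5)$values, g$gt$class_mask == 1L)
  expect_identical(binarize(map, "nerve", 0.5)$values, g$gt$class_mask == 2L)
  # benign glands are background to the segmenter
  expect_true(all(map$values[, , 1][g$gt$class_mask == 3L] == 0))
  expect_true(all(map$values %in% c(0, 1)))
})

test_that("miss_rate 1 empties the prediction for both classes", {
  g <- generate_tile(tile_spec(height = 96, width = 96, n_nerves = 1,
                               n_malignant_glands = 3, n_benign_glands = 0,
                               nerve_thickness_range = c(6, 9),
                               gland_radius_range = c(6, 9),
                               min_component_area = 0, rng_seed = 8),
                     render = FALSE)
  map <- oracle_noise_segment(g$gt, noise_model(miss_rate = 1))
  expect_true(all(map$values == 0))
})

test_that("spurious component counts follow their Poisson rate", {
  gt <- ground_truth(matrix(0L, 96, 96))
  counts <- matrix(0, 200, 2)
  for (i in 1:200) {
    map <- oracle_noise_segment(gt, noise_model(spurious_rate = 3,
                                                spurious_area_range = c(30, 120),
                                                rng_seed = i))
    for (ch in 1:2) {
      counts[i, ch] <- length(label_components(map$values[, , ch] >= 0.5)$areas)
    }
  }
  expect_equal(mean(counts[, 1]), 3, tolerance = 0.5 / 3)
  expect_equal(mean(counts[, 2]), 3, tolerance = 0.5 / 3)
  # spurious foci never touch true structures
  g <- generate_tile(tile_spec(height = 96, width = 96, n_nerves = 1,
                               n_malignant_glands = 3, n_benign_glands = 0,
                               nerve_thickness_range = c(6, 9),
                               gland_radius_range = c(6, 9),
                               min_component_area = 0, rng_seed = 9),
                     render = FALSE)
  map <- oracle_noise_segment(g$gt, noise_model(spurious_rate = 2,
                                                spurious_area_range = c(30, 80),
                                                rng_seed = 4))
  spur_t <- (map$values[, , 1] >= 0.5) & !(g$gt$class_mask == 1L)
  expect_false(any(spur_t & (g$gt$class_mask != 0L)))
})

test_that("the trainable segmenter learns the two classes and is deterministic", {
  sp <- function(seed) tile_spec(height = 96, width = 96, n_nerves = 1,
                                 n_malignant_glands = 4, n_benign_glands = 1,
                                 nerve_thickness_range = c(8, 12),
                                 gland_radius_range = c(8, 12),
                                 min_component_area = 0, rng_seed = seed)
  tiles <- list(); masks <- list()
  for (s in 1:12) {
    g <- generate_tile(sp(s))
    tiles[[s]] <- g$tile; masks[[s]] <- g$gt$class_mask
  }
  expect_error(train_segmenter(tiles[1:4], masks[1:4]), "at least 8")
  expect_error(train_segmenter(list(), list()), "empty")
  cfg <- segmenter_config(samples_per_tile = 900, rng_seed = 3)
  model <- train_segmenter(tiles[1:10], masks[1:10], cfg)
  # the fit explains substantially more than the base rate
  expect_lt(model$deviance[["tumor"]], 0.6 * model$null_deviance[["tumor"]])
  expect_lt(model$deviance[["nerve"]], 0.6 * model$null_deviance[["nerve"]])
  model2 <- train_segmenter(tiles[1:10], masks[1:10], cfg)
  expect_equal(model$coef_tumor, model2$coef_tumor, tolerance = 1e-6)
  # held-out prediction beats IOU 0.5 per class at threshold 0.5
  for (s in 11:12) {
    map <- predict(model, tiles[[s]])
    expect_true(all(map$values >= 0 & map$values <= 1))
    iou_t <- pixel_iou(binarize(map, "tumor", 0.5)$values, masks[[s]] == 1L)
    iou_n <- pixel_iou(binarize(map, "nerve", 0.5)$values, masks[[s]] == 2L)
    expect_gt(iou_t, 0.5)
    expect_gt(iou_n, 0.5)
  }
  # inference is deterministic
  m1 <- predict(model, tiles[[11]])
  m2 <- predict(model, tiles[[11]])
  expect_identical(m1$values, m2$values)
  # an all-background tile draws low confidence
  bg <- generate_tile(tile_spec(height = 96, width = 96, n_nerves = 0,
                                n_malignant_glands = 0, n_benign_glands = 0,
                                min_component_area = 0, rng_seed = 30))
  mb <- predict(model, bg$tile)
  expect_lt(mean(mb$values[, , 1]), 0.5)
  expect_lt(mean(mb$values[, , 2]), 0.5)
  # model artifact round trip
  path <- tempfile(fileext = ".rds")
  save_segmenter(model, path)
  expect_identical(load_segmenter(path)$coef_tumor, model$coef_tumor)
})
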