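test_that("pooled two-proportion z-test reproduces known values", {
  # symmetric case: no difference
  t0 <- two_proportion_test(5, 10, 5, 10)
  expect_equal(unname(t0$statistic), 0)
  expect_equal(t0$p.value, 1)
  # extreme split: z = 1 / sqrt(0.05)
  t1 <- two_proportion_test(0, 10, 10, 10)
  expect_equal(unname(t1$statistic), 1 / sqrt(0.05))
  expect_equal(t1$p.value, 2 * pnorm(-1 / sqrt(0.05)))
  expect_equal(t1$p.value, 7.7e-6, tolerance = 0.01)
  # degenerate pooled proportion with equal rates
  expect_equal(two_proportion_test(0, 5, 0, 5)$p.value, 1)
  expect_equal(two_proportion_test(5, 5, 5, 5)$p.value, 1)
  expect_error(two_proportion_test(6, 5, 1, 5), "0 <= x <= n")
})

test_that("z squared equals the Pearson chi-square statistic without correction", {
  set.seed(81)
  for (i in 1:25) {
    n1 <- sample(5:80, 1); n2 <- sample(5:80, 1)
    x1 <- sample(1:(n1 - 1), 1); x2 <- sample(1:(n2 - 1), 1)
    z <- unname(two_proportion_test(x1, n1, x2, n2)$statistic)
    tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2)
    chi <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
    expect_equal(z^2, unname(chi), tolerance = 1e-9)
  }
})

test_that("rank-sum test: exact small-sample, ties, and invariances", {
  r <- rank_sum_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p.value, 0.1)  # 2/20 orderings as extreme
  # identical samples
  expect_equal(rank_sum_test(c(4, 4, 4), c(4, 4, 4))$p.value, 1)
  expect_equal(rank_sum_test(1:3, 1:3)$p.value, 1, tolerance = 1e-12)
  # permutation invariance
  a <- c(3.2, 8, 1.5, 9, 4); b <- c(2, 7.5, 6, 11, 0.3, 5)
  r1 <- rank_sum_test(a, b)
  r2 <- rank_sum_test(sample(a), sample(b))
  expect_identical(r1$statistic, r2$statistic)
  expect_identical(r1$p.value, r2$p.value)
  # large-sample route agrees with wilcox.test without continuity correction
  set.seed(91)
  x <- rnorm(20); y <- rnorm(25, 0.8)
  w <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  got <- rank_sum_test(x, y)
  expect_equal(got$p.value, w$p.value, tolerance = 1e-10)
  expect_equal(unname(got$statistic), unname(w$statistic))
  expect_error(rank_sum_test(numeric(0), 1), "nonempty")
})

test_that("case aggregation tracks confirmations and ranks", {
  cand <- data.frame(slide_id = rep("s", 7), min_distance = 1:7)
  res <- aggregate_case(cand, c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE),
                        "caseA")
  expect_true(res$pni_called)
  expect_equal(res$first_positive_rank, 3)
  expect_equal(res$n_confirmed, 2)
  expect_equal(res$n_candidates_reviewed, 7)
  neg <- aggregate_case(cand, rep(FALSE, 7), "caseB")
  expect_false(neg$pni_called)
  expect_true(is.na(neg$first_positive_rank))
  one <- aggregate_case(cand[1, ], TRUE, "caseC")
  expect_equal(one$first_positive_rank, 1)
  expect_error(aggregate_case(cand, c(TRUE, FALSE)), "1:1")
})

screen_gt_slide <- function(gt, config = ranking_config(field_size = 128),
                            min_area = c(tumor = 300, nerve = 300)) {
  map <- oracle_noise_segment(gt)
  screen_slide(map, config, 0.5, min_area, 8, "s1")
}

test_that("the simulated reviewer confirms planted contact events", {
  sp <- tile_spec(height = 192, width = 192, n_nerves = 1,
                  n_malignant_glands = 5, n_benign_glands = 0,
                  nerve_thickness_range = c(12, 16),
                  gland_radius_range = c(12, 18), min_component_area = 400,
                  rng_seed = 21)
  g <- generate_tile(sp, list(pni_event()), render = FALSE)
  sc <- screen_gt_slide(g$gt)
  expect_gte(nrow(sc$candidates), 1)
  best <- rank_top_k(sc$candidates, 1)
  expect_true(review_candidate(best, sc$nerve, sc$tumor, g$gt, review_rule()))
})

test_that("a benign gland paired with a nerve is never confirmed", {
  # nerve bar plus a benign ring close to it; the segmenter (wrongly) calls
  # the benign gland tumor
  m <- matrix(0L, 120, 120)
  m[10:110, 10:40] <- 2L
  rr <- matrix(seq_len(120), 120, 120)
  cc <- matrix(seq_len(120), 120, 120, byrow = TRUE)
  ring <- (rr - 60)^2 + (cc - 52)^2 <= 10^2
  m[ring & m == 0L] <- 3L
  gt <- ground_truth(m)
  vals <- array(0, c(120, 120, 2))
  vals[, , 1][m == 3L] <- 1   # benign misread as tumor
  vals[, , 2][m == 2L] <- 1
  map <- probability_map(vals)
  sc <- screen_slide(map, ranking_config(field_size = 64), 0.5,
                     c(tumor = 10, nerve = 10), 8, "s1")
  expect_gte(nrow(sc$candidates), 1)
  expect_false(review_candidate(sc$candidates[1, ], sc$nerve, sc$tumor, gt,
                                review_rule()))
})

test_that("intratumoral nerves require a third of their circumference encircled", {
  sp <- tile_spec(rng_seed = 23, n_nerves = 1, n_malignant_glands = 8)
  weak <- generate_tile(sp, list(pni_event(target_encirclement = 0.2)),
                        render = FALSE)
  sc_w <- screen_gt_slide(weak$gt, ranking_config(field_size = 512),
                          min_area = c(tumor = 10000, nerve = 10000))
  best_w <- rank_top_k(sc_w$candidates, 1)
  expect_equal(best_w$min_distance, 1)
  expect_false(review_candidate(best_w, sc_w$nerve, sc_w$tumor, weak$gt,
                                review_rule()))
  strong <- generate_tile(sp, list(pni_event(target_encirclement = 0.6)),
                          render = FALSE)
  sc_s <- screen_gt_slide(strong$gt, ranking_config(field_size = 512),
                          min_area = c(tumor = 10000, nerve = 10000))
  best_s <- rank_top_k(sc_s$candidates, 1)
  expect_true(review_candidate(best_s, sc_s$nerve, sc_s$tumor, strong$gt,
                               review_rule()))
  # with the encirclement requirement disabled, contact suffices
  expect_true(review_candidate(best_w, sc_w$nerve, sc_w$tumor, weak$gt,
                               review_rule(require_encirclement_inside_tumor = FALSE)))
})

test_that("study summary reproduces the printed clinical contingency", {
  report <- c(rep(TRUE, 31), rep(FALSE, 28))
  called <- c(rep(TRUE, 30), FALSE, rep(TRUE, 18), rep(FALSE, 10))
  summ <- study_summary(data.frame(report = report, called = called))
  expect_equal(summ$n_cases, 59)
  expect_equal(summ$report_positive, 31)
  expect_equal(summ$algorithm_positive, 48)
  expect_equal(summ$report_positive_pct, 52.5, tolerance = 1e-3)
  expect_equal(summ$algorithm_positive_pct, 81.4, tolerance = 1e-3)
  expect_equal(summ$missed, 1)
  expect_equal(summ$newly_detected, 18)
  # counts are mutually consistent
  expect_equal(summ$algorithm_positive,
               summ$report_positive - summ$missed + summ$newly_detected)
  expect_equal(signif(summ$test$p.value, 2), 0.00088)
  # degenerate studies
  allneg <- study_summary(data.frame(report = rep(FALSE, 10),
                                     called = rep(FALSE, 10)))
  expect_equal(allneg$algorithm_positive_pct, 0)
  expect_equal(allneg$test$p.value, 1)
  same <- study_summary(data.frame(report = report, called = report))
  expect_equal(same$missed + same$newly_detected, 0)
  expect_error(study_summary(list(structure(list(case_id = "a",
                                                 pni_called = TRUE,
                                                 first_positive_rank = 1L),
                                            class = "case_result")),
                             report = c(TRUE, FALSE)),
               "one report label per case")
})

test_that("a zero-noise synthetic study is called perfectly", {
  st <- run_synthetic_study(n_cases = 6, prevalence = 0.5, seed = 12,
                            tile = tile_spec(height = 256, width = 256,
                                             n_nerves = 2,
                                             n_malignant_glands = 6,
                                             n_benign_glands = 1,
                                             nerve_thickness_range = c(14, 20),
                                             gland_radius_range = c(14, 20),
                                             min_component_area = 900),
                            segmenter = noise_model(),
                            min_area = c(tumor = 800, nerve = 800),
                            config = ranking_config(field_size = 256))
  expect_equal(st$sensitivity, 1)
  expect_equal(st$specificity, 1)
  # every positive case is flagged by its very first presented field
  pos <- st$cases[st$cases$report, ]
  expect_true(all(pos$first_positive_rank == 1))
})
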