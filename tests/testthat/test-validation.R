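test_that("hypergeometric null matches brute-force enumeration of subsets", {
  # oracle: enumerate every k-subset and tally overlaps with a fixed truth
  enumerate_null <- function(n, k) {
    subsets <- utils::combn(n, k)
    overlaps <- apply(subsets, 2, function(s) length(intersect(s, seq_len(k))))
    tabulate(overlaps + 1L, nbins = k + 1L) / ncol(subsets)
  }
  for (case in list(c(10, 3), c(8, 3), c(12, 4), c(5, 2))) {
    null <- null_probabilities(case[1], case[2])
    expect_equal(unname(null$probabilities), enumerate_null(case[1], case[2]),
                 tolerance = 1e-12, label = paste(case, collapse = ","))
    expect_equal(sum(null$probabilities), 1)
  }
  # the canonical 3-of-10 case, exactly
  p <- null_probabilities(10, 3)$probabilities
  expect_equal(unname(p), c(35, 63, 21, 1) / 120)
  expect_equal(null_probabilities(3, 3)$probabilities[["r3"]], 1)
  expect_error(null_probabilities(3, 5))
})

test_that("expected counts reproduce the benchmark tallies and rounding", {
  null <- null_probabilities(10, 3)
  e200 <- expected_counts(null, 200)
  expect_equal(unname(e200$expected), c(58 + 1 / 3, 105, 35, 5 / 3),
               tolerance = 1e-12)
  expect_equal(e200$expected_rounded, c(58L, 105L, 35L, 2L))
  expect_equal(unname(expected_counts(null, 0)$expected), rep(0, 4))
  # 120 species give exact integers
  expect_equal(unname(expected_counts(null, 120)$expected), c(35, 63, 21, 1))
})

test_that("goodness-of-fit uses unrounded expectations and the upper tail", {
  null <- null_probabilities(10, 3)
  all200 <- chisq_gof(c(13, 50, 106, 31), null)
  expect_equal(all200$statistic, 724.3, tolerance = 0.1 / 724.3)
  expect_equal(all200$df, 3L)
  expect_lt(all200$p_value, 1e-4)
  weak <- chisq_gof(c(4, 24, 57, 15), null)
  expect_equal(weak$statistic, 367.2, tolerance = 0.1 / 367.2)
  strong <- chisq_gof(c(9, 26, 49, 16), null)
  expect_equal(strong$statistic, 360.1, tolerance = 0.1 / 360.1)
  # O = E exactly -> statistic 0
  expect_equal(chisq_gof(c(35, 63, 21, 1), null)$statistic, 0)
  # permutation of categories permutes nothing about the statistic
  null_flip <- null
  null_flip$probabilities <- rev(null$probabilities)
  expect_equal(chisq_gof(rev(c(13, 50, 106, 31)), null_flip)$statistic,
               all200$statistic)
})

test_that("homogeneity test matches the 2xR contingency chi-square", {
  h <- chisq_homogeneity(c(4, 24, 57, 15), c(9, 26, 49, 16))
  expect_equal(h$statistic, 2.64, tolerance = 0.01 / 2.64)
  expect_equal(h$df, 3)
  expect_equal(h$p_value, 0.45, tolerance = 0.02)
  expect_equal(chisq_homogeneity(c(5, 6, 7), c(5, 6, 7))$statistic, 0)
  # closed-form 2x2 oracle: n(ad - bc)^2 / row/col products
  a <- 12; b <- 8; c <- 5; d <- 15
  n <- a + b + c + d
  oracle <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(chisq_homogeneity(c(a, b), c(c, d))$statistic, oracle)
  # empty category dropped with a warning, df reduced
  expect_warning(h0 <- chisq_homogeneity(c(3, 0, 7), c(4, 0, 6)),
                 "empty categor")
  expect_equal(h0$df, 1)
})

test_that("correct-identification counts are set intersections", {
  expect_equal(count_correct(c("a", "b", "c"), c("a", "b", "c")), 3)
  expect_equal(count_correct(c("a", "b", "c"), c("d", "e", "f")), 0)
  expect_equal(count_correct(c("a", "b", "c"), c("a", "b", "z")), 2)
  expect_error(count_correct(c("a", "b"), c("a", "b", "c")), "same size")
})

test_that("accuracy metrics match hand enumeration on a toy raster", {
  g <- grid_spec(n_cols = 4, n_rows = 4, resolution = 1, origin_x = 0,
                 origin_y = 0)
  # agreement raster (rows north -> south), n_best = 2
  agree <- matrix(c(2, 2, 1, 0,
                    2, 1, 0, 0,
                    1, 0, 0, 0,
                    0, 0, 0, 0), 4, 4, byrow = TRUE)
  # test presences on the three agreement-2 cells plus one agreement-0 cell
  tp <- cell_centroids(g, c(1L, 2L, 5L, 16L))
  bg <- cell_centroids(g, c(4L, 8L, 12L, 13L, 14L, 15L))  # all agreement 0
  acc <- accuracy_metrics(agree, g, tp, bg, n_best = 2)
  expect_equal(acc$total_omission, 25)            # 1 of 4 on agreement 0
  expect_equal(acc$average_omission, 100 * mean(1 - c(2, 2, 2, 0) / 2))
  expect_equal(acc$total_commission, 100 * 3 / 16)
  expect_equal(acc$average_commission, 100 * mean(agree / 2))
  # hand ROC: thresholds 0..3 give (FPR, TPR) = (1,1), (0,.75), (0,.75),
  # (0,0); the trapezoid between (0,.75) and (1,1) has area .875, matching
  # the rank statistic P(a_pres > a_bg) + 0.5 P(tie) = 3/4 + 1/8
  expect_equal(acc$auc, 0.875)
  expect_error(accuracy_metrics(agree, g, tp[0, ], bg, 2), "empty")
})

test_that("agreement AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  g <- grid_spec(n_cols = 10, n_rows = 10, resolution = 1, origin_x = 0,
                 origin_y = 0)
  set.seed(31)
  agree <- matrix(sample(0:10, 100, replace = TRUE), 10, 10)
  tp_cells <- sample(100, 30)
  bg_cells <- sample(100, 40, replace = TRUE)
  acc <- accuracy_metrics(agree, g, cell_centroids(g, tp_cells),
                          cell_centroids(g, bg_cells), n_best = 10)
  av <- as.vector(t(agree))
  roc <- pROC::roc(response = rep(c(1, 0), c(30, 40)),
                   predictor = c(av[tp_cells], av[bg_cells]),
                   quiet = TRUE, direction = "<")
  expect_equal(acc$auc, as.numeric(pROC::auc(roc)), tolerance = 1e-9)
})

test_that("degenerate agreement rasters bound the AUC", {
  g <- grid_spec(n_cols = 5, n_rows = 5, resolution = 1, origin_x = 0,
                 origin_y = 0)
  flat <- matrix(0L, 5, 5)
  tp <- cell_centroids(g, 1:5); bg <- cell_centroids(g, 6:25)
  acc <- accuracy_metrics(flat, g, tp, bg, n_best = 10)
  expect_equal(acc$auc, 0.5)
  expect_equal(acc$total_omission, 100)
  # perfect separation: presences at n_best, everything else 0
  sep <- matrix(0L, 5, 5); sep[1, ] <- 10L
  acc2 <- accuracy_metrics(sep, g, cell_centroids(g, 1:5),
                           cell_centroids(g, 6:25), n_best = 10)
  expect_equal(acc2$auc, 1)
  expect_equal(acc2$total_omission, 0)
})

test_that("a tiny simulation study returns scored species and tests", {
  ls <- tiny_landscape(n = 25, seed = 5, n_exp = 2, n_sph = 2)
  res <- suppressWarnings(run_simulation_study(
    n_per_scenario = 2, landscape = ls,
    params = garp_params(n_models = 6, max_iterations = 10,
                         resample_size = 150, n_background = 150),
    subset_args = list(n_low_omission = 6, n_best = 3,
                       omission_threshold = 100),
    seed = 42))
  expect_s3_class(res, "ui_validation")
  expect_equal(nrow(res$scores), 4)
  expect_true(all(res$scores$r[!res$scores$failed] %in% 0:3))
  expect_setequal(unique(res$tallies$scenario), c("weak", "strong", "all"))
  expect_equal(sum(res$tallies$observed[res$tallies$scenario == "all"]),
               sum(!res$scores$failed))
  expect_true(all(c("gof", "homogeneity") %in% res$tests$test))
  # the null for 4 covariates, 3 drawn
  expect_equal(res$null$n, 4L)
  g <- glance(res)
  expect_equal(g$n_species + g$n_failed, 4)
})
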