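r_presence <- function(...) rule_range(list(...), consequent = "presence")

test_that("dominant rules are the smallest prefix strictly above the cutoff", {
  specs <- list(r_presence(cov01 = c(0, 1)), r_presence(cov02 = c(0, 1)),
                r_presence(cov03 = c(0, 1)), r_presence(cov04 = c(0, 1)))
  # coverages 0.50, 0.30, 0.15, 0.05 over 100 presence decisions
  bs <- fake_best_subset(specs, c(50, 30, 15, 5))
  dom <- dominant_presence_rules(bs)
  expect_equal(nrow(dom), 3)                       # 0.95 > 0.90
  expect_equal(dom$coverage, c(0.50, 0.30, 0.15))
  expect_equal(dom$cum_coverage[3], 0.95)

  # a single all-covering rule stands alone
  bs1 <- fake_best_subset(specs[1], 80)
  expect_equal(nrow(dominant_presence_rules(bs1)), 1)

  # 0.90 is not > 0.90: both rules kept
  bs2 <- fake_best_subset(specs[1:2], c(90, 10))
  expect_equal(nrow(dominant_presence_rules(bs2)), 2)

  # absence-only predictions are an error
  bs0 <- fake_best_subset(specs[1], 0)
  expect_error(dominant_presence_rules(bs0), "presence nowhere")
})

test_that("prevalence counts rule references per covariate", {
  specs <- c(rep(list(r_presence(cov01 = c(0, 1))), 9),
             list(r_presence(cov01 = c(0, 1), cov02 = c(0, 1))))
  bs <- fake_best_subset(specs, rep(10, 10))
  dom <- dominant_presence_rules(bs, cutoff = 0.99)
  expect_equal(nrow(dom), 10)
  expect_equal(prevalence("cov01", dom), 1.0)
  expect_equal(prevalence("cov02", dom), 0.1)
  expect_equal(prevalence("cov99", dom), 0.0)

  # 3 of 12 rules reference the covariate -> 0.25
  specs2 <- c(rep(list(r_presence(cov01 = c(0, 1))), 9),
              rep(list(r_presence(cov02 = c(0, 1))), 3))
  dom2 <- dominant_presence_rules(fake_best_subset(specs2, rep(5, 12)),
                                  cutoff = 0.99)
  expect_equal(prevalence("cov02", dom2), 0.25)
})

test_that("rule bounds come from stored envelopes, atoms, or zonal statistics", {
  g <- grid_spec(n_cols = 10, n_rows = 10)
  specs <- list(r_presence(temp = c(10.2, 13.5)),
                rule_atomic(c(temp = 12.5)),
                rule_logit(c(temp = 2), intercept = 0))
  bs <- fake_best_subset(specs, c(40, 30, 30), grid = g)
  # a landscape whose temp values are known on the logit rule's cells
  temp <- matrix(seq(8, 14, length.out = 100), 10, 10, byrow = TRUE)
  ls <- landscape(g, list(temp = temp))
  dom <- dominant_presence_rules(bs, cutoff = 0.99)
  expect_equal(rule_bounds(which(dom$rule == 1), "temp", dom), c(10.2, 13.5))
  expect_equal(rule_bounds(which(dom$rule == 2), "temp", dom), c(12.5, 12.5))
  # zonal min/max over the 30 cells the logit rule decides (cells 71..100)
  i3 <- which(dom$rule == 3)
  zonal <- range(as.vector(t(temp))[attr(dom, "cells")[[i3]]])
  expect_equal(rule_bounds(i3, "temp", dom, ls), zonal)
  expect_null(rule_bounds(which(dom$rule == 1), "other", dom))
})

test_that("median range is the difference of bound medians", {
  specs <- list(r_presence(cov01 = c(10, 20)), r_presence(cov01 = c(12, 18)),
                r_presence(cov01 = c(11, 25)))
  dom <- dominant_presence_rules(fake_best_subset(specs, c(40, 30, 29)),
                                 cutoff = 0.99)
  expect_equal(median_range("cov01", dom), 20 - 11)

  dom1 <- dominant_presence_rules(fake_best_subset(
    list(r_presence(cov01 = c(0, 1))), 50))
  expect_equal(median_range("cov01", dom1), 1)

  same <- rep(list(r_presence(cov01 = c(3, 7))), 4)
  dom2 <- dominant_presence_rules(fake_best_subset(same, rep(10, 4)),
                                  cutoff = 0.99)
  expect_equal(median_range("cov01", dom2), 4)
  # atomic rules contribute degenerate intervals
  dom3 <- dominant_presence_rules(fake_best_subset(
    list(rule_atomic(c(cov01 = 5))), 10))
  expect_equal(median_range("cov01", dom3), 0)
  expect_true(is.na(median_range("cov99", dom3)))
})

test_that("scaled median range divides by the landscape span and clips", {
  g <- grid_spec(n_cols = 2, n_rows = 2)
  ls <- landscape(g, list(cov01 = matrix(c(0, 12, 24, 36), 2, 2)))
  expect_equal(scaled_median_range("cov01", 36, ls), 1)
  expect_equal(scaled_median_range("cov01", 9, ls), 0.25)
  expect_equal(scaled_median_range("cov01", 0, ls), 0)
  expect_equal(scaled_median_range("cov01", 99, ls), 1)  # clipped
  ls_const <- landscape(g, list(cov01 = matrix(5, 2, 2)))
  expect_error(scaled_median_range("cov01", 1, ls_const), "constant")
})

test_that("the unimportance index follows its defining identities", {
  expect_equal(unimportance_index(1.0, 0.7), 0)
  expect_equal(unimportance_index(0.25, 0.4), 0.3)
  expect_equal(rescale_ui(c(0.1, 0.3, 0.5)), c(0, 0.5, 1))
  expect_warning(z <- rescale_ui(c(0.2, 0.2, 0.2)), "equal")
  expect_equal(z, c(0, 0, 0))

  # property checks over generated inputs
  set.seed(202)
  for (i in 1:50) {
    prev <- runif(1); smr <- runif(1)
    expect_equal(unimportance_index(1, smr), 0)
    expect_equal(unimportance_index(prev, 0), 0)
    # monotone: increasing in range, decreasing in prevalence
    expect_gte(unimportance_index(prev, min(smr + 0.1, 1)),
               unimportance_index(prev, smr))
    expect_lte(unimportance_index(min(prev + 0.1, 1), smr),
               unimportance_index(prev, smr))
    # rescaling is invariant to positive affine transformation
    ui <- runif(5)
    a <- runif(1, 0.1, 5); b <- runif(1, -2, 2)
    expect_equal(rescale_ui(a * ui + b), rescale_ui(ui))
  }
})

test_that("variable selection keeps strictly-below-threshold covariates", {
  ct <- tibble::tibble(covariate = c("a", "b", "c"),
                       ui = c(0.05, 0.2, 0.4),
                       rescaled_ui = c(0, 0.43, 1))
  expect_equal(select_variables(ct, 0.5), c("a", "b"))
  # the maximum rescaled UI (1.0) is excluded at threshold 1 (strict <)
  expect_equal(select_variables(ct, 1.0), c("a", "b"))
  expect_equal(select_variables(ct, 1.0 + 1e-9), c("a", "b", "c"))
  expect_warning(lowest <- select_variables(ct, 0), "lowest-UI")
  expect_equal(lowest, "a")
})

test_that("contribution tables rank and flag covariates coherently", {
  ls <- plateau_landscape(n = 24, seed = 3)
  sp <- plateau_species(ls, n_points = 40, seed = 4)
  ex <- run_experiment(sp$presences, ls,
                       garp_params(n_models = 8, max_iterations = 25,
                                   resample_size = 300, n_background = 300),
                       seed = 5)
  bs <- suppressWarnings(best_subset(ex, n_low_omission = 8, n_best = 4))
  ct <- variable_contribution(bs, ls)
  expect_s3_class(ct, "ui_contribution")
  expect_setequal(ct$covariate, names(ls$covariates))
  expect_true(all(ct$prevalence >= 0 & ct$prevalence <= 1))
  expect_true(all(ct$scaled_median_range >= 0 & ct$scaled_median_range <= 1))
  expect_true(all(ct$rescaled_ui >= 0 & ct$rescaled_ui <= 1))
  expect_setequal(ct$rank, seq_len(nrow(ct)))
  expect_equal(min(ct$rescaled_ui), 0)
  expect_equal(max(ct$rescaled_ui), 1)
  # the plateau driver is the most important covariate
  expect_equal(ct$covariate[ct$rank == 1], "cov01")
})

test_that("true drivers have lower rescaled UI than decoys across species", {
  study <- get_scaled_study()
  ok <- study$scores[!study$scores$failed, ]
  strong <- ok[ok$scenario == "strong", ]
  wt <- stats::wilcox.test(strong$mean_rui_true, strong$mean_rui_decoy,
                           paired = TRUE, alternative = "less", exact = FALSE)
  expect_lt(wt$p.value, 0.05)
  # and pooled across both scenarios
  wt_all <- stats::wilcox.test(ok$mean_rui_true, ok$mean_rui_decoy,
                               paired = TRUE, alternative = "less",
                               exact = FALSE)
  expect_lt(wt_all$p.value, 0.05)
})
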