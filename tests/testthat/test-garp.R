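test_that("internal splits are disjoint with the documented rounding", {
  pts <- tibble::tibble(x = runif(50), y = runif(50))
  sp <- internal_split(pts, 0.75, seed = 3)
  expect_equal(nrow(sp$train), 38)   # round(37.5) half-up
  expect_equal(nrow(sp$test), 12)
  expect_equal(nrow(dplyr::intersect(sp$train, sp$test)), 0)
  pts657 <- tibble::tibble(x = runif(657), y = runif(657))
  expect_equal(nrow(internal_split(pts657, 0.75, 1, rule = "down")$train),
               492)  # floor(492.75)
  expect_equal(nrow(internal_split(pts657, 0.75, 1)$train), 493)
  # at least one point on each side
  tiny <- tibble::tibble(x = 1:2, y = 1:2)
  sp2 <- internal_split(tiny, 0.99, seed = 1)
  expect_equal(nrow(sp2$test), 1)
  expect_error(internal_split(pts, 1.5, seed = 1), "between 0 and 1")
  expect_identical(internal_split(pts, 0.75, seed = 9),
                   internal_split(pts, 0.75, seed = 9))
})

test_that("background samples are uniform in-extent centroids", {
  ls <- tiny_landscape(n = 12, seed = 2, n_exp = 1, n_sph = 1)
  bg <- sample_background(ls, 1250, seed = 5)
  expect_equal(nrow(bg), 1250)
  g <- ls$grid
  expect_true(all(bg$x > g$origin_x & bg$x < g$origin_x + g$n_cols * g$resolution))
  expect_true(all(bg$y > g$origin_y & bg$y < g$origin_y + g$n_rows * g$resolution))
  expect_equal(point_to_cell(g, bg$x, bg$y), bg$cell)
  expect_identical(bg, sample_background(ls, 1250, seed = 5))
  expect_equal(nrow(sample_background(ls, 1, seed = 1)), 1)
})

test_that("evolution is deterministic and obeys the stopping rule", {
  ls <- plateau_landscape(n = 20, seed = 8)
  sp <- plateau_species(ls, n_points = 30, seed = 9)
  par <- garp_params(n_models = 1, max_iterations = 15, resample_size = 200,
                     n_background = 200)
  rs1 <- evolve_ruleset(sp$presences, ls, par, seed = 4)
  rs2 <- evolve_ruleset(sp$presences, ls, par, seed = 4)
  expect_identical(rs1$pop, rs2$pop)
  expect_identical(rs1$stats, rs2$stats)
  expect_length(rs1, 50)
  # an infinite convergence threshold stops the run immediately
  par_inf <- garp_params(n_models = 1, max_iterations = 15,
                         resample_size = 200, n_background = 200,
                         convergence = Inf)
  rs_inf <- evolve_ruleset(sp$presences, ls, par_inf, seed = 4)
  expect_equal(rs_inf$meta$iterations, 1L)
  expect_true(rs_inf$meta$converged)
})

test_that("a separable species yields envelopes bracketing the true region", {
  ls <- plateau_landscape(n = 24, seed = 13)
  sp <- plateau_species(ls, n_points = 40, seed = 14)
  rs <- evolve_ruleset(sp$presences, ls,
                       garp_params(max_iterations = 40, resample_size = 400,
                                   n_background = 400), seed = 6)
  # the top-ranked presence rule constrains the driver, and its envelope
  # brackets the presence plateau (values near +1) within the plateau width
  top <- ruleset_rule(rs, 1)
  expect_equal(top$consequent, "presence")
  expect_true("cov01" %in% garpui:::rule_covariates(top))
  b <- if (top$rule_type == "logit") NULL else top$bounds[["cov01"]]
  if (!is.null(b)) {
    expect_lt(b[1], 1)        # lower bound below the plateau values
    expect_gt(b[1], -1)       # but above the absence plateau
    expect_gte(b[2], 0.8)
  }
})

test_that("experiments evaluate every model within range", {
  ls <- plateau_landscape(n = 20, seed = 18)
  sp <- plateau_species(ls, n_points = 30, seed = 19)
  ex <- run_experiment(sp$presences, ls,
                       garp_params(n_models = 5, max_iterations = 15,
                                   resample_size = 200, n_background = 200),
                       seed = 21)
  ev <- tidy(ex)
  expect_equal(nrow(ev), 5)
  expect_true(all(ev$omission >= 0 & ev$omission <= 100))
  expect_true(all(ev$commission >= 0 & ev$commission <= 100))
  expect_false(any(ev$failed))
  # perfectly learnable species: the models rarely miss internal test points
  expect_lte(median(ev$omission), 10)
  ex2 <- run_experiment(sp$presences, ls,
                        garp_params(n_models = 5, max_iterations = 15,
                                    resample_size = 200, n_background = 200),
                        seed = 21)
  expect_identical(tidy(ex2), ev)
  g <- glance(ex)
  expect_equal(g$n_models, 5)
})

test_that("best-subset selection matches the brute-force oracle", {
  set.seed(91)
  for (rep in 1:20) {
    om <- round(runif(25, 0, 30), 1)
    cm <- round(runif(25, 10, 90), 1)
    ev <- tibble::tibble(omission = om, commission = cm)
    qualifying <- sum(om <= 10)
    if (qualifying == 0) {
      expect_error(select_best_subset(ev), "omission threshold")
      next
    }
    sel <- if (qualifying < 10) {
      expect_warning(s <- select_best_subset(ev), "fewer than")
      s
    } else {
      select_best_subset(ev)
    }
    expect_equal(sel$indices, best_subset_brute_force(om, cm))
  }
  # exact selection size with a full pool
  ev20 <- tibble::tibble(omission = rep(5, 20), commission = 1:20)
  s20 <- select_best_subset(ev20)
  expect_length(s20$indices, 10)
  expect_equal(s20$median_commission, 10.5)
  # commissions nearest the median are kept: 6..15
  expect_equal(s20$indices, 6:15)
})

test_that("agreement rasters sum the member projections", {
  ls <- plateau_landscape(n = 16, seed = 23)
  sp <- plateau_species(ls, n_points = 25, seed = 24)
  ex <- run_experiment(sp$presences, ls,
                       garp_params(n_models = 6, max_iterations = 10,
                                   resample_size = 150, n_background = 150),
                       seed = 25)
  bs <- suppressWarnings(best_subset(ex, n_low_omission = 6, n_best = 3,
                                     omission_threshold = 100))
  expect_true(all(bs$agreement >= 0 & bs$agreement <= bs$n_best))
  manual <- Reduce(`+`, lapply(bs$models, function(m) m$prediction))
  expect_equal(as.vector(t(bs$agreement)), manual)
  # agreement-weighted prediction tracks the true distribution
  truth <- as.vector(t(sp$realized))
  rho <- cor(as.vector(t(bs$agreement)), truth, method = "spearman")
  expect_gt(rho, 0.3)
})
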