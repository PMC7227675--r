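test_that("rule firing honours bounds, negation, logistic threshold, atoms", {
  r <- rule_range(list(temp = c(10.2, 13.5), ndvi = c(0.15, 0.23)))
  expect_true(rule_fires(r, c(temp = 12.0, ndvi = 0.2)))
  expect_true(rule_fires(r, c(temp = 13.5, ndvi = 0.15)))  # inclusive bounds
  expect_false(rule_fires(r, c(temp = 13.6, ndvi = 0.2)))
  nr <- rule_negated_range(list(temp = c(10.2, 13.5), ndvi = c(0.15, 0.23)))
  expect_false(rule_fires(nr, c(temp = 12.0, ndvi = 0.2)))
  expect_true(rule_fires(nr, c(temp = 9.0, ndvi = 0.2)))
  lg <- rule_logit(c(temp = 1), intercept = -10)
  expect_true(rule_fires(lg, c(temp = 11)))   # eta > 0
  expect_false(rule_fires(lg, c(temp = 9)))
  at <- rule_atomic(c(temp = 12.5))
  expect_true(rule_fires(at, c(temp = 12.5)))
  expect_true(rule_fires(at, c(temp = 12.52), tol = c(temp = 0.1)))
  expect_false(rule_fires(at, c(temp = 12.58), tol = c(temp = 0.1)))
  expect_error(rule_fires(r, c(temp = 12.0)), "ndvi")
  expect_error(rule_range(list(temp = c(5, 2))), "lower <= upper")
})

test_that("the compiled kernel agrees with the reference evaluator", {
  set.seed(55)
  covn <- c("a", "b", "c")
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, covn))
  rules <- list(
    rule_range(list(a = c(-0.5, 0.5))),
    rule_range(list(a = c(-1, 1), b = c(0, 2)), consequent = "absence"),
    rule_negated_range(list(b = c(-0.3, 0.3))),
    rule_logit(c(a = 1.2, c = -0.7), intercept = 0.1),
    rule_atomic(c(b = 0.25)),
    rule_range(list(c = c(-2, 0)))
  )
  tol <- c(a = 0.2, b = 0.2, c = 0.2)
  rs <- ruleset(rules, covariates = covn, tol = tol)
  fires_cpp <- garpui:::eval_rules_cpp(X, rs$pop$type, rs$pop$lo, rs$pop$hi,
                                       rs$pop$coef, unname(tol[covn]))
  for (i in seq_along(rules)) {
    ref <- rule_fires(rules[[i]], as.data.frame(X), tol = tol)
    expect_equal(as.logical(fires_cpp[, i]), ref, label = paste("rule", i))
  }
})

test_that("rule scoring builds the 2x2 chi-square without correction", {
  # a rule firing exactly on all presences in a balanced sample of 100
  d <- data.frame(a = rep(c(0, 10), each = 50), label = rep(c(1, 0), each = 50))
  perfect <- rule_range(list(a = c(-1, 1)))
  s <- score_rule(perfect, d)
  expect_equal(s$chisq, 100)
  expect_equal(s$accuracy, 1)
  expect_true(s$significant)
  # independence: firing unrelated to the label
  d2 <- data.frame(a = rep(c(0, 10), 50), label = rep(c(1, 0), each = 50))
  s2 <- score_rule(rule_range(list(a = c(-1, 1))), d2)
  expect_equal(s2$chisq, 0)
  # firing nowhere: degenerate, flagged
  s3 <- score_rule(rule_range(list(a = c(100, 200))), d)
  expect_true(s3$degenerate)
  expect_false(s3$significant)
  expect_true(is.na(s3$accuracy))
  # cross-check against R's chi-square test on a non-degenerate table
  d4 <- data.frame(a = c(rep(0, 40), rep(10, 60)),
                   label = rep(c(1, 0), 50))
  s4 <- score_rule(rule_range(list(a = c(-1, 1))), d4)
  tab <- table(d4$a < 5, d4$label)
  expect_equal(s4$chisq,
               unname(stats::chisq.test(tab, correct = FALSE)$statistic))
})

test_that("projection is first-match-wins with absent default", {
  g <- grid_spec(n_cols = 3, n_rows = 3, resolution = 1, origin_x = 0,
                 origin_y = 0)
  ls <- landscape(g, list(a = matrix(1:9, 3, 3, byrow = TRUE),
                          b = matrix(9:1, 3, 3, byrow = TRUE)))
  rs <- ruleset(list(rule_range(list(a = c(2, 5))),
                     rule_range(list(b = c(1, 3)), consequent = "absence")),
                covariates = c("a", "b"))
  proj <- project(rs, ls)
  oracle <- project_brute_force(rs, ls)
  expect_identical(proj$prediction, oracle$prediction)
  expect_identical(proj$rule_index, oracle$rule_index)
  # hand check: cells with a in 2..5 fire rule 1 (presence); of the rest,
  # cells with b in 1..3 fire rule 2 (absence); others default absent, -1
  expect_equal(as.vector(t(proj$prediction)), c(0, 1, 1, 1, 1, 0, 0, 0, 0))
  expect_equal(as.vector(t(proj$rule_index)), c(-1, 1, 1, 1, 1, -1, 2, 2, 2))

  always <- ruleset(list(rule_logit(c(a = 0), intercept = 5)),
                    covariates = c("a", "b"))
  expect_true(all(project(always, ls)$prediction == 1L))
  never <- ruleset(list(rule_range(list(a = c(100, 101)))),
                   covariates = c("a", "b"))
  p0 <- project(never, ls)
  expect_true(all(p0$prediction == 0L))
  expect_true(all(p0$rule_index == -1L))
})

test_that("projection of random rulesets matches brute force and repeats", {
  ls <- tiny_landscape(n = 8, seed = 77, n_exp = 1, n_sph = 2)
  set.seed(42)
  for (rep in 1:3) {
    rules <- list(
      rule_range(setNames(list(sort(rnorm(2))), sample(names(ls$covariates), 1))),
      rule_negated_range(setNames(list(sort(rnorm(2))),
                                  sample(names(ls$covariates), 1))),
      rule_logit(setNames(rnorm(2), sample(names(ls$covariates), 2)),
                 intercept = rnorm(1))
    )
    rs <- ruleset(rules, covariates = names(ls$covariates))
    proj <- project(rs, ls)
    oracle <- project_brute_force(rs, ls)
    expect_identical(proj, oracle)
    expect_identical(proj, project(rs, ls))  # purely functional
  }
})

test_that("rulesets round-trip through JSON and the text listing", {
  rules <- list(
    rule_range(list(cov01 = c(-0.25, 1.5), cov02 = c(0, 2))),
    rule_negated_range(list(cov01 = c(-1, -0.5))),
    rule_logit(c(cov02 = 0.33, cov03 = -1.75), intercept = 0.5),
    rule_atomic(c(cov03 = -0.125))
  )
  rs <- ruleset(rules, covariates = c("cov01", "cov02", "cov03"),
                tol = c(cov01 = 0.1, cov02 = 0.1, cov03 = 0.1))
  jp <- withr::local_tempfile(fileext = ".json")
  write_ruleset_json(rs, jp)
  rs2 <- read_ruleset_json(jp)
  expect_equal(rs2$pop, rs$pop)
  expect_equal(rs2$covariates, rs$covariates)
  expect_equal(rs2$tol, rs$tol)

  tp <- withr::local_tempfile(fileext = ".txt")
  write_ruleset_text(rs, tp)
  lines <- readLines(tp)
  expect_length(lines, 4)
  expect_match(lines[1], "^IF cov01=\\(.+\\) AND cov02=\\(.+\\) THEN species=PRESENCE$")
  expect_match(lines[2], "^IF NOT ")
  rs3 <- parse_ruleset_text(tp, covariates = rs$covariates, tol = rs$tol)
  expect_equal(rs3$pop, rs$pop)
})
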