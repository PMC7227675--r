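# Shared fixtures, built in code at test time.

# small landscape for fast engine tests
tiny_landscape <- function(n = 30, seed = 404, n_exp = 2, n_sph = 2) {
  simulate_landscape(grid_spec(n_cols = n, n_rows = n),
                     n_exponential = n_exp, n_spherical = n_sph, seed = seed)
}

# A perfectly separable toy: cov01 is a two-plateau field (-1 west, +1 east,
# small within-plateau jitter) plus independent noise decoys; the species
# occupies the +1 plateau. Any learned envelope that lands inside the wide
# value gap between the plateaus classifies every cell perfectly.
plateau_landscape <- function(n = 30, seed = 11, jitter = 0.05, n_decoys = 2) {
  g <- grid_spec(n_cols = n, n_rows = n)
  set.seed(seed)
  plate <- matrix(rep(c(-1, 1), each = n / 2), nrow = n, ncol = n,
                  byrow = TRUE) + matrix(rnorm(n * n, 0, jitter), n, n)
  covs <- c(list(cov01 = plate),
            lapply(seq_len(n_decoys), function(i) matrix(rnorm(n * n), n, n)))
  names(covs) <- sprintf("cov%02d", seq_along(covs))
  landscape(g, covs)
}

plateau_species <- function(ls, n_points = 50, seed = 12) {
  realized <- (ls$covariates$cov01 > 0) * 1L
  list(realized = realized,
       presences = sample_presences(realized, ls$grid, n_points, seed = seed))
}

# brute-force projection oracle: evaluate every rule on every cell with the
# reference rule_fires(), first match wins
project_brute_force <- function(rs, ls) {
  g <- ls$grid
  X <- landscape_values(ls)
  pred <- integer(nrow(X)); idx <- rep(-1L, nrow(X))
  rules <- lapply(seq_len(length(rs)), function(i) ruleset_rule(rs, i))
  for (cell in seq_len(nrow(X))) {
    vals <- X[cell, ]
    for (i in seq_along(rules)) {
      if (rule_fires(rules[[i]], vals, tol = rs$tol)) {
        pred[cell] <- as.integer(rules[[i]]$consequent == "presence")
        idx[cell] <- i
        break
      }
    }
  }
  list(prediction = matrix(pred, g$n_rows, g$n_cols, byrow = TRUE),
       rule_index = matrix(idx, g$n_rows, g$n_cols, byrow = TRUE))
}

# brute-force best-subset oracle mirroring the documented selection rules
best_subset_brute_force <- function(om, cm, threshold = 10, n_low = 20,
                                    n_best = 10) {
  idx <- which(om <= threshold)
  pool <- idx[order(om[idx], cm[idx], idx)]
  pool <- pool[seq_len(min(n_low, length(pool)))]
  med <- median(cm[pool])
  sel <- pool[order(abs(cm[pool] - med), om[pool], pool)]
  sort(sel[seq_len(min(n_best, length(sel)))])
}

# fabricate a garp_best_subset with prescribed per-rule presence decisions,
# for unit-testing the dominant-rule/coverage logic in isolation
fake_best_subset <- function(rule_specs, n_cells_per_rule, grid = grid_spec(
                               n_cols = 10, n_rows = 10)) {
  stopifnot(length(rule_specs) == length(n_cells_per_rule),
            sum(n_cells_per_rule) <= n_cells(grid))
  rs <- ruleset(rule_specs)
  pred <- integer(n_cells(grid)); idx <- rep(-1L, n_cells(grid))
  at <- 1L
  for (i in seq_along(rule_specs)) {
    n_i <- n_cells_per_rule[i]
    if (n_i > 0) {
      cells <- at:(at + n_i - 1L)
      pred[cells] <- 1L
      idx[cells] <- i
      at <- at + n_i
    }
  }
  structure(list(models = list(list(ruleset = rs, prediction = pred,
                                    rule_index = idx)),
                 evaluations = tibble::tibble(model = 1, omission = 0,
                                              commission = 0),
                 agreement = matrix(pred, grid$n_rows, grid$n_cols,
                                    byrow = TRUE),
                 n_best = 1L, median_commission = 0, grid = grid,
                 short = TRUE),
            class = "garp_best_subset")
}
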