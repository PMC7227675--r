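#' Genetic-algorithm engine parameters
#'
#' Tunables of the rule-evolution engine, with defaults matching the
#' benchmark configuration: models of 50 rules, up to 1,000 iterations or a
#' convergence of 0.01 (absolute change between generations in the whole
#' ruleset's predictive accuracy on a fixed monitor sample), an internal
#' resample of 1,250 presence draws plus 1,250
#' background pseudo-absences per generation, rule significance at
#' chi-square >= 3.84 (alpha 0.05, 1 df), and genetic operator rates
#' crossover 0.25, point mutation 0.25, insertion 0.1, deletion 0.1 (the
#' remainder of each offspring batch is fresh random rules). Covariates are
#' binned to 254 levels for atomic rules, mirroring 8-bit raster grids.
#'
#' @param n_models Models per experiment.
#' @param rules_per_model Rules per ruleset.
#' @param max_iterations Generation cap.
#' @param convergence Convergence threshold on the absolute change in the
#'   ruleset's predictive accuracy between generations.
#' @param resample_size Presence draws (with replacement) per generation.
#' @param n_background Background pseudo-absence draws per generation.
#' @param chisq_crit Rule significance cutoff.
#' @param p_crossover,p_mutation,p_insertion,p_deletion Operator rates.
#' @param n_offspring Base number of offspring per generation; the engine
#'   breeds `offspring_oversample * n_offspring` candidates and
#'   truncation-selects the next population from the union of the current
#'   population and the candidates ((mu + lambda) selection).
#' @param init_oversample Initial population oversampling factor: the start
#'   population is the best `rules_per_model` of
#'   `init_oversample * rules_per_model` random rules.
#' @param offspring_oversample Candidate oversampling factor per generation.
#' @param type_quotas Named population shares per rule archetype
#'   (`range`, `logit`, `atomic`, `absence`); quotas keep the archetypes in
#'   competition so no single rule family takes over the population.
#' @param split_fraction Internal training fraction.
#' @param split_rule Rounding rule for the split, `"half_up"` or `"down"`.
#' @param n_bins Discretisation levels defining the atomic binning tolerance.
#' @return A `garp_params` list.
#' @export
garp_params <- function(n_models = 200, rules_per_model = 50,
                        max_iterations = 1000, convergence = 0.01,
                        resample_size = 1250, n_background = 1250,
                        chisq_crit = 3.84,
                        p_crossover = 0.25, p_mutation = 0.25,
                        p_insertion = 0.1, p_deletion = 0.1,
                        n_offspring = 20,
                        init_oversample = 4, offspring_oversample = 3,
                        type_quotas = c(range = 0.4, logit = 0.2,
                                        atomic = 0.2, absence = 0.2),
                        split_fraction = 0.75, split_rule = "half_up",
                        n_bins = 254) {
  stopifnot(rules_per_model >= 2, max_iterations >= 1, n_offspring >= 1,
            init_oversample >= 1, offspring_oversample >= 1,
            p_crossover + p_mutation + p_insertion + p_deletion <= 1,
            abs(sum(type_quotas) - 1) < 1e-8)
  structure(as.list(environment()), class = "garp_params")
}

#' Split points into internal training and testing sets
#'
#' Disjoint random partition. The training size is
#' `round(fraction * n)` under the default `"half_up"` rounding rule
#' (half-values round up) or `floor(fraction * n)` under `"down"`; at least
#' one point is kept on each side.
#'
#' @param points Tibble/data frame of points.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @param rule `"half_up"` or `"down"`.
#' @return List with `train` and `test` tibbles.
#' @export
internal_split <- function(points, fraction = 0.75, seed, rule = "half_up") {
  n <- nrow(points)
  stopifnot(n >= 2)
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  n_train <- switch(match.arg(rule, c("half_up", "down")),
                    half_up = floor(fraction * n + 0.5),
                    down = floor(fraction * n))
  n_train <- min(max(n_train, 1L), n - 1L)
  i <- withr::with_seed(as.integer(seed), sample.int(n, n_train))
  list(train = points[i, , drop = FALSE], test = points[-i, , drop = FALSE])
}

#' Sample background (pseudo-absence) points
#'
#' Uniform draws of cell centroids from the landscape grid, standing in for
#' absence data in presence-only modelling.
#'
#' @param landscape A `garp_landscape`.
#' @param n Number of points.
#' @param seed Integer seed.
#' @param replace Draw cells with replacement (default TRUE; the background
#'   is a sample of the landscape, not a partition of it).
#' @return Tibble with columns `x`, `y`, `cell`.
#' @export
sample_background <- function(landscape, n = 1250, seed, replace = TRUE) {
  stopifnot(n >= 1)
  g <- landscape$grid
  cells <- withr::with_seed(as.integer(seed),
                            sample.int(n_cells(g), n, replace = replace))
  cell_centroids(g, cells)[, c("x", "y", "cell")]
}

# fresh-rule generators ------------------------------------------------------
# Xp: presence-point covariate values; Xs/y: the current labelled resample.

# envelope rule built from random quantile windows of Xsrc (the rows whose
# label matches the rule's consequent: presence rules envelope presences,
# absence rules envelope background)
fresh_range <- function(pop, i, Xsrc, negated = FALSE, conseq = 1L) {
  p <- ncol(pop$lo)
  k <- min(sample(1:3, 1L, prob = c(0.25, 0.4, 0.35)), p)
  vars <- sample.int(p, k)
  for (v in vars) {
    q <- quantile(Xsrc[, v], c(runif(1, 0, 0.45), runif(1, 0.55, 1)),
                  names = FALSE)
    pop$lo[i, v] <- q[1]; pop$hi[i, v] <- q[2]
  }
  pop$type[i] <- if (negated) 1L else 0L
  pop$conseq[i] <- if (negated) 0L else conseq
  pop
}

fresh_atomic <- function(pop, i, Xp, tol, rng_lo) {
  p <- ncol(pop$lo)
  k <- sample.int(min(2L, p), 1L)
  vars <- sample.int(p, k)
  row <- Xp[sample.int(nrow(Xp), 1L), ]
  for (v in vars) {
    atom <- rng_lo[v] + (floor((row[v] - rng_lo[v]) / tol[v]) + 0.5) * tol[v]
    pop$lo[i, v] <- atom; pop$hi[i, v] <- atom
  }
  pop$type[i] <- 3L
  pop$conseq[i] <- 1L
  pop
}

# logit rules are a logistic-regression superset over ALL covariates (as in
# classic rule-set engines); fitted on a bootstrap replicate of the current
# resample so distinct logit rules differ
fresh_logit <- function(pop, i, Xs, y) {
  p <- ncol(pop$lo)
  b <- sample.int(nrow(Xs), nrow(Xs), replace = TRUE)
  fit <- tryCatch(
    suppressWarnings(glm.fit(cbind(1, Xs[b, , drop = FALSE]), y[b],
                             family = binomial())),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) {
    return(fresh_range(pop, i, Xs[y == 1L, , drop = FALSE]))
  }
  pop$coef[i, ] <- NA_real_
  pop$coef[i, seq_len(p)] <- fit$coefficients[-1]
  pop$coef[i, p + 1L] <- fit$coefficients[1]
  pop$type[i] <- 2L
  pop$conseq[i] <- 1L
  pop
}

clear_row <- function(pop, i) {
  pop$lo[i, ] <- NA_real_; pop$hi[i, ] <- NA_real_; pop$coef[i, ] <- NA_real_
  pop
}

copy_row <- function(pop, to, from) {
  pop$type[to] <- pop$type[from]; pop$conseq[to] <- pop$conseq[from]
  pop$lo[to, ] <- pop$lo[from, ]; pop$hi[to, ] <- pop$hi[from, ]
  pop$coef[to, ] <- pop$coef[from, ]
  pop
}

# genetic operators acting in place on row i -------------------------------

op_mutate <- function(pop, i, span, rng_lo, rng_hi) {
  p <- ncol(pop$lo)
  if (pop$type[i] == 2L) {
    j <- which(!is.na(pop$coef[i, ]))
    v <- j[sample.int(length(j), 1L)]
    pop$coef[i, v] <- pop$coef[i, v] + rnorm(1, 0, 0.25 * abs(pop$coef[i, v]) + 0.1)
  } else {
    j <- which(!is.na(pop$lo[i, ]))
    if (length(j) == 0L) return(pop)
    v <- j[sample.int(length(j), 1L)]
    jitter <- rnorm(1, 0, 0.05 * span[v])
    if (pop$type[i] == 3L) {
      atom <- min(max(pop$lo[i, v] + jitter, rng_lo[v]), rng_hi[v])
      pop$lo[i, v] <- atom; pop$hi[i, v] <- atom
    } else if (runif(1) < 0.5) {
      pop$lo[i, v] <- min(pop$lo[i, v] + jitter, pop$hi[i, v])
    } else {
      pop$hi[i, v] <- max(pop$hi[i, v] + jitter, pop$lo[i, v])
    }
  }
  pop
}

op_insert <- function(pop, i, Xp, span) {
  if (pop$type[i] == 2L) {
    p <- ncol(pop$lo)
    free <- which(is.na(pop$coef[i, seq_len(p)]))
    if (length(free) == 0L) return(pop)
    v <- free[sample.int(length(free), 1L)]
    pop$coef[i, v] <- rnorm(1, 0, 0.5)
  } else {
    free <- which(is.na(pop$lo[i, ]))
    if (length(free) == 0L) return(pop)
    v <- free[sample.int(length(free), 1L)]
    if (pop$type[i] == 3L) {
      pop$lo[i, v] <- Xp[sample.int(nrow(Xp), 1L), v]
      pop$hi[i, v] <- pop$lo[i, v]
    } else {
      q <- quantile(Xp[, v], c(runif(1, 0, 0.45), runif(1, 0.55, 1)),
                    names = FALSE)
      pop$lo[i, v] <- q[1]; pop$hi[i, v] <- q[2]
    }
  }
  pop
}

op_delete <- function(pop, i) {
  if (pop$type[i] == 2L) {
    p <- ncol(pop$lo)
    j <- which(!is.na(pop$coef[i, seq_len(p)]))
    if (length(j) < 2L) return(pop)
    pop$coef[i, j[sample.int(length(j), 1L)]] <- NA_real_
  } else {
    j <- which(!is.na(pop$lo[i, ]))
    if (length(j) < 2L) return(pop)
    v <- j[sample.int(length(j), 1L)]
    pop$lo[i, v] <- NA_real_; pop$hi[i, v] <- NA_real_
  }
  pop
}

op_crossover <- function(pop, i, a, b) {
  pop <- copy_row(pop, i, a)
  if (pop$type[a] == 2L && pop$type[b] == 2L) {
    mix <- runif(ncol(pop$coef)) < 0.5
    pop$coef[i, mix] <- pop$coef[b, mix]
  } else if (pop$type[a] != 2L && pop$type[b] != 2L) {
    mix <- runif(ncol(pop$lo)) < 0.5
    pop$lo[i, mix] <- pop$lo[b, mix]
    pop$hi[i, mix] <- pop$hi[b, mix]
    bad <- !is.na(pop$lo[i, ]) & pop$lo[i, ] > pop$hi[i, ]
    if (any(bad)) {  # mixing can invert bounds; swap to restore the invariant
      tmp <- pop$lo[i, bad]; pop$lo[i, bad] <- pop$hi[i, bad]; pop$hi[i, bad] <- tmp
    }
    if (all(is.na(pop$lo[i, ]))) pop <- copy_row(pop, i, a)
  }
  pop
}

FRESH_KINDS <- c("range", "range_absence", "negated", "logit", "atomic")
FRESH_PROBS <- c(0.35, 0.10, 0.10, 0.20, 0.25)

# rule archetype groups used for the selection quotas: without quotas a
# single archetype (in practice the all-covariate logit fits) takes over the
# population and the ruleset loses the envelope structure the rule types
# are there to provide
pop_groups <- function(pop) {
  ifelse(pop$conseq == 0L, "absence",
         ifelse(pop$type == 2L, "logit",
                ifelse(pop$type == 3L, "atomic", "range")))
}

# truncation-select R rules from a scored pool, honouring per-archetype
# quotas; unfilled quota slots fall back to the global ranking
select_population <- function(comb, sc_comb, R, quotas) {
  grp <- pop_groups(comb)
  rank_all <- order(-as.integer(sc_comb$significant), -sc_comb$chisq,
                    seq_along(grp))
  take <- integer(0)
  for (g in names(quotas)) {
    cand_g <- rank_all[grp[rank_all] == g]
    take <- c(take, head(cand_g, round(quotas[[g]] * R)))
  }
  if (length(take) < R) {
    take <- c(take, setdiff(rank_all, take)[seq_len(R - length(take))])
  }
  take[seq_len(R)]
}

fresh_rule <- function(pop, i, kind, Xp, Xs, y, tol, rng_lo) {
  switch(kind,
         range = fresh_range(pop, i, Xp),
         range_absence = fresh_range(pop, i, Xs[y == 0L, , drop = FALSE],
                                     conseq = 0L),
         negated = fresh_range(pop, i, Xp, negated = TRUE),
         logit = fresh_logit(pop, i, Xs, y),
         atomic = fresh_atomic(pop, i, Xp, tol, rng_lo))
}

init_population <- function(R, Xp, Xs, y, covariates, tol, rng_lo) {
  pop <- pop_new(R, covariates)
  # mixture of starting material: presence envelopes, background (absence)
  # envelopes and complements, logistic fits on the first resample, binned
  # presence atoms
  counts <- c(range = ceiling(0.3 * R), range_absence = ceiling(0.1 * R),
              negated = ceiling(0.1 * R), logit = ceiling(0.2 * R))
  kind <- rep(c(names(counts), "atomic"),
              c(counts, max(R - sum(counts), 0)))[seq_len(R)]
  for (i in seq_len(R)) {
    pop <- fresh_rule(pop, i, kind[i], Xp, Xs, y, tol, rng_lo)
  }
  pop
}

#' Evolve a ruleset from training presences
#'
#' Runs the genetic algorithm: each generation draws a fresh internal
#' resample (presence draws with replacement plus uniform background
#' pseudo-absences), scores every rule by its 2x2 chi-square and predictive
#' accuracy, breeds an oversampled batch of candidates by crossover, point
#' mutation, constraint insertion/deletion, fresh random rules and directed
#' envelope refinement, and truncation-selects the next population from the
#' union of parents and candidates on chi-square significance, within
#' per-archetype quotas ((mu + lambda) selection with implicit elitism).
#' Evolution stops at `max_iterations` or when the change in the whole
#' ruleset's predictive accuracy on a fixed monitor sample falls below
#' `convergence`. The returned rules are ordered for projection by
#' descending chi-square, ties broken by higher accuracy, then original
#' position, so each model's predictions are decided by its most
#' significant rules.
#'
#' @param train Tibble of training presence points (`x`, `y`).
#' @param landscape A `garp_landscape`.
#' @param params A [garp_params()].
#' @param seed Integer seed; identical inputs and seed give an identical
#'   ruleset.
#' @return A `garp_ruleset` with per-rule internal statistics and training
#'   metadata.
#' @export
evolve_ruleset <- function(train, landscape, params = garp_params(), seed) {
  stopifnot(nrow(train) >= 2)
  Xl <- landscape_values(landscape)
  covariates <- colnames(Xl)
  rng <- apply(Xl, 2, range)
  rng_lo <- rng[1, ]; rng_hi <- rng[2, ]
  span <- rng_hi - rng_lo
  tol <- span / params$n_bins
  cells <- point_to_cell(landscape$grid, train$x, train$y)
  Xp <- Xl[cells, , drop = FALSE]
  R <- params$rules_per_model

  state <- withr::with_seed(as.integer(seed), {
    draw_sample <- function() {
      ip <- sample.int(nrow(Xp), params$resample_size, replace = TRUE)
      ib <- sample.int(nrow(Xl), params$n_background, replace = TRUE)
      list(X = rbind(Xp[ip, , drop = FALSE], Xl[ib, , drop = FALSE]),
           y = rep(c(1L, 0L), c(params$resample_size, params$n_background)))
    }
    s <- draw_sample()
    monitor <- draw_sample()  # fixed across generations: the convergence
                              # delta then reflects ruleset change, not
                              # resampling noise
    # (mu + lambda)-style start: oversample random rules, keep the best R
    cand <- init_population(params$init_oversample * R, Xp, s$X, s$y,
                            covariates, tol, rng_lo)
    fires <- eval_rules_cpp(s$X, cand$type, cand$lo, cand$hi, cand$coef, tol)
    sc_cand <- score_population(fires, s$y, cand$conseq, params$chisq_crit)
    # selection fitness is the chi-square significance: it rewards both
    # association strength and coverage, so broad informative rules beat
    # narrow lucky ones; projection order (accuracy) is decided at the end
    top <- select_population(cand, sc_cand, R, params$type_quotas)
    pop <- pop_subset(cand, top)
    sc <- sc_cand[top, ]
    prev_acc <- 0
    converged <- FALSE
    delta <- NA_real_
    it <- 0L
    repeat {
      it <- it + 1L
      fit <- ifelse(is.na(sc$accuracy), -1, sc$accuracy)
      # convergence tracks the whole ruleset's predictive accuracy
      # (first-match-wins in fitness order) on the fixed monitor sample
      ord_now <- order(-fit, -sc$chisq, seq_len(R))
      pred_now <- project_rules_cpp(monitor$X, pop$type[ord_now],
                                    pop$lo[ord_now, , drop = FALSE],
                                    pop$hi[ord_now, , drop = FALSE],
                                    pop$coef[ord_now, , drop = FALSE],
                                    tol, pop$conseq[ord_now])$prediction
      model_acc <- mean(pred_now == monitor$y)
      delta <- abs(model_acc - prev_acc)
      if (delta < params$convergence) { converged <- TRUE; break }
      prev_acc <- model_acc
      if (it >= params$max_iterations) break

      # breed an oversampled batch of candidate rules from the current
      # parents, then truncation-select the next population from the union
      parents <- which(sc$significant)
      if (length(parents) < 2L) parents <- seq_len(R)
      w <- pmax(sc$chisq[parents], 0.01)
      n_cand <- params$offspring_oversample * params$n_offspring
      ops <- sample(c("crossover", "mutation", "insertion", "deletion", "fresh"),
                    n_cand, replace = TRUE,
                    prob = c(params$p_crossover, params$p_mutation,
                             params$p_insertion, params$p_deletion,
                             max(1 - params$p_crossover - params$p_mutation -
                                   params$p_insertion - params$p_deletion, 0)))
      s <- draw_sample()
      cand <- pop_new(n_cand, covariates)
      for (i in seq_len(n_cand)) {
        par <- parents[sample.int(length(parents), 2L, replace = TRUE,
                                  prob = w)]
        # candidate rows start as a copy of parent rows inside the combined
        # encoding so operators can edit them in place
        cand$type[i] <- pop$type[par[1]]; cand$conseq[i] <- pop$conseq[par[1]]
        cand$lo[i, ] <- pop$lo[par[1], ]; cand$hi[i, ] <- pop$hi[par[1], ]
        cand$coef[i, ] <- pop$coef[par[1], ]
        cand <- switch(ops[i],
                       crossover = {
                         comb <- pop_bind(cand, pop_subset(pop, par[2]))
                         comb <- op_crossover(comb, i, i, n_cand + 1L)
                         pop_subset(comb, seq_len(n_cand))
                       },
                       mutation = op_mutate(cand, i, span, rng_lo, rng_hi),
                       insertion = op_insert(cand, i, Xp, span),
                       deletion = op_delete(cand, i),
                       fresh = fresh_rule(clear_row(cand, i), i,
                                          sample(FRESH_KINDS, 1L,
                                                 prob = FRESH_PROBS),
                                          Xp, s$X, s$y, tol, rng_lo))
      }
      # directed refinement: for the strongest presence envelopes, propose
      # adding each free covariate constrained to its presence-conditional
      # central window; truncation selection keeps the ones that pay off
      is_env <- pop$type == 0L & pop$conseq == 1L
      if (any(is_env)) {
        top_env <- which(is_env)[order(-sc$chisq[is_env])]
        top_env <- head(top_env, 5L)
        fires_p <- eval_rules_cpp(Xp, pop$type, pop$lo, pop$hi, pop$coef, tol)
        ref <- list()
        for (r0 in top_env) {
          rows <- which(fires_p[, r0] == 1L)
          if (length(rows) < 5L) next
          for (v in seq_len(ncol(pop$lo))) {
            # free covariates gain a conditional window; constrained ones
            # are re-derived (tightened) on the same conditional sample
            q <- quantile(Xp[rows, v], c(0.1, 0.9), names = FALSE)
            one <- pop_subset(pop, r0)
            one$lo[1, v] <- q[1]; one$hi[1, v] <- q[2]
            ref[[length(ref) + 1L]] <- one
          }
        }
        if (length(ref) > 0) {
          cand <- Reduce(pop_bind, ref, accumulate = FALSE, init = cand)
        }
      }
      comb <- pop_bind(pop, cand)
      fires <- eval_rules_cpp(s$X, comb$type, comb$lo, comb$hi, comb$coef, tol)
      sc_comb <- score_population(fires, s$y, comb$conseq, params$chisq_crit)
      # elitism: the union is truncation-selected on significance within the
      # archetype quotas, so top-ranked rules survive automatically;
      # position breaks exact ties in favour of the incumbent population
      top <- select_population(comb, sc_comb, R, params$type_quotas)
      pop <- pop_subset(comb, top)
      sc <- sc_comb[top, ]
    }
    if (!any(sc$significant)) {
      stop("no significant rule found; consider more training points or iterations",
           call. = FALSE)
    }
    list(pop = pop, sc = sc, it = it, converged = converged, delta = delta)
  })

  # projection order: significance-dominant (chi-square), accuracy
  # tie-break, then position; high-significance rules carry both coverage
  # and association, so each model's presence is decided by its few
  # dominant rules rather than fragmented across narrow ones
  fit <- ifelse(is.na(state$sc$accuracy), -1, state$sc$accuracy)
  ord <- order(-state$sc$chisq, -fit, seq_len(R))
  new_ruleset(pop_subset(state$pop, ord), state$sc[ord, ], tol,
              meta = list(seed = as.integer(seed), iterations = state$it,
                          converged = state$converged,
                          convergence_value = state$delta))
}

#' Run a multi-model experiment
#'
#' Trains `n_models` independently seeded rulesets. Each model gets its own
#' internal 75%/25% split of the presences; its *extrinsic omission* is the
#' percentage of its internal test presences predicted absent, and its
#' *commission* the percentage of landscape cells predicted present.
#' Per-model failures are caught, reported and excluded.
#'
#' @param presences Tibble of presence points (`x`, `y`).
#' @param landscape A `garp_landscape`.
#' @param params A [garp_params()].
#' @param seed Integer master seed.
#' @return A `garp_experiment`: list with `models` (each holding `ruleset`,
#'   `prediction`, `rule_index` in row-major cell order) and an
#'   `evaluations` tibble (`model`, `omission`, `commission`, `iterations`,
#'   `converged`, `failed`).
#' @export
run_experiment <- function(presences, landscape, params = garp_params(), seed) {
  n <- params$n_models
  seeds <- matrix(derive_seeds(seed, 2L * n), ncol = 2)
  models <- vector("list", n)
  evals <- vector("list", n)
  Xl <- landscape_values(landscape)
  for (m in seq_len(n)) {
    res <- tryCatch({
      split <- internal_split(presences, params$split_fraction, seeds[m, 1],
                              params$split_rule)
      rs <- evolve_ruleset(split$train, landscape, params, seeds[m, 2])
      proj <- project_matrix(rs, Xl)
      test_cells <- point_to_cell(landscape$grid, split$test$x, split$test$y)
      test_pred <- project_matrix(rs, Xl[test_cells, , drop = FALSE])$prediction
      list(model = list(ruleset = rs, prediction = proj$prediction,
                        rule_index = proj$rule_index),
           eval = tibble(model = m,
                         omission = 100 * mean(test_pred == 0L),
                         commission = 100 * mean(proj$prediction == 1L),
                         iterations = rs$meta$iterations,
                         converged = rs$meta$converged,
                         failed = FALSE, message = NA_character_))
    }, error = function(e) {
      list(model = NULL,
           eval = tibble(model = m, omission = NA_real_, commission = NA_real_,
                         iterations = NA_integer_, converged = NA,
                         failed = TRUE, message = conditionMessage(e)))
    })
    models[[m]] <- res$model
    evals[[m]] <- res$eval
  }
  structure(list(models = models, evaluations = dplyr::bind_rows(evals),
                 grid = landscape$grid, seed = as.integer(seed),
                 params = params),
            class = "garp_experiment")
}

#' @export
print.garp_experiment <- function(x, ...) {
  ev <- x$evaluations[!x$evaluations$failed, ]
  cat(sprintf("<garp_experiment> %d models (%d failed)\n",
              nrow(x$evaluations), sum(x$evaluations$failed)))
  if (nrow(ev) > 0) {
    cat(sprintf("  omission: median %.1f%%; commission: median %.1f%%\n",
                median(ev$omission), median(ev$commission)))
  }
  invisible(x)
}

#' Select model indices for a best subset
#'
#' Pure selection logic on (omission, commission) pairs: filter to models
#' with omission at or below the threshold, take the `n_low_omission`
#' lowest-omission models (ties by lower commission, then position), compute
#' their median commission, and keep the `n_best` whose commission is
#' closest to that median (ties by lower omission, then position).
#'
#' @param evaluations Tibble/data frame with `omission` and `commission`
#'   columns (percentages).
#' @param omission_threshold Maximum extrinsic omission (%).
#' @param n_low_omission Size of the low-omission pool.
#' @param commission_window Fraction of the pool to keep (0.5 of 20 = 10).
#' @param n_best Number of models to keep; defaults to
#'   `round(commission_window * n_low_omission)`.
#' @return List with `indices` (row positions into `evaluations`),
#'   `median_commission` and `short` (TRUE when fewer than `n_best` models
#'   qualified).
#' @export
select_best_subset <- function(evaluations, omission_threshold = 10,
                               n_low_omission = 20, commission_window = 0.5,
                               n_best = NULL) {
  if (is.null(n_best)) n_best <- round(commission_window * n_low_omission)
  om <- evaluations$omission
  cm <- evaluations$commission
  idx <- which(!is.na(om) & om <= omission_threshold)
  if (length(idx) == 0L) {
    stop("no model meets the omission threshold", call. = FALSE)
  }
  short <- length(idx) < n_best
  if (short) {
    warning(sprintf("only %d model(s) meet the omission threshold; fewer than n_best = %d",
                    length(idx), n_best), call. = FALSE)
  }
  pool <- idx[order(om[idx], cm[idx], idx)][seq_len(min(n_low_omission, length(idx)))]
  med <- median(cm[pool])
  sel <- pool[order(abs(cm[pool] - med), om[pool], pool)]
  sel <- sel[seq_len(min(n_best, length(sel)))]
  list(indices = sort(sel), median_commission = med, short = short)
}

#' Build the best subset of an experiment
#'
#' Applies [select_best_subset()] to the experiment's evaluations and sums
#' the selected models' binary predictions into the 0..n_best agreement
#' raster (cellwise model votes for presence).
#'
#' @inheritParams select_best_subset
#' @param experiment A `garp_experiment`.
#' @return A `garp_best_subset`: list with `models`, `evaluations` (selected
#'   rows), `agreement` matrix, `n_best`, `median_commission`, `grid`,
#'   `short`.
#' @export
best_subset <- function(experiment, omission_threshold = 10,
                        n_low_omission = 20, commission_window = 0.5,
                        n_best = NULL) {
  stopifnot(inherits(experiment, "garp_experiment"))
  sel <- select_best_subset(experiment$evaluations, omission_threshold,
                            n_low_omission, commission_window, n_best)
  models <- experiment$models[sel$indices]
  agreement <- Reduce(`+`, lapply(models, function(m) m$prediction))
  agreement <- cells_to_mat(agreement, experiment$grid)
  structure(list(models = models,
                 evaluations = experiment$evaluations[sel$indices, ],
                 agreement = agreement,
                 n_best = length(models),
                 median_commission = sel$median_commission,
                 grid = experiment$grid, short = sel$short),
            class = "garp_best_subset")
}

#' @export
print.garp_best_subset <- function(x, ...) {
  cat(sprintf("<garp_best_subset> %d models; agreement raster %d x %d (values 0..%d)\n",
              x$n_best, nrow(x$agreement), ncol(x$agreement), x$n_best))
  invisible(x)
}
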