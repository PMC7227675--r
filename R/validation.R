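#' Count correctly identified driver variables
#'
#' @param true_vars,chosen_vars Character vectors of equal length `k`.
#' @return Overlap count `r` in `0..k`.
#' @export
count_correct <- function(true_vars, chosen_vars) {
  if (length(true_vars) != length(chosen_vars)) {
    stop("true and chosen variable sets must have the same size", call. = FALSE)
  }
  length(intersect(true_vars, chosen_vars))
}

#' Hypergeometric null for random variable draws
#'
#' The baseline for selection performance: if three variables are drawn at
#' random (without replacement) from the candidate set, the overlap `r`
#' with the true three follows the hypergeometric distribution
#' `P(R = r) = choose(k, r) choose(n - k, k - r) / choose(n, k)`.
#'
#' @param n Total number of candidate covariates.
#' @param k Number drawn (and number of true drivers).
#' @return A `null_model` list: `n`, `k`, `probabilities` (named vector over
#'   r = 0..k, summing to 1).
#' @examples
#' null_probabilities(10, 3)$probabilities  # 35/120, 63/120, 21/120, 1/120
#' @export
null_probabilities <- function(n = 10, k = 3) {
  stopifnot(n >= 1, k >= 1, k <= n)
  r <- 0:k
  p <- choose(k, r) * choose(n - k, k - r) / choose(n, k)
  structure(list(n = as.integer(n), k = as.integer(k),
                 probabilities = setNames(p, paste0("r", r))),
            class = "null_model")
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Expected counts under the random-draw null
#'
#' @param null A [null_probabilities()] model.
#' @param n_species Number of species scored.
#' @return List with `expected` (real) and `expected_rounded` (integers,
#'   rounded half away from zero).
#' @export
expected_counts <- function(null, n_species) {
  stopifnot(inherits(null, "null_model"), n_species >= 0)
  e <- n_species * null$probabilities
  list(expected = e, expected_rounded = as.integer(round_half_away(e)))
}

#' One-tailed chi-square goodness of fit against the null
#'
#' Pearson statistic `sum((O - E)^2 / E)` with unrounded expectations,
#' `df = categories - 1`, and the upper-tail p-value (the one-tailed
#' reading: large statistics mean the observed counts do not follow the
#' random-draw distribution).
#'
#' @param observed Integer counts over r = 0..k (must sum to the number
#'   of species).
#' @param null A [null_probabilities()] model.
#' @return Tibble with `statistic`, `df`, `p_value`, `n`.
#' @examples
#' chisq_gof(c(13, 50, 106, 31), null_probabilities(10, 3))  # 724.3
#' @export
chisq_gof <- function(observed, null) {
  stopifnot(inherits(null, "null_model"),
            length(observed) == null$k + 1L, all(observed >= 0))
  n <- sum(observed)
  e <- n * null$probabilities
  if (any(e == 0)) stop("zero expected count", call. = FALSE)
  stat <- sum((observed - e)^2 / e)
  df <- length(observed) - 1L
  tibble(statistic = stat, df = df,
         p_value = pchisq(stat, df, lower.tail = FALSE), n = n)
}

#' Chi-square homogeneity test between two count vectors
#'
#' Standard 2 x R contingency chi-square without continuity correction,
#' comparing the distribution of `r` between two scenarios. Categories with
#' zero column totals are dropped with a warning (reducing the df).
#'
#' @param counts_a,counts_b Non-negative integer vectors of equal length
#'   with positive totals.
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @examples
#' chisq_homogeneity(c(4, 24, 57, 15), c(9, 26, 49, 16))  # 2.64, df 3
#' @export
chisq_homogeneity <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == length(counts_b),
            sum(counts_a) > 0, sum(counts_b) > 0)
  tab <- rbind(counts_a, counts_b)
  keep <- colSums(tab) > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d empty categor%s", sum(!keep),
                    if (sum(!keep) == 1) "y" else "ies"), call. = FALSE)
    tab <- tab[, keep, drop = FALSE]
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = unname(ht$p.value))
}

#' Accuracy metrics of an agreement raster
#'
#' Scores a 0..n_best model-agreement raster against external test
#' presences and a background sample:
#' * **total omission**: % of test presences on cells with agreement 0
#'   (no model predicts presence);
#' * **average omission**: mean over member models of the per-model
#'   omission %, i.e. `100 * mean(1 - agreement / n_best)` over test
#'   presences;
#' * **total commission**: % of landscape cells with agreement `n_best`
#'   (all models predict presence);
#' * **average commission**: mean per-model % of cells predicted present,
#'   i.e. `100 * mean(agreement / n_best)` over cells;
#' * **AUC**: trapezoidal area under the ROC obtained by thresholding the
#'   agreement at 0..n_best, scoring test presences against the background
#'   sample, with the Hanley-McNeil standard error and the z-score of the
#'   AUC against 0.5.
#'
#' @param agreement Integer matrix with values in `0..n_best`.
#' @param grid The matching [grid_spec()].
#' @param test_presences Tibble of test presence points (`x`, `y`).
#' @param background Tibble of background points (`x`, `y`), e.g. from
#'   [sample_background()].
#' @param n_best Number of models summed into the agreement raster.
#' @return A one-row `garp_accuracy` tibble.
#' @export
accuracy_metrics <- function(agreement, grid, test_presences, background,
                             n_best) {
  if (nrow(test_presences) == 0L) {
    stop("empty external test set", call. = FALSE)
  }
  stopifnot(all(agreement >= 0), all(agreement <= n_best))
  cells_t <- point_to_cell(grid, test_presences$x, test_presences$y)
  cells_b <- point_to_cell(grid, background$x, background$y)
  av <- mat_to_cells(agreement)
  at <- av[cells_t]; ab <- av[cells_b]

  roc <- roc_from_agreement(at, ab, n_best)
  tibble(total_omission = 100 * mean(at == 0L),
         average_omission = 100 * mean(1 - at / n_best),
         total_commission = 100 * mean(av == n_best),
         average_commission = 100 * mean(av / n_best),
         auc = roc$auc, auc_se = roc$se, auc_z = roc$z) |>
    structure(class = c("garp_accuracy", class(tibble())))
}

# ROC by thresholding agreement at t = 0..n_best+1 ("present" = agreement
# >= t); trapezoidal AUC; Hanley-McNeil SE; z against the chance AUC 0.5.
roc_from_agreement <- function(agree_pres, agree_bg, n_best) {
  th <- 0:(n_best + 1)
  tpr <- vapply(th, function(t) mean(agree_pres >= t), 1)
  fpr <- vapply(th, function(t) mean(agree_bg >= t), 1)
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (head(tpr[ord], -1) + tpr[ord][-1]) / 2)
  n1 <- length(agree_pres); n2 <- length(agree_bg)
  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  list(auc = auc, se = se,
       z = if (se > 0) (auc - 0.5) / se else Inf,
       tpr = tpr, fpr = fpr)
}

#' Replicate the virtual-species selection study
#'
#' The full benchmark loop: simulate (or reuse) a shared landscape, then for
#' each species draw true drivers and coefficients, realize the
#' distribution, sample presences, run a multi-model experiment, select the
#' best subset, compute UI, take the three lowest-UI covariates and score
#' the overlap `r` with the true drivers. Tallies of `r` per scenario and
#' pooled are tested against the hypergeometric null by the one-tailed
#' chi-square goodness of fit, and the scenarios are compared with a
#' homogeneity chi-square. Per-species failures are caught, counted and
#' excluded from the tallies.
#'
#' @param n_per_scenario Species per scenario.
#' @param scenarios Character vector of scenario names.
#' @param landscape Optional shared `garp_landscape`; simulated from `grid`
#'   when NULL.
#' @param grid [grid_spec()] used when simulating the landscape.
#' @param params [garp_params()] for the per-species experiments.
#' @param subset_args List of arguments passed to [best_subset()].
#' @param seed Integer master seed.
#' @param progress Print one line per species.
#' @return A `ui_validation` object: list with `scores` (per-species
#'   tibble), `tallies` (observed/expected per scenario and pooled),
#'   `tests` (GOF and homogeneity rows), `null`, `n_failed`, `landscape_seed`.
#' @export
run_simulation_study <- function(n_per_scenario = 100,
                                 scenarios = c("weak", "strong"),
                                 landscape = NULL, grid = grid_spec(),
                                 params = garp_params(),
                                 subset_args = list(), seed = 1,
                                 progress = FALSE) {
  seeds <- derive_seeds(seed, 1L + n_per_scenario * length(scenarios))
  if (is.null(landscape)) {
    landscape <- simulate_landscape(grid, seed = seeds[1])
  }
  n_cov <- length(landscape$covariates)
  scores <- list()
  n_failed <- 0L
  si <- 1L
  for (scn in scenarios) {
    scenario <- species_scenario(scn)
    for (i in seq_len(n_per_scenario)) {
      sp_seed <- seeds[1L + si]
      res <- tryCatch({
        sp <- simulate_species(landscape, scenario, seed = sp_seed)
        ex <- run_experiment(sp$presences, landscape, params, seed = sp_seed)
        # a short subset (fewer qualifying models than n_best) is recorded
        # on the object; the console warning would be noise across species
        bs <- suppressWarnings(do.call(best_subset, c(list(ex), subset_args)))
        ct <- variable_contribution(bs, landscape)
        chosen <- ct$covariate[order(ct$ui, ct$covariate)][seq_len(scenario$n_true_vars)]
        r <- count_correct(sp$true_vars, chosen)
        is_true <- ct$covariate %in% sp$true_vars
        tibble(species = si, scenario = scn, seed = sp_seed,
               true_vars = paste(sort(sp$true_vars), collapse = ","),
               chosen_vars = paste(sort(chosen), collapse = ","),
               r = r,
               mean_rui_true = mean(ct$rescaled_ui[is_true]),
               mean_rui_decoy = mean(ct$rescaled_ui[!is_true]),
               failed = FALSE)
      }, error = function(e) {
        tibble(species = si, scenario = scn, seed = sp_seed,
               true_vars = NA_character_, chosen_vars = NA_character_,
               r = NA_integer_, mean_rui_true = NA_real_,
               mean_rui_decoy = NA_real_, failed = TRUE)
      })
      if (res$failed) n_failed <- n_failed + 1L
      if (progress) {
        message(sprintf("species %d (%s): r = %s", si, scn,
                        ifelse(res$failed, "failed", res$r)))
      }
      scores[[si]] <- res
      si <- si + 1L
    }
  }
  scores <- dplyr::bind_rows(scores)
  k <- species_scenario(scenarios[1])$n_true_vars
  null <- null_probabilities(n_cov, k)

  tally_one <- function(r_values, label) {
    obs <- tabulate(r_values + 1L, nbins = k + 1L)
    e <- expected_counts(null, sum(obs))
    tibble(scenario = label, r = 0:k, observed = obs,
           expected = unname(e$expected),
           expected_rounded = e$expected_rounded)
  }
  ok <- scores[!scores$failed, ]
  tallies <- dplyr::bind_rows(
    lapply(scenarios, function(s) tally_one(ok$r[ok$scenario == s], s)),
    tally_one(ok$r, "all"))
  # categories the null makes impossible (small covariate sets) carry zero
  # probability and zero observations; the GOF runs on the attainable ones
  attainable <- null$probabilities > 0
  null_gof <- null
  null_gof$probabilities <- null$probabilities[attainable] /
    sum(null$probabilities[attainable])
  null_gof$k <- sum(attainable) - 1L
  tests <- dplyr::bind_rows(lapply(c(scenarios, "all"), function(s) {
    obs <- tallies$observed[tallies$scenario == s]
    if (sum(obs) == 0) {
      return(tibble(test = "gof", scenario = s, statistic = NA_real_,
                    df = NA_integer_, p_value = NA_real_, n = 0L))
    }
    dplyr::mutate(chisq_gof(obs[attainable], null_gof), test = "gof",
                  scenario = s, .before = 1)
  }))
  counts_1 <- tallies$observed[tallies$scenario == scenarios[1]]
  counts_2 <- tallies$observed[tallies$scenario == scenarios[2]]
  if (length(scenarios) == 2 && sum(counts_1) > 0 && sum(counts_2) > 0) {
    hom <- chisq_homogeneity(counts_1, counts_2)
    tests <- dplyr::bind_rows(tests,
                              dplyr::mutate(hom, test = "homogeneity",
                                            scenario = paste(scenarios, collapse = " vs "),
                                            n = NA_integer_, .before = 1))
  }
  structure(list(scores = scores, tallies = tallies, tests = tests,
                 null = null, n_failed = n_failed,
                 landscape_seed = landscape$master_seed,
                 seed = as.integer(seed)),
            class = "ui_validation")
}

#' @export
print.ui_validation <- function(x, ...) {
  ok <- x$scores[!x$scores$failed, ]
  cat(sprintf("<ui_validation> %d species scored (%d failed)\n",
              nrow(ok), x$n_failed))
  if (nrow(ok) > 0) {
    cat(sprintf("  fraction with r >= 2: %.1f%% (null expectation %.1f%%)\n",
                100 * mean(ok$r >= 2),
                100 * sum(x$null$probabilities[-(1:2)])))
  }
  invisible(x)
}
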