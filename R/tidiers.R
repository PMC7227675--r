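#' Tidy a multi-model experiment
#'
#' @param x A `garp_experiment`.
#' @param ... Unused.
#' @return The per-model evaluation tibble (`model`, `omission`,
#'   `commission`, `iterations`, `converged`, `failed`).
#' @method tidy garp_experiment
#' @export
tidy.garp_experiment <- function(x, ...) x$evaluations

#' @rdname tidy.garp_experiment
#' @return For `glance()`: a one-row summary tibble.
#' @method glance garp_experiment
#' @export
glance.garp_experiment <- function(x, ...) {
  ev <- x$evaluations[!x$evaluations$failed, ]
  tibble(n_models = nrow(x$evaluations), n_failed = sum(x$evaluations$failed),
         median_omission = median(ev$omission),
         median_commission = median(ev$commission),
         mean_iterations = mean(ev$iterations),
         prop_converged = mean(ev$converged))
}

#' Tidy a ruleset
#'
#' @param x A `garp_ruleset`.
#' @param ... Unused.
#' @return One row per rule, in projection order: `rule`, `rule_type`,
#'   `consequent`, `n_covariates`, the formatted condition, and the internal
#'   statistics.
#' @method tidy garp_ruleset
#' @export
tidy.garp_ruleset <- function(x, ...) {
  rules <- lapply(seq_len(length(x)), function(i) decode_rule(x$pop, i))
  dplyr::bind_cols(
    tibble(rule = seq_along(rules),
           rule_type = vapply(rules, function(r) r$rule_type, ""),
           consequent = vapply(rules, function(r) r$consequent, ""),
           n_covariates = vapply(rules, function(r)
             length(rule_covariates(r)), 1L),
           condition = vapply(rules, format_rule, "")),
    x$stats)
}

#' Tidy a best subset
#'
#' @param x A `garp_best_subset`.
#' @param ... Unused.
#' @return The selected models' evaluation rows.
#' @method tidy garp_best_subset
#' @export
tidy.garp_best_subset <- function(x, ...) x$evaluations

#' @rdname tidy.garp_best_subset
#' @method glance garp_best_subset
#' @export
glance.garp_best_subset <- function(x, ...) {
  tibble(n_best = x$n_best, median_commission = x$median_commission,
         short = x$short,
         mean_agreement = mean(x$agreement),
         prop_full_agreement = mean(x$agreement == x$n_best))
}

#' Tidy a contribution table
#'
#' @param x A `ui_contribution`.
#' @param ... Unused.
#' @return The contribution tibble (already tidy), stripped of attributes.
#' @method tidy ui_contribution
#' @export
tidy.ui_contribution <- function(x, ...) {
  as_tibble(x)
}

#' Tidy a simulation-study result
#'
#' @param x A `ui_validation`.
#' @param ... Unused.
#' @return The per-species score tibble.
#' @method tidy ui_validation
#' @export
tidy.ui_validation <- function(x, ...) x$scores

#' @rdname tidy.ui_validation
#' @return For `glance()`: one row with the pooled recovery fraction, the
#'   null expectation of r >= 2, and the pooled GOF statistic.
#' @method glance ui_validation
#' @export
glance.ui_validation <- function(x, ...) {
  ok <- x$scores[!x$scores$failed, ]
  gof <- x$tests[x$tests$test == "gof" & x$tests$scenario == "all", ]
  tibble(n_species = nrow(ok), n_failed = x$n_failed,
         prop_r_ge_2 = mean(ok$r >= 2),
         null_prop_r_ge_2 = sum(x$null$probabilities[-seq_len(2)]),
         gof_statistic = gof$statistic, gof_df = gof$df,
         gof_p_value = gof$p_value)
}
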