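#' Dominant presence rules of a best subset
#'
#' Pools every presence-deciding rule across the subset's models. A rule's
#' coverage is the share of presence cell-decisions it makes: (cells where
#' it is the first-firing rule and predicts presence) divided by the total
#' presence cell-decisions across all member models (a cell predicted
#' present by 4 models contributes 4 decisions). Rules are sorted by
#' descending coverage and the smallest prefix whose cumulative coverage
#' strictly exceeds `cutoff` is kept: the primary environmental conditions
#' behind the subset's prediction.
#'
#' @param best A `garp_best_subset`.
#' @param cutoff Cumulative-coverage cutoff (strict inequality; 0.90 keeps
#'   rules until more than 90% of presence decisions are covered).
#' @return A `dominant_rules` tibble: `model`, `rule`, `rule_type`,
#'   `coverage`, `cum_coverage`, `n_cells`, with the decoded rules in
#'   attribute `rules` and the per-rule presence-cell ids in attribute
#'   `cells`.
#' @export
dominant_presence_rules <- function(best, cutoff = 0.90) {
  stopifnot(inherits(best, "garp_best_subset"))
  recs <- list()
  for (m in seq_along(best$models)) {
    mod <- best$models[[m]]
    pres <- mod$prediction == 1L
    if (!any(pres)) next
    idx <- mod$rule_index[pres]
    counts <- tabulate(idx, nbins = length(mod$ruleset))
    for (r in which(counts > 0L)) {
      recs[[length(recs) + 1L]] <- list(model = m, rule = r,
                                        n_cells = counts[r],
                                        cells = which(pres)[idx == r])
    }
  }
  if (length(recs) == 0L) {
    stop("the best subset predicts presence nowhere", call. = FALSE)
  }
  total <- sum(vapply(recs, function(x) x$n_cells, 1L))
  cov <- vapply(recs, function(x) x$n_cells, 1L) / total
  ord <- order(-cov, vapply(recs, function(x) x$model, 1L),
               vapply(recs, function(x) x$rule, 1L))
  recs <- recs[ord]; cov <- cov[ord]
  cum <- cumsum(cov)
  keep <- seq_len(which(cum > cutoff)[1])
  recs <- recs[keep]
  rules <- lapply(recs, function(x)
    ruleset_rule(best$models[[x$model]]$ruleset, x$rule))
  out <- tibble(model = vapply(recs, function(x) x$model, 1L),
                rule = vapply(recs, function(x) x$rule, 1L),
                rule_type = vapply(rules, function(r) r$rule_type, ""),
                coverage = cov[keep], cum_coverage = cum[keep],
                n_cells = vapply(recs, function(x) x$n_cells, 1L))
  structure(out, rules = rules,
            cells = lapply(recs, function(x) x$cells),
            total_decisions = total,
            class = c("dominant_rules", class(out)))
}

#' Prevalence of a covariate in the dominant rules
#'
#' The fraction of dominant presence rules whose condition references the
#' covariate. For logit rules every covariate with a coefficient beyond
#' `coef_tol` counts as referenced (default 0: all fitted coefficients
#' count).
#'
#' @param covariate Covariate name.
#' @param dominant A [dominant_presence_rules()] result.
#' @param coef_tol Minimum absolute logit coefficient to count.
#' @return Fraction in `[0, 1]`.
#' @export
prevalence <- function(covariate, dominant, coef_tol = 0) {
  rules <- attr(dominant, "rules")
  stopifnot(length(rules) >= 1)
  mean(vapply(rules, function(r) covariate %in% rule_covariates(r, coef_tol), TRUE))
}

#' Bounds a dominant rule implies for a covariate
#'
#' Range and negated-range rules carry explicit bounds. Logit rules have no
#' stored bounds, so the covariate's minimum and maximum are taken over the
#' cells where the rule is the deciding presence rule (zonal statistics on
#' the landscape). Atomic rules contribute their atom as a degenerate
#' (point) interval.
#'
#' @param i Position of the rule within `dominant`.
#' @param covariate Covariate name.
#' @param dominant A [dominant_presence_rules()] result.
#' @param landscape The `garp_landscape` the subset was projected on
#'   (needed for logit rules).
#' @return `c(min, max)`, or `NULL` when the rule does not constrain the
#'   covariate or (for a logit rule) decides no cells.
#' @export
rule_bounds <- function(i, covariate, dominant, landscape = NULL) {
  rules <- attr(dominant, "rules")
  stopifnot(i >= 1, i <= length(rules))
  r <- rules[[i]]
  if (!covariate %in% rule_covariates(r)) return(NULL)
  switch(r$rule_type,
         range = , negated_range = unname(r$bounds[[covariate]]),
         atomic = rep(unname(r$atoms[[covariate]]), 2),
         logit = {
           if (is.null(landscape)) {
             stop("a landscape is required to extract zonal bounds for logit rules",
                  call. = FALSE)
           }
           cells <- attr(dominant, "cells")[[i]]
           if (length(cells) == 0L) return(NULL)
           vals <- mat_to_cells(landscape$covariates[[covariate]])[cells]
           range(vals)
         })
}

#' Median range of a covariate over the dominant rules
#'
#' Difference between the median of the per-rule upper bounds and the median
#' of the per-rule lower bounds, over the dominant rules that reference the
#' covariate with defined bounds (atomic atoms contribute min = max).
#'
#' @inheritParams prevalence
#' @param landscape Landscape for logit zonal bounds.
#' @return Width in covariate units, or `NA` if no dominant rule bounds the
#'   covariate.
#' @export
median_range <- function(covariate, dominant, landscape = NULL, coef_tol = 0) {
  rules <- attr(dominant, "rules")
  bounds <- list()
  for (i in seq_along(rules)) {
    if (!covariate %in% rule_covariates(rules[[i]], coef_tol)) next
    b <- rule_bounds(i, covariate, dominant, landscape)
    if (!is.null(b)) bounds[[length(bounds) + 1L]] <- b
  }
  if (length(bounds) == 0L) return(NA_real_)
  median(vapply(bounds, `[`, 1, 2)) - median(vapply(bounds, `[`, 1, 1))
}

#' Scale a median range by the covariate's landscape range
#'
#' @param covariate Covariate name.
#' @param med_range Median range in covariate units.
#' @param landscape A `garp_landscape`.
#' @return Value in `[0, 1]` (clipped).
#' @export
scaled_median_range <- function(covariate, med_range, landscape) {
  vals <- landscape$covariates[[covariate]]
  if (is.null(vals)) stop(sprintf("no covariate '%s' in landscape", covariate),
                          call. = FALSE)
  span <- max(vals) - min(vals)
  if (span <= 0) stop(sprintf("covariate '%s' is constant on the landscape",
                              covariate), call. = FALSE)
  min(max(med_range / span, 0), 1)
}

#' Unimportance Index
#'
#' `UI = (1 - prevalence) * scaled median range`: zero (maximally important)
#' when a covariate appears in every dominant rule or is constrained to a
#' point, largest when it is rarely referenced and, when referenced, barely
#' constrained. The scaled median range is used so the index is comparable
#' across covariates.
#'
#' @param prevalence Fraction in `[0, 1]`.
#' @param scaled_range Scaled median range in `[0, 1]`.
#' @return UI value.
#' @export
unimportance_index <- function(prevalence, scaled_range) {
  stopifnot(all(prevalence >= 0 & prevalence <= 1, na.rm = TRUE),
            all(scaled_range >= 0 & scaled_range <= 1, na.rm = TRUE))
  (1 - prevalence) * scaled_range
}

#' Min-max rescale UI values across covariates
#'
#' `(UI_k - UI_min) / (UI_max - UI_min)`; invariant under positive affine
#' transformations of the raw UIs. If all UIs are equal the rescaling is
#' degenerate and defined as all zeros, with a warning.
#'
#' @param ui Numeric vector of UI values.
#' @return Values in `[0, 1]` attaining both 0 and 1 (unless degenerate).
#' @export
rescale_ui <- function(ui) {
  lo <- min(ui); hi <- max(ui)
  if (hi - lo <= 0) {
    warning("all UI values are equal; rescaled UI set to 0 for all covariates",
            call. = FALSE)
    return(rep(0, length(ui)))
  }
  (ui - lo) / (hi - lo)
}

#' Variable contributions from a best subset
#'
#' The full contribution table: for every covariate of the landscape, its
#' prevalence in the dominant presence rules, median range, scaled median
#' range, UI, rescaled UI, importance rank (1 = most important = lowest UI)
#' and whether it passes the selection threshold. A covariate never
#' referenced by any dominant rule is maximally unconstrained by the model:
#' it gets prevalence 0 and scaled median range 1.
#'
#' @param best A `garp_best_subset`.
#' @param landscape The `garp_landscape` the experiment ran on.
#' @param threshold Rescaled-UI selection threshold (strict `<`).
#' @param cutoff Dominant-rule cumulative coverage cutoff.
#' @param coef_tol Minimum absolute logit coefficient to count as a
#'   reference.
#' @param scale `"landscape"` divides each median range by the covariate's
#'   full landscape range; `"minmax"` instead min-max rescales the raw
#'   median ranges across covariates.
#' @return A `ui_contribution` tibble with columns `covariate`,
#'   `prevalence`, `median_range`, `scaled_median_range`, `ui`,
#'   `rescaled_ui`, `rank`, `selected`.
#' @examples
#' \donttest{
#' ls <- simulate_landscape(grid_spec(n_cols = 40, n_rows = 40), seed = 5)
#' sp <- simulate_species(ls, species_scenario("strong"), seed = 9)
#' ex <- run_experiment(sp$presences, ls,
#'                      garp_params(n_models = 12, max_iterations = 30), seed = 1)
#' bs <- best_subset(ex, n_low_omission = 12, n_best = 6)
#' variable_contribution(bs, ls)
#' }
#' @export
variable_contribution <- function(best, landscape, threshold = 0.5,
                                  cutoff = 0.90, coef_tol = 0,
                                  scale = c("landscape", "minmax")) {
  scale <- match.arg(scale)
  dominant <- dominant_presence_rules(best, cutoff)
  covs <- names(landscape$covariates)
  prev <- vapply(covs, prevalence, 1, dominant = dominant, coef_tol = coef_tol)
  mrange <- vapply(covs, median_range, 1, dominant = dominant,
                   landscape = landscape, coef_tol = coef_tol)
  span <- vapply(covs, function(nm) {
    v <- landscape$covariates[[nm]]; max(v) - min(v)
  }, 1)
  # never-referenced covariates: the model left them fully unconstrained
  mrange[is.na(mrange)] <- span[is.na(mrange)]
  smr <- if (scale == "landscape") {
    pmin(pmax(mrange / span, 0), 1)
  } else {
    if (max(mrange) > min(mrange)) {
      (mrange - min(mrange)) / (max(mrange) - min(mrange))
    } else rep(1, length(mrange))
  }
  ui <- unimportance_index(prev, smr)
  rui <- rescale_ui(ui)
  out <- tibble(covariate = covs, prevalence = unname(prev),
                median_range = unname(mrange),
                scaled_median_range = unname(smr),
                ui = unname(ui), rescaled_ui = unname(rui),
                rank = rank(ui, ties.method = "first"),
                selected = rui < threshold)
  if (!any(out$selected)) {
    warning("no covariate below the UI threshold; keeping the single lowest-UI covariate",
            call. = FALSE)
    out$selected[which.min(out$ui)] <- TRUE
  }
  structure(out, dominant = dominant, threshold = threshold,
            class = c("ui_contribution", class(out)))
}

#' Select important covariates from a contribution table
#'
#' Covariates with rescaled UI strictly below the threshold. If none
#' qualifies, the single lowest-UI covariate is returned with a warning.
#'
#' @param contributions A [variable_contribution()] tibble.
#' @param threshold Strict rescaled-UI cutoff.
#' @return Character vector of covariate names.
#' @export
select_variables <- function(contributions, threshold = 0.5) {
  sel <- contributions$covariate[contributions$rescaled_ui < threshold]
  if (length(sel) == 0L) {
    warning("no covariate below the UI threshold; returning the lowest-UI covariate",
            call. = FALSE)
    sel <- contributions$covariate[which.min(contributions$ui)]
  }
  sel
}
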