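# Rule populations are encoded as parallel structures so the C++ kernel can
# evaluate a whole generation at once:
#   type   integer: 0 range, 1 negated range, 2 logit, 3 atomic
#   conseq integer: 1 presence, 0 absence
#   lo/hi  n_rules x p matrices of bounds (NA = unconstrained); atomic rules
#          store the atom value in both
#   coef   n_rules x (p+1); covariate coefficients then intercept (logit)

RULE_TYPES <- c("range", "negated_range", "logit", "atomic")

pop_new <- function(R, covariates) {
  p <- length(covariates)
  list(type = integer(R), conseq = integer(R),
       lo = matrix(NA_real_, R, p, dimnames = list(NULL, covariates)),
       hi = matrix(NA_real_, R, p, dimnames = list(NULL, covariates)),
       coef = matrix(NA_real_, R, p + 1,
                     dimnames = list(NULL, c(covariates, ".intercept"))))
}

pop_size <- function(pop) length(pop$type)

pop_subset <- function(pop, i) {
  list(type = pop$type[i], conseq = pop$conseq[i],
       lo = pop$lo[i, , drop = FALSE], hi = pop$hi[i, , drop = FALSE],
       coef = pop$coef[i, , drop = FALSE])
}

pop_bind <- function(a, b) {
  list(type = c(a$type, b$type), conseq = c(a$conseq, b$conseq),
       lo = rbind(a$lo, b$lo), hi = rbind(a$hi, b$hi),
       coef = rbind(a$coef, b$coef))
}

# single-row encoding <-> user-facing rule object ---------------------------

decode_rule <- function(pop, i, stats = NULL) {
  type <- RULE_TYPES[pop$type[i] + 1L]
  conseq <- if (pop$conseq[i] == 1L) "presence" else "absence"
  covn <- colnames(pop$lo)
  out <- list(rule_type = type, consequent = conseq,
              bounds = NULL, coefficients = NULL, intercept = NULL,
              atoms = NULL, stats = stats)
  if (type %in% c("range", "negated_range")) {
    j <- which(!is.na(pop$lo[i, ]))
    out$bounds <- lapply(j, function(k) c(pop$lo[i, k], pop$hi[i, k]))
    names(out$bounds) <- covn[j]
  } else if (type == "atomic") {
    j <- which(!is.na(pop$lo[i, ]))
    out$atoms <- setNames(pop$lo[i, j], covn[j])
  } else {
    j <- which(!is.na(pop$coef[i, seq_along(covn)]))
    out$coefficients <- setNames(pop$coef[i, j], covn[j])
    out$intercept <- pop$coef[i, length(covn) + 1L]
  }
  structure(out, class = "garp_rule")
}

encode_rule <- function(rule, covariates) {
  pop <- pop_new(1L, covariates)
  pop$type[1] <- match(rule$rule_type, RULE_TYPES) - 1L
  pop$conseq[1] <- as.integer(rule$consequent == "presence")
  if (rule$rule_type %in% c("range", "negated_range")) {
    for (nm in names(rule$bounds)) {
      pop$lo[1, nm] <- rule$bounds[[nm]][1]
      pop$hi[1, nm] <- rule$bounds[[nm]][2]
    }
  } else if (rule$rule_type == "atomic") {
    for (nm in names(rule$atoms)) {
      pop$lo[1, nm] <- rule$atoms[[nm]]
      pop$hi[1, nm] <- rule$atoms[[nm]]
    }
  } else {
    for (nm in names(rule$coefficients)) pop$coef[1, nm] <- rule$coefficients[[nm]]
    pop$coef[1, length(covariates) + 1L] <- rule$intercept
  }
  pop
}

check_bounds <- function(bounds) {
  stopifnot(is.list(bounds), length(bounds) >= 1, !is.null(names(bounds)))
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2 || !is.numeric(b) || b[1] > b[2]) {
      stop(sprintf("bounds for '%s' must be numeric (lower, upper) with lower <= upper",
                   nm), call. = FALSE)
    }
  }
}

#' Construct rules
#'
#' If/then statements over covariates. A *range* rule fires when every
#' constrained covariate lies inside its (inclusive) envelope; a *negated
#' range* rule fires when that conjunction fails; a *logit* rule fires when
#' the logistic probability `plogis(intercept + sum(coef * x))` exceeds 0.5;
#' an *atomic* rule fires when every constrained covariate equals its atom
#' within half a binning tolerance.
#'
#' @param bounds Named list of `c(lower, upper)` bound pairs.
#' @param consequent `"presence"` or `"absence"`.
#' @param coefficients Named numeric covariate coefficients.
#' @param intercept Intercept of the logit rule.
#' @param atoms Named numeric atom values.
#' @return A `garp_rule` object.
#' @examples
#' r <- rule_range(list(temp = c(10.2, 13.5), ndvi = c(0.15, 0.23)))
#' rule_fires(r, c(temp = 12, ndvi = 0.2))
#' @name rules
NULL

#' @rdname rules
#' @export
rule_range <- function(bounds, consequent = "presence") {
  check_bounds(bounds)
  structure(list(rule_type = "range", consequent = match.arg(consequent, c("presence", "absence")),
                 bounds = bounds, coefficients = NULL, intercept = NULL,
                 atoms = NULL, stats = NULL), class = "garp_rule")
}

#' @rdname rules
#' @export
rule_negated_range <- function(bounds, consequent = "absence") {
  check_bounds(bounds)
  structure(list(rule_type = "negated_range", consequent = match.arg(consequent, c("absence", "presence")),
                 bounds = bounds, coefficients = NULL, intercept = NULL,
                 atoms = NULL, stats = NULL), class = "garp_rule")
}

#' @rdname rules
#' @export
rule_logit <- function(coefficients, intercept = 0, consequent = "presence") {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  structure(list(rule_type = "logit", consequent = match.arg(consequent, c("presence", "absence")),
                 bounds = NULL, coefficients = coefficients,
                 intercept = as.numeric(intercept), atoms = NULL, stats = NULL),
            class = "garp_rule")
}

#' @rdname rules
#' @export
rule_atomic <- function(atoms, consequent = "presence") {
  stopifnot(is.numeric(atoms), !is.null(names(atoms)))
  structure(list(rule_type = "atomic", consequent = match.arg(consequent, c("presence", "absence")),
                 bounds = NULL, coefficients = NULL, intercept = NULL,
                 atoms = atoms, stats = NULL), class = "garp_rule")
}

#' @export
print.garp_rule <- function(x, ...) {
  cat(format_rule(x), "\n")
  invisible(x)
}

rule_covariates <- function(rule, coef_tol = 0) {
  switch(rule$rule_type,
         range = , negated_range = names(rule$bounds),
         atomic = names(rule$atoms),
         logit = names(rule$coefficients)[abs(rule$coefficients) > coef_tol |
                                            coef_tol == 0])
}

#' Does a rule fire on given cell values?
#'
#' Reference (pure R) evaluation of a single rule, used both directly and as
#' a cross-check of the compiled engine kernel.
#'
#' @param rule A `garp_rule`.
#' @param values Named numeric vector, or a data frame with one column per
#'   covariate (evaluated rowwise).
#' @param tol Binning tolerance per covariate for atomic rules (named vector
#'   or single number); an atomic constraint matches within `tol / 2`.
#' @return Logical scalar (or vector for a data frame input).
#' @export
rule_fires <- function(rule, values, tol = 1e-8) {
  stopifnot(inherits(rule, "garp_rule"))
  if (is.data.frame(values)) {
    need <- rule_covariates(rule)
    missing <- setdiff(need, names(values))
    if (length(missing) > 0) {
      stop(sprintf("missing covariate(s): %s", paste(missing, collapse = ", ")),
           call. = FALSE)
    }
    n <- nrow(values)
  } else {
    need <- rule_covariates(rule)
    missing <- setdiff(need, names(values))
    if (length(missing) > 0) {
      stop(sprintf("missing covariate(s): %s", paste(missing, collapse = ", ")),
           call. = FALSE)
    }
    values <- as.data.frame(as.list(values))
    n <- 1L
  }
  get_tol <- function(nm) if (length(tol) > 1) tol[[nm]] else tol
  switch(rule$rule_type,
         range = {
           ok <- rep(TRUE, n)
           for (nm in names(rule$bounds)) {
             b <- rule$bounds[[nm]]
             ok <- ok & values[[nm]] >= b[1] & values[[nm]] <= b[2]
           }
           ok
         },
         negated_range = {
           ok <- rep(TRUE, n)
           for (nm in names(rule$bounds)) {
             b <- rule$bounds[[nm]]
             ok <- ok & values[[nm]] >= b[1] & values[[nm]] <= b[2]
           }
           !ok
         },
         logit = {
           eta <- rep(rule$intercept, n)
           for (nm in names(rule$coefficients)) {
             eta <- eta + rule$coefficients[[nm]] * values[[nm]]
           }
           stats::plogis(eta) > 0.5
         },
         atomic = {
           ok <- rep(TRUE, n)
           for (nm in names(rule$atoms)) {
             ok <- ok & abs(values[[nm]] - rule$atoms[[nm]]) <= get_tol(nm) / 2
           }
           ok
         })
}

#' Score a rule on a labelled sample
#'
#' Internal rule quality: a 2x2 contingency table of (rule fires) x
#' (presence label) summarised by the Pearson chi-square statistic without
#' continuity correction, plus the rule's predictive accuracy among the
#' samples where it fires and its coverage. Degenerate tables (rule firing
#' nowhere or everywhere, or one label class absent) get chi-square 0 and
#' are flagged non-significant.
#'
#' @param rule A `garp_rule`.
#' @param data Data frame with covariate columns and a logical/0-1 `label`
#'   column (TRUE/1 = presence).
#' @param chisq_crit Significance cutoff for the chi-square statistic
#'   (3.84 = alpha 0.05 at 1 df).
#' @param tol Atomic binning tolerance, as in [rule_fires()].
#' @return List with `chisq`, `p_value`, `accuracy`, `coverage`,
#'   `significant`, `n_fired`, `degenerate`.
#' @export
score_rule <- function(rule, data, chisq_crit = 3.84, tol = 1e-8) {
  stopifnot("label" %in% names(data))
  y <- as.integer(data$label)
  stopifnot(all(y %in% c(0L, 1L)))
  f <- rule_fires(rule, data[setdiff(names(data), "label")], tol = tol)
  chisq_from_counts(sum(f & y == 1L), sum(f & y == 0L),
                    sum(!f & y == 1L), sum(!f & y == 0L),
                    conseq = as.integer(rule$consequent == "presence"),
                    chisq_crit = chisq_crit)
}

# closed-form 2x2 Pearson chi-square (no continuity correction)
chisq_from_counts <- function(a, b, c, d, conseq = 1L, chisq_crit = 3.84) {
  n <- a + b + c + d
  m1 <- a + b; m2 <- c + d; m3 <- a + c; m4 <- b + d
  degenerate <- m1 == 0 || m2 == 0 || m3 == 0 || m4 == 0
  chisq <- if (degenerate) 0 else n * (a * d - b * c)^2 / (m1 * m2 * m3 * m4)
  accuracy <- if (m1 == 0) NA_real_ else if (conseq == 1L) a / m1 else b / m1
  list(chisq = chisq,
       p_value = pchisq(chisq, df = 1, lower.tail = FALSE),
       accuracy = accuracy,
       coverage = m1 / n,
       significant = !degenerate && chisq >= chisq_crit,
       n_fired = m1,
       degenerate = degenerate)
}

# vectorised scoring of a whole population from a firing matrix
score_population <- function(fires, y, conseq, chisq_crit = 3.84) {
  n <- length(y)
  n_fired <- colSums(fires)
  a <- as.numeric(colSums(fires * y))          # fired & presence
  b <- n_fired - a                             # fired & absence
  cc <- sum(y) - a
  d <- (n - sum(y)) - b
  m1 <- a + b; m2 <- cc + d; m3 <- a + cc; m4 <- b + d
  denom <- m1 * m2 * m3 * m4
  chisq <- ifelse(denom == 0, 0, n * (a * d - b * cc)^2 / pmax(denom, 1))
  accuracy <- ifelse(m1 == 0, NA_real_, ifelse(conseq == 1L, a / m1, b / m1))
  tibble(chisq = chisq, accuracy = accuracy, coverage = m1 / n,
         n_fired = as.integer(n_fired),
         significant = denom > 0 & chisq >= chisq_crit & !is.na(accuracy))
}

# ruleset -------------------------------------------------------------------

new_ruleset <- function(pop, stats, tol, meta) {
  structure(list(pop = pop, stats = stats, covariates = colnames(pop$lo),
                 tol = tol, meta = meta),
            class = "garp_ruleset")
}

#' Assemble a ruleset from individual rules
#'
#' Rules are applied in the supplied order (first match wins) when the
#' ruleset is projected.
#'
#' @param rules List of `garp_rule` objects.
#' @param covariates Covariate name universe (defaults to the union of the
#'   rules' covariates).
#' @param tol Named per-covariate atomic binning tolerance.
#' @return A `garp_ruleset`.
#' @export
ruleset <- function(rules, covariates = NULL, tol = NULL) {
  stopifnot(length(rules) >= 1, all(vapply(rules, inherits, TRUE, "garp_rule")))
  if (is.null(covariates)) {
    covariates <- unique(unlist(lapply(rules, rule_covariates)))
  }
  pop <- Reduce(pop_bind, lapply(rules, encode_rule, covariates = covariates))
  if (is.null(tol)) tol <- setNames(rep(1e-8, length(covariates)), covariates)
  stats <- tibble(chisq = rep(NA_real_, length(rules)),
                  accuracy = NA_real_, coverage = NA_real_,
                  n_fired = NA_integer_, significant = NA)
  new_ruleset(pop, stats, tol, meta = list(seed = NA_integer_,
                                           iterations = NA_integer_,
                                           converged = NA,
                                           convergence_value = NA_real_))
}

#' @export
length.garp_ruleset <- function(x) pop_size(x$pop)

#' @export
print.garp_ruleset <- function(x, n = 5, ...) {
  R <- pop_size(x$pop)
  cat(sprintf("<garp_ruleset> %d rules over %d covariates", R,
              length(x$covariates)))
  if (!is.na(x$meta$iterations)) {
    cat(sprintf(" (evolved %d iterations, %s)", x$meta$iterations,
                if (isTRUE(x$meta$converged)) "converged" else "iteration cap"))
  }
  cat("\n")
  for (i in seq_len(min(n, R))) cat(" ", format_rule(decode_rule(x$pop, i)), "\n")
  if (R > n) cat(sprintf("  ... and %d more rules\n", R - n))
  invisible(x)
}

#' Extract one rule from a ruleset
#'
#' @param rs A `garp_ruleset`.
#' @param i Rule position (projection order).
#' @return A `garp_rule` with its internal `stats` attached.
#' @export
ruleset_rule <- function(rs, i) {
  stopifnot(inherits(rs, "garp_ruleset"), i >= 1, i <= pop_size(rs$pop))
  decode_rule(rs$pop, i, stats = as.list(rs$stats[i, ]))
}

#' Project a ruleset onto a landscape
#'
#' Applies the rules in stored order to every cell; the first rule that
#' fires decides the cell and its index is recorded. Cells matched by no
#' rule are predicted absent with index -1.
#'
#' @param rs A `garp_ruleset`.
#' @param landscape A `garp_landscape` containing every covariate the rules
#'   reference.
#' @return List with `prediction` (0/1 integer matrix) and `rule_index`
#'   (integer matrix, -1 where no rule fired).
#' @export
project <- function(rs, landscape) {
  stopifnot(inherits(rs, "garp_ruleset"), inherits(landscape, "garp_landscape"))
  X <- landscape_values(landscape)
  missing <- setdiff(rs$covariates, colnames(X))
  if (length(missing) > 0) {
    stop(sprintf("landscape lacks covariate(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  X <- X[, rs$covariates, drop = FALSE]
  out <- project_rules_cpp(X, rs$pop$type, rs$pop$lo, rs$pop$hi, rs$pop$coef,
                           as.numeric(rs$tol[rs$covariates]), rs$pop$conseq)
  g <- landscape$grid
  list(prediction = cells_to_mat(out$prediction, g),
       rule_index = cells_to_mat(out$rule_index, g))
}

# evaluate ordered rules on a plain value matrix (first-match-wins)
project_matrix <- function(rs, X) {
  X <- X[, rs$covariates, drop = FALSE]
  project_rules_cpp(X, rs$pop$type, rs$pop$lo, rs$pop$hi, rs$pop$coef,
                    as.numeric(rs$tol[rs$covariates]), rs$pop$conseq)
}
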