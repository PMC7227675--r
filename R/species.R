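#' Virtual-species scenario settings
#'
#' Two benchmark scenarios control how strongly the environment shapes the
#' species: under `weak` the niche coefficients are drawn from Normal(1, 0.5),
#' under `strong` from Normal(5, 0.5). Each species responds to
#' `n_true_vars` covariates drawn without replacement and is sampled at
#' `n_presence_points` presence-cell centroids.
#'
#' @param scenario `"weak"` or `"strong"`.
#' @param coefficient_mean Mean of the coefficient distribution; defaults to
#'   1 (weak) or 5 (strong).
#' @param coefficient_sd Standard deviation of the coefficient distribution.
#' @param n_true_vars Number of true driver covariates per species.
#' @param n_presence_points Number of presence points sampled per species.
#' @return A `species_scenario` object.
#' @examples
#' species_scenario("strong")
#' @export
species_scenario <- function(scenario = c("weak", "strong"),
                             coefficient_mean = NULL, coefficient_sd = 0.5,
                             n_true_vars = 3, n_presence_points = 50) {
  scenario <- match.arg(scenario)
  if (is.null(coefficient_mean)) {
    coefficient_mean <- if (scenario == "weak") 1 else 5
  }
  stopifnot(coefficient_sd >= 0, n_true_vars >= 1, n_presence_points >= 1)
  structure(list(scenario = scenario,
                 coefficient_mean = as.numeric(coefficient_mean),
                 coefficient_sd = as.numeric(coefficient_sd),
                 n_true_vars = as.integer(n_true_vars),
                 n_presence_points = as.integer(n_presence_points)),
            class = "species_scenario")
}

#' Draw the true driver covariates
#'
#' @param landscape A `garp_landscape`.
#' @param k Number of covariates to draw (without replacement, uniformly).
#' @param seed Integer seed.
#' @return Character vector of `k` distinct covariate names.
#' @export
select_true_variables <- function(landscape, k = 3, seed) {
  nm <- names(landscape$covariates)
  if (k > length(nm)) {
    stop(sprintf("cannot draw %d of %d covariates without replacement",
                 k, length(nm)), call. = FALSE)
  }
  withr::with_seed(as.integer(seed), sample(nm, k))
}

#' Draw niche coefficients for one species
#'
#' @param scenario A [species_scenario()].
#' @param seed Integer seed.
#' @return Numeric vector of `n_true_vars` Normal(mean, sd) draws.
#' @export
draw_coefficients <- function(scenario, seed) {
  stopifnot(inherits(scenario, "species_scenario"))
  withr::with_seed(as.integer(seed),
                   rnorm(scenario$n_true_vars, scenario$coefficient_mean,
                         scenario$coefficient_sd))
}

#' Occurrence probability surface
#'
#' The niche is ridge-shaped: `P = exp(-(beta1 x1 + beta2 x2 + beta3 x3)^2)`,
#' maximal (P = 1) where the linear combination of the true covariates is
#' zero and falling off as a Gaussian in that combination. No intercept is
#' added. Because occurrence depends on the covariates only through
#' `sum(beta * x)`, jointly permuting `(true_vars, betas)` leaves the
#' surface unchanged.
#'
#' @param landscape A `garp_landscape`.
#' @param true_vars Covariate names (must exist in the landscape).
#' @param betas Coefficients, same length as `true_vars`.
#' @return Probability matrix in (0, 1], same shape as the covariates.
#' @examples
#' ls <- simulate_landscape(grid_spec(n_cols = 20, n_rows = 20), seed = 3)
#' p <- occurrence_probability(ls, c("cov01", "cov02", "cov03"), c(5, 5, 5))
#' range(p)
#' @export
occurrence_probability <- function(landscape, true_vars, betas) {
  stopifnot(length(true_vars) == length(betas))
  missing <- setdiff(true_vars, names(landscape$covariates))
  if (length(missing) > 0) {
    stop(sprintf("covariate(s) not in landscape: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  lin <- 0
  for (i in seq_along(true_vars)) {
    lin <- lin + betas[i] * landscape$covariates[[true_vars[i]]]
  }
  exp(-lin^2)
}

#' Realize a binary distribution from a probability surface
#'
#' Independent cellwise Bernoulli trials with the given success
#' probabilities.
#'
#' @param probability Matrix of probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return Integer 0/1 matrix of the same shape.
#' @export
realize_distribution <- function(probability, seed) {
  if (any(probability < 0 | probability > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    r <- matrix(rbinom(length(probability), 1L, as.vector(probability)),
                nrow = nrow(probability))
  })
  r
}

#' Sample presence points from a realized distribution
#'
#' Draws `n` distinct presence cells (uniformly, without replacement by
#' default) and returns their centroids: presence-only data as a niche
#' model would receive it.
#'
#' @param realized Integer 0/1 matrix.
#' @param grid The matching [grid_spec()].
#' @param n Number of points.
#' @param seed Integer seed.
#' @param replace Sample cells with replacement (non-default; the standard
#'   reading is one point per cell).
#' @return Tibble with columns `x`, `y`, `cell`.
#' @export
sample_presences <- function(realized, grid, n, seed, replace = FALSE) {
  pres <- which(mat_to_cells(realized) == 1L)
  if (!replace && length(pres) < n) {
    stop(sprintf("only %d presence cells available; %d requested (short by %d)",
                 length(pres), n, n - length(pres)), call. = FALSE)
  }
  cells <- withr::with_seed(as.integer(seed), {
    if (length(pres) == 1L && !replace) pres
    else sample(pres, n, replace = replace)
  })
  cell_centroids(grid, cells)[, c("x", "y", "cell")]
}

#' Simulate one virtual species
#'
#' Full pipeline for a single species: draw the true driver covariates, draw
#' the niche coefficients for the scenario, build the occurrence-probability
#' surface, realize it as Bernoulli trials, and sample presence points from
#' presence-cell centroids. If a realization has fewer presence cells than
#' `n_presence_points`, it is rejected and re-realized with the next derived
#' seed (logged in the returned `attempts`).
#'
#' @param landscape A `garp_landscape`.
#' @param scenario A [species_scenario()].
#' @param seed Integer master seed for this species; variable selection,
#'   coefficients, realization and sampling get separate derived seeds,
#'   recorded in the result.
#' @param max_attempts Rejection limit before erroring.
#' @return A `garp_species`: list with `scenario`, `true_vars`, `betas`,
#'   `probability`, `realized`, `presences`, `seeds`, `attempts`.
#' @examples
#' ls <- simulate_landscape(grid_spec(n_cols = 40, n_rows = 40), seed = 2)
#' sp <- simulate_species(ls, species_scenario("weak"), seed = 11)
#' sp$true_vars
#' @export
simulate_species <- function(landscape, scenario = species_scenario("weak"),
                             seed, max_attempts = 25) {
  seeds <- derive_seeds(seed, 4 + max_attempts)
  true_vars <- select_true_variables(landscape, scenario$n_true_vars, seeds[1])
  betas <- draw_coefficients(scenario, seeds[2])
  prob <- occurrence_probability(landscape, true_vars, betas)
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    if (attempt > max_attempts) {
      stop(sprintf("no realization with >= %d presence cells after %d attempts",
                   scenario$n_presence_points, max_attempts), call. = FALSE)
    }
    realization_seed <- seeds[2 + attempt]
    realized <- realize_distribution(prob, realization_seed)
    if (sum(realized) >= scenario$n_presence_points) break
  }
  sampling_seed <- seeds[3 + max_attempts]
  presences <- sample_presences(realized, landscape$grid,
                                scenario$n_presence_points, sampling_seed)
  structure(list(scenario = scenario, true_vars = true_vars, betas = betas,
                 probability = prob, realized = realized,
                 presences = presences,
                 seeds = c(landscape = landscape$master_seed,
                           variables = seeds[1], betas = seeds[2],
                           realization = realization_seed,
                           sampling = sampling_seed),
                 attempts = attempt),
            class = "garp_species")
}

#' @export
print.garp_species <- function(x, ...) {
  cat(sprintf("<garp_species> %s scenario; true drivers: %s\n",
              x$scenario$scenario, paste(x$true_vars, collapse = ", ")))
  cat(sprintf("  betas: %s; %d presence cells, %d points sampled\n",
              paste(signif(x$betas, 3), collapse = ", "),
              sum(x$realized), nrow(x$presences)))
  invisible(x)
}
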