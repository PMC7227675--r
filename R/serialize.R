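# Ruleset serialization: JSON is the canonical round-trip format; the text
# dump mirrors classic desktop rule listings ("IF ... THEN species=PRESENCE")
# and is parsed back on a best-effort basis (bounds are printed as
# "(lower,upper)" so negative values stay unambiguous).

#' Format one rule as an if/then line
#'
#' @param rule A `garp_rule`.
#' @param digits Significant digits for printed numbers.
#' @return A single character string.
#' @export
format_rule <- function(rule, digits = 6) {
  num <- function(x) format(signif(x, digits), trim = TRUE, scientific = FALSE)
  cond <- switch(rule$rule_type,
                 range = paste(vapply(names(rule$bounds), function(nm)
                   sprintf("%s=(%s,%s)", nm, num(rule$bounds[[nm]][1]),
                           num(rule$bounds[[nm]][2])), ""), collapse = " AND "),
                 negated_range = paste0("NOT ", paste(
                   vapply(names(rule$bounds), function(nm)
                     sprintf("%s=(%s,%s)", nm, num(rule$bounds[[nm]][1]),
                             num(rule$bounds[[nm]][2])), ""),
                   collapse = " AND ")),
                 atomic = paste(vapply(names(rule$atoms), function(nm)
                   sprintf("%s=%s", nm, num(rule$atoms[[nm]])), ""),
                   collapse = " AND "),
                 logit = paste0("LOGIT ", paste(
                   c(vapply(names(rule$coefficients), function(nm)
                     sprintf("%s*%s", num(rule$coefficients[[nm]]), nm), ""),
                     num(rule$intercept)), collapse = " + ")))
  sprintf("IF %s THEN species=%s", cond, toupper(rule$consequent))
}

#' Serialize a ruleset
#'
#' @param rs A `garp_ruleset`.
#' @param path Output path (`.json` or text).
#' @return `path`, invisibly.
#' @export
write_ruleset_json <- function(rs, path) {
  stopifnot(inherits(rs, "garp_ruleset"))
  rules <- lapply(seq_len(length(rs)), function(i) {
    r <- decode_rule(rs$pop, i)
    list(rule_type = r$rule_type, consequent = r$consequent,
         bounds = r$bounds, coefficients = as.list(r$coefficients),
         intercept = r$intercept, atoms = as.list(r$atoms))
  })
  obj <- list(covariates = rs$covariates, tol = as.list(rs$tol),
              rules = rules, stats = rs$stats, meta = rs$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_ruleset_json
#' @export
read_ruleset_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  covn <- unlist(obj$covariates)
  rules <- lapply(obj$rules, function(r) {
    switch(r$rule_type,
           range = rule_range(lapply(r$bounds, unlist), r$consequent),
           negated_range = rule_negated_range(lapply(r$bounds, unlist),
                                              r$consequent),
           atomic = rule_atomic(unlist(r$atoms), r$consequent),
           logit = rule_logit(unlist(r$coefficients), r$intercept,
                              r$consequent))
  })
  rs <- ruleset(rules, covariates = covn, tol = unlist(obj$tol))
  if (!is.null(obj$stats)) {
    rs$stats <- dplyr::bind_rows(lapply(obj$stats, function(s)
      tibble(chisq = s$chisq %||% NA_real_,
             accuracy = s$accuracy %||% NA_real_,
             coverage = s$coverage %||% NA_real_,
             n_fired = as.integer(s$n_fired %||% NA),
             significant = s$significant %||% NA)))
  }
  if (!is.null(obj$meta)) {
    rs$meta <- list(seed = obj$meta$seed %||% NA_integer_,
                    iterations = obj$meta$iterations %||% NA_integer_,
                    converged = obj$meta$converged %||% NA,
                    convergence_value = obj$meta$convergence_value %||% NA_real_)
  }
  rs
}

#' Write and parse the human-readable rule listing
#'
#' @param rs A `garp_ruleset`.
#' @param path Text file path.
#' @return `path` invisibly (write); a `garp_ruleset` (parse).
#' @export
write_ruleset_text <- function(rs, path) {
  lines <- vapply(seq_len(length(rs)), function(i)
    format_rule(decode_rule(rs$pop, i), digits = 15), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_ruleset_text
#' @param covariates Covariate universe; defaults to the union referenced.
#' @param tol Atomic binning tolerance per covariate.
#' @export
parse_ruleset_text <- function(path, covariates = NULL, tol = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  rules <- lapply(lines, parse_rule_line)
  ruleset(rules, covariates = covariates, tol = tol)
}

parse_rule_line <- function(line) {
  m <- regmatches(line, regexec("^IF\\s+(.*)\\s+THEN\\s+species=(PRESENCE|ABSENCE)\\s*$",
                                line, ignore.case = TRUE))[[1]]
  if (length(m) != 3) stop(sprintf("cannot parse rule line: '%s'", line),
                           call. = FALSE)
  cond <- m[2]
  conseq <- tolower(m[3])
  if (grepl("^LOGIT\\s", cond, ignore.case = TRUE)) {
    terms <- strsplit(sub("^LOGIT\\s+", "", cond, ignore.case = TRUE),
                      "\\s\\+\\s")[[1]]
    coefs <- c(); intercept <- 0
    for (t in terms) {
      if (grepl("\\*", t)) {
        parts <- strsplit(t, "\\*")[[1]]
        coefs[trimws(parts[2])] <- as.numeric(parts[1])
      } else {
        intercept <- as.numeric(t)
      }
    }
    return(rule_logit(coefs, intercept, conseq))
  }
  negated <- grepl("^NOT\\s", cond)
  if (negated) cond <- sub("^NOT\\s+", "", cond)
  terms <- strsplit(cond, "\\s+AND\\s+")[[1]]
  if (all(grepl("=\\(", terms))) {
    bounds <- list()
    for (t in terms) {
      p <- regmatches(t, regexec("^(\\S+)=\\(([^,]+),([^)]+)\\)$", t))[[1]]
      if (length(p) != 4) stop(sprintf("cannot parse range term: '%s'", t),
                               call. = FALSE)
      bounds[[p[2]]] <- c(as.numeric(p[3]), as.numeric(p[4]))
    }
    if (negated) rule_negated_range(bounds, conseq) else rule_range(bounds, conseq)
  } else {
    atoms <- c()
    for (t in terms) {
      p <- strsplit(t, "=")[[1]]
      atoms[trimws(p[1])] <- as.numeric(p[2])
    }
    rule_atomic(atoms, conseq)
  }
}
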