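#' @importFrom stats aggregate as.formula binomial coef glm median plogis
#'   prop.test qlogis qnorm quantile rbinom rnorm runif sd setNames vcov
#'   complete.cases lm pnorm predict rgamma rpois update AIC logLik rchisq
#' @importFrom utils head read.csv write.csv
NULL

# canonical aggregate variables a rule predicate may reference
.sofa_vars <- c("pf_ratio", "sf_ratio", "platelets", "bilirubin", "map",
                "gcs", "creatinine", "urine_output", "nee")
# support flags a rule predicate may reference
.sofa_flags <- c("mechanical_ventilation", "resp_support", "rrt", "ecmo",
                 "delirium_medication", "vasopressor", "inotrope")
.sofa_domains <- c("respiration", "coagulation", "liver", "cardiovascular",
                   "brain", "renal")

#' Path to a shipped SOFA threshold table
#'
#' The package ships two threshold tables as YAML configuration:
#' `"sofa1"` (the classical 1996 system, cardiovascular domain banded on
#' noradrenaline equivalents) and `"sofa2"` (the 2025 recalibration with
#' ECMO/RRT/delirium-medication rules). The scoring engine itself is
#' threshold-agnostic; any table following the same schema can be used.
#'
#' @param system `"sofa1"` or `"sofa2"`.
#' @return Path to the YAML file.
#' @export
sofa_table_path <- function(system = c("sofa1", "sofa2")) {
  system <- match.arg(system)
  system.file("extdata", paste0(system, ".yaml"), package = "sofaval",
              mustWork = TRUE)
}

#' Read and validate a SOFA threshold table
#'
#' Parses a YAML threshold document into a `sofa_table` object. The schema
#' has six domains (respiration, coagulation, liver, cardiovascular, brain,
#' renal), each with an ordered rule list mapping predicates over worst-value
#' aggregates and therapy support flags to integer points 0--4. Rules are
#' evaluated highest-points-first; the first matching rule wins and an
#' unmatched row scores 0. The document also carries unit conversions to the
#' canonical units (µmol/L bilirubin/creatinine, 10^9/L platelets, mmHg,
#' FiO2 as a fraction), noradrenaline-equivalence factors per vasopressor,
#' and the per-domain normal values used for day-1 imputation.
#'
#' @param path Path to a YAML file, or `"sofa1"` / `"sofa2"` for a shipped
#'   table.
#' @return A `sofa_table` object.
#' @examples
#' tab <- read_score_table("sofa1")
#' tab
#' @export
read_score_table <- function(path) {
  if (path %in% c("sofa1", "sofa2")) path <- sofa_table_path(path)
  doc <- yaml::read_yaml(path)
  validate_score_table(doc)
  # order rules highest-points-first within each domain
  doc$domains <- lapply(doc$domains, function(d) {
    pts <- vapply(d$rules, function(r) as.integer(r$points), integer(1))
    d$rules <- d$rules[order(pts, decreasing = TRUE)]
    d
  })
  names(doc$domains) <- vapply(doc$domains, `[[`, "", "name")
  structure(doc, class = "sofa_table")
}

#' Validate a threshold-table document
#'
#' Checks the structural invariants of a threshold table: exactly the six
#' SOFA domains, every rule's points in 1--4, predicates referencing only
#' known aggregate variables and support flags, noradrenaline factor 1 for
#' noradrenaline itself, and normal values present for every aggregate.
#'
#' @param doc A list as parsed from the YAML schema.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_score_table <- function(doc) {
  stopifnot(is.list(doc), !is.null(doc$system), !is.null(doc$domains))
  dn <- vapply(doc$domains, `[[`, "", "name")
  if (!setequal(dn, .sofa_domains) || anyDuplicated(dn)) {
    stop("score table must define exactly the six domains: ",
         paste(.sofa_domains, collapse = ", "))
  }
  for (d in doc$domains) {
    for (r in d$rules) {
      p <- as.integer(r$points)
      if (is.na(p) || p < 1L || p > 4L) {
        stop("rule points must be integers in 1..4 (domain ", d$name, ")")
      }
      .check_predicate(r$when, d$name)
    }
  }
  if (!is.null(doc$nee_factors)) {
    if (!isTRUE(all.equal(doc$nee_factors[["noradrenaline"]], 1)))
      stop("noradrenaline must have equivalence factor 1")
    if (any(unlist(doc$nee_factors) < 0))
      stop("noradrenaline-equivalence factors must be non-negative")
  }
  nv <- doc$normal_values
  missing_nv <- setdiff(.sofa_vars, names(nv))
  if (length(missing_nv))
    stop("normal_values missing for: ", paste(missing_nv, collapse = ", "))
  invisible(TRUE)
}

.check_predicate <- function(p, domain) {
  if (!is.list(p)) stop("malformed predicate in domain ", domain)
  if (!is.null(p$all_of) || !is.null(p$any_of)) {
    kids <- if (!is.null(p$all_of)) p$all_of else p$any_of
    for (k in kids) .check_predicate(k, domain)
  } else if (!is.null(p$flag)) {
    if (!p$flag %in% .sofa_flags)
      stop("unknown support flag '", p$flag, "' in domain ", domain)
  } else if (!is.null(p$var)) {
    if (!p$var %in% .sofa_vars)
      stop("unknown aggregate variable '", p$var, "' in domain ", domain)
    if (!p$op %in% c("<", "<=", ">", ">=", "=="))
      stop("unknown comparison operator '", p$op, "' in domain ", domain)
    if (!is.numeric(p$value)) stop("non-numeric threshold in domain ", domain)
  } else {
    stop("predicate must contain var/op/value, flag, all_of or any_of ",
         "(domain ", domain, ")")
  }
  invisible(TRUE)
}

#' @export
print.sofa_table <- function(x, ...) {
  cat("<sofa_table> ", x$system, " (version ", x$version, ")\n", sep = "")
  for (d in x$domains) {
    cat("  ", format(d$name, width = 15), length(d$rules), "rules\n")
  }
  cat("  nee factors:", paste(names(x$nee_factors), unlist(x$nee_factors),
                              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Evaluate a rule predicate vectorised over a scoring grid.
# `grid` holds numeric columns for aggregates and logical columns for flags;
# NA aggregate values make a comparison FALSE (never NA).
.eval_predicate <- function(p, grid) {
  if (!is.null(p$all_of)) {
    out <- rep(TRUE, nrow(grid))
    for (k in p$all_of) out <- out & .eval_predicate(k, grid)
    out
  } else if (!is.null(p$any_of)) {
    out <- rep(FALSE, nrow(grid))
    for (k in p$any_of) out <- out | .eval_predicate(k, grid)
    out
  } else if (!is.null(p$flag)) {
    v <- grid[[p$flag]]
    if (is.null(v)) rep(FALSE, nrow(grid)) else !is.na(v) & v
  } else {
    v <- grid[[p$var]]
    if (is.null(v)) return(rep(FALSE, nrow(grid)))
    out <- switch(p$op,
      "<"  = v <  p$value,
      "<=" = v <= p$value,
      ">"  = v >  p$value,
      ">=" = v >= p$value,
      "==" = v == p$value)
    out & !is.na(out)
  }
}
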