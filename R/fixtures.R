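# Deterministic fixtures reconstructed from printed marginal summaries.
# These are synthetic person-level tables that reproduce published margins
# exactly after integer rounding; they contain no patient data.

#' Person-level fixture from group shares and group mortality
#'
#' Reconstructs a person-level table from marginal summaries: group sizes by
#' deterministic largest-remainder rounding of `n * shares` (so counts sum
#' exactly to `n`), and deaths per group by nearest-integer rounding of
#' `count * mortality`. No randomness is involved.
#'
#' @param n Total number of records.
#' @param shares Numeric vector of group shares (must sum to ~1).
#' @param mortality Numeric vector of per-group death proportions.
#' @param groups Group labels.
#' @return Data frame `admission_id`, `group`, `died` whose margins
#'   reproduce the request after rounding.
#' @examples
#' fx <- fixture_from_margins(29820, c(0.245, 0.153, 0.602),
#'                            c(0.143, 0.203, 0.128))
#' table(fx$group)
#' @export
fixture_from_margins <- function(n, shares, mortality,
                                 groups = c("equal", "sofa2_higher",
                                            "sofa2_lower")[seq_along(shares)]) {
  stopifnot(length(shares) == length(mortality),
            length(groups) == length(shares),
            abs(sum(shares) - 1) < 0.01, all(shares >= 0),
            all(mortality >= 0 & mortality <= 1))
  counts <- largest_remainder_round(n * shares, n)
  if (any(counts > n)) stop("infeasible margins: group count exceeds n")
  deaths <- floor(counts * mortality + 0.5)
  if (any(deaths > counts)) stop("infeasible margins: deaths exceed count")
  group <- rep(groups, counts)
  died <- unlist(lapply(seq_along(counts), function(i)
    rep(c(TRUE, FALSE), c(deaths[i], counts[i] - deaths[i]))))
  data.frame(admission_id = sprintf("fx%05d", seq_len(sum(counts))),
             group = factor(group, levels = groups), died = died)
}

#' Largest-remainder rounding to a fixed total
#'
#' Rounds non-negative reals to integers summing exactly to `total`:
#' floor everything, then distribute the remaining units to the largest
#' fractional parts (ties broken by position).
#'
#' @param x Non-negative numeric vector.
#' @param total Target integer sum (default `round(sum(x))`).
#' @return Integer vector summing to `total`.
#' @export
largest_remainder_round <- function(x, total = round(sum(x))) {
  stopifnot(all(x >= 0))
  f <- floor(x)
  rem <- total - sum(f)
  if (rem < 0) stop("total below the floor sum")
  ord <- order(x - f, decreasing = TRUE)
  bump <- ord[seq_len(rem)]
  f[bump] <- f[bump] + 1
  as.integer(f)
}

#' Admission-table fixture with planted exclusion flags
#'
#' Builds a raw admission table of `n_total` rows of which exactly
#' `n_invalid_ssn` lack a valid social security number, `n_external_icu`
#' are referred from external ICUs, and `n_under18` are minors — the flag
#' sets are disjoint, so the cohort-flow filter retains
#' `n_total - n_invalid_ssn - n_external_icu - n_under18` admissions.
#'
#' @param n_total Total raw admissions.
#' @param n_invalid_ssn,n_external_icu,n_under18 Flag counts.
#' @param n_overlap Number of admissions carrying both the invalid-SSN and
#'   the external-ICU flag (flag counts then refer to the flagged totals, so
#'   the retained cohort is `n_total - n_invalid_ssn - n_external_icu +
#'   n_overlap - n_under18`). Published flow diagrams sometimes report flag
#'   totals whose sum exceeds the number actually excluded; the overlap
#'   reconciles them.
#' @return Admission data frame consumable by [apply_exclusions()].
#' @export
fixture_admission_flow <- function(n_total, n_invalid_ssn = 0,
                                   n_external_icu = 0, n_under18 = 0,
                                   n_overlap = 0) {
  stopifnot(n_overlap <= min(n_invalid_ssn, n_external_icu),
            n_invalid_ssn + n_external_icu - n_overlap + n_under18 <= n_total)
  id <- sprintf("raw%05d", seq_len(n_total))
  ssn <- rep(TRUE, n_total)
  ext <- rep(FALSE, n_total)
  age <- rep(60, n_total)
  if (n_invalid_ssn) ssn[seq_len(n_invalid_ssn)] <- FALSE
  # the first n_overlap invalid-SSN rows also carry the external flag
  if (n_overlap) ext[seq_len(n_overlap)] <- TRUE
  n_ext_only <- n_external_icu - n_overlap
  if (n_ext_only) ext[n_invalid_ssn + seq_len(n_ext_only)] <- TRUE
  i <- n_invalid_ssn + n_ext_only
  if (n_under18) age[i + seq_len(n_under18)] <- 17
  data.frame(admission_id = id, has_valid_ssn = ssn,
             referred_from_external_icu = ext, age = age)
}
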