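# Daily reclassification between two scoring systems and per-day mortality
# odds ratios from a day x group interaction logistic model.

#' Classify an admission-day by the relation between two total scores
#'
#' @param total_sofa2,total_sofa1 Numeric vectors of daily totals.
#' @return Factor with levels `equal`, `sofa2_higher`, `sofa2_lower`
#'   (`equal` is the reference).
#' @export
classify_day <- function(total_sofa2, total_sofa1) {
  stopifnot(length(total_sofa2) == length(total_sofa1))
  s <- sign(total_sofa2 - total_sofa1)
  factor(c("sofa2_lower", "equal", "sofa2_higher")[s + 2],
         levels = c("equal", "sofa2_higher", "sofa2_lower"))
}

#' Build day-level reclassification records from two daily-score tables
#'
#' Joins the two systems' totals on (admission, day), classifies each
#' admission-day, and attaches the outcome label.
#'
#' @param daily_a Daily scores of the comparator system (treated as
#'   "SOFA-2" in the group labels).
#' @param daily_b Daily scores of the reference system ("SOFA-1").
#' @param outcomes Data frame `admission_id` plus an outcome column.
#' @param outcome Name of the outcome column (default `death_30d`).
#' @return Data frame `admission_id`, `day`, `group`, `outcome`.
#' @export
reclass_records <- function(daily_a, daily_b, outcomes,
                            outcome = "death_30d") {
  a <- as.data.frame(daily_a)[c("admission_id", "day", "total")]
  b <- as.data.frame(daily_b)[c("admission_id", "day", "total")]
  m <- merge(a, b, by = c("admission_id", "day"), suffixes = c("_a", "_b"))
  m <- m[!is.na(m$total_a) & !is.na(m$total_b), ]
  m$group <- classify_day(m$total_a, m$total_b)
  o <- as.data.frame(outcomes)[c("admission_id", outcome)]
  names(o)[2] <- "outcome"
  m <- merge(m, o, by = "admission_id")
  m[c("admission_id", "day", "group", "outcome")]
}

#' Per-day reclassification proportions and group mortality
#'
#' For each requested day, the share of admission-days in each group with a
#' Wilson 95% CI, and the group-specific outcome proportion. Proportions
#' sum to 1 per day; a requested day without records is omitted with a
#' warning.
#'
#' @param records As from [reclass_records()].
#' @param days Integer vector of days to report (default 1--7).
#' @param conf_level CI level.
#' @return Data frame `day`, `group`, `n`, `proportion`, `ci_low`,
#'   `ci_high`, `mortality`.
#' @export
reclassification_summary <- function(records, days = 1:7, conf_level = 0.95) {
  out <- list()
  for (d in days) {
    r <- records[records$day == d, ]
    if (!nrow(r)) { warning("no records on day ", d, "; omitted"); next }
    nd <- nrow(r)
    for (g in levels(records$group)) {
      rg <- r[r$group == g, ]
      ci <- prop_ci(nrow(rg), nd, conf_level)
      out[[length(out) + 1L]] <- data.frame(
        day = d, group = g, n = nrow(rg), proportion = nrow(rg) / nd,
        ci_low = ci$ci_low, ci_high = ci$ci_high,
        mortality = if (nrow(rg)) mean(rg$outcome) else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Daily mortality odds ratios per reclassification group
#'
#' Fits a single logistic regression of the outcome on ICU-day (categorical)
#' interacted with reclassification group, then extracts, for each day, the
#' odds ratio of each non-reference group versus the `equal` reference.
#' Because day is categorical and group is the only other predictor, the
#' model is saturated and each per-day OR equals the corresponding 2x2
#' contingency odds ratio. CIs and p-values are Bonferroni-adjusted for the
#' `m` simultaneously reported contrasts (default: all day-group contrasts).
#'
#' @param records As from [reclass_records()].
#' @param days Days to report.
#' @param m_adjust Number of comparisons for the Bonferroni family; default
#'   `length(days) * 2`. Use 1 for unadjusted results.
#' @param alpha Nominal two-sided level before adjustment.
#' @return Data frame of class `sofa_daily_or`: `day`, `group`, `or`,
#'   `ci_low`, `ci_high`, `p`, `p_adj`, `adjusted`, `n`. Days where a group
#'   is absent are reported as `NA` rows, never extrapolated; quasi-separated
#'   contrasts are flagged via infinite CI bounds.
#' @export
daily_group_or <- function(records, days = sort(unique(records$day)),
                           m_adjust = NULL, alpha = 0.05) {
  r <- records[records$day %in% days, ]
  r$day_f <- factor(r$day)
  r$group <- droplevels(factor(r$group,
                               levels = c("equal", "sofa2_higher", "sofa2_lower")))
  for (d in days) {
    if (!any(r$day == d & r$group == "equal"))
      stop("day ", d, " has no records in the reference (equal) group")
  }
  form <- if (length(unique(r$day)) > 1) outcome ~ day_f * group else
    outcome ~ group
  fit <- stats::glm(form, family = stats::binomial(),
                    data = r, control = list(epsilon = 1e-12, maxit = 100))
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  grps <- setdiff(levels(r$group), "equal")
  m <- if (is.null(m_adjust)) length(days) * length(grps) else m_adjust
  zq <- stats::qnorm(1 - (alpha / m) / 2)
  base_day <- levels(r$day_f)[1]
  out <- list()
  for (d in days) {
    for (g in grps) {
      n_dg <- sum(r$day == d & r$group == g)
      if (n_dg == 0) {
        out[[length(out) + 1L]] <- data.frame(
          day = d, group = g, or = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, p = NA_real_, p_adj = NA_real_,
          adjusted = m > 1, n = 0L)
        next
      }
      sel <- paste0("group", g)
      if (as.character(d) != base_day) {
        inter <- paste0("day_f", d, ":group", g)
        idx <- c(sel, inter)
      } else idx <- sel
      idx <- idx[idx %in% names(cf)]
      est <- sum(cf[idx])
      se <- sqrt(sum(V[idx, idx]))
      p <- 2 * stats::pnorm(-abs(est / se))
      out[[length(out) + 1L]] <- data.frame(
        day = d, group = g, or = exp(est),
        ci_low = exp(est - zq * se), ci_high = exp(est + zq * se),
        p = p, p_adj = min(1, m * p), adjusted = m > 1, n = n_dg)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("sofa_daily_or", "data.frame")
  attr(res, "m_adjust") <- m
  attr(res, "fit") <- fit
  res
}

#' @export
print.sofa_daily_or <- function(x, digits = 3, ...) {
  cat("<daily reclassification ORs> (reference: equal scores; Bonferroni m =",
      attr(x, "m_adjust"), ")\n")
  print.data.frame(cbind(x[c("day", "group", "n")],
                         round(x[c("or", "ci_low", "ci_high", "p_adj")],
                               digits)), row.names = FALSE)
  invisible(x)
}

#' Odds ratio of a 2x2 table
#'
#' Closed-form `(a/b) / (c/d)` odds ratio used as the independent check of
#' the saturated interaction model.
#'
#' @param events_1,n_1 Events and totals in the index group.
#' @param events_0,n_0 Events and totals in the reference group.
#' @return The odds ratio.
#' @export
or_2x2 <- function(events_1, n_1, events_0, n_0) {
  (events_1 / (n_1 - events_1)) / (events_0 / (n_0 - events_0))
}
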