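# Cohort construction: exclusion filters, Charlson comorbidity
# classification, retrospective sepsis-3 at admission, and mortality labels.

#' Apply cohort exclusion filters
#'
#' Removes, in order: admissions without a valid social security number,
#' admissions referred from ICUs outside the participating hospitals, and
#' patients under 18 years. Returns the retained cohort together with a
#' per-step tally for a cohort flow diagram; tallies plus the retained count
#' always equal the input count.
#'
#' @param admissions Data frame with (at least) `admission_id`,
#'   `has_valid_ssn`, `referred_from_external_icu`, `age`.
#' @return List with `cohort` (retained rows) and `tally` (data frame
#'   `step`, `excluded`, `remaining`).
#' @export
apply_exclusions <- function(admissions) {
  a <- as.data.frame(admissions)
  n0 <- nrow(a)
  steps <- character(0); excl <- integer(0); rem <- integer(0)
  drop1 <- !isTRUE_vec(a$has_valid_ssn)
  a1 <- a[!drop1, , drop = FALSE]
  steps <- c(steps, "no_valid_ssn"); excl <- c(excl, sum(drop1))
  rem <- c(rem, nrow(a1))
  drop2 <- isTRUE_vec(a1$referred_from_external_icu)
  a2 <- a1[!drop2, , drop = FALSE]
  steps <- c(steps, "external_icu_referral"); excl <- c(excl, sum(drop2))
  rem <- c(rem, nrow(a2))
  drop3 <- !is.na(a2$age) & a2$age < 18
  a3 <- a2[!drop3, , drop = FALSE]
  steps <- c(steps, "age_under_18"); excl <- c(excl, sum(drop3))
  rem <- c(rem, nrow(a3))
  tally <- data.frame(step = steps, excluded = excl, remaining = rem)
  stopifnot(sum(tally$excluded) + nrow(a3) == n0)
  list(cohort = a3, tally = tally, n_input = n0)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Read the shipped ICD-10 Charlson mapping
#'
#' A standard ICD-10 prefix mapping to Charlson categories and weights,
#' with a `group` column assigning categories to the five descriptive
#' comorbidity groups (renal, liver, cardiovascular, pulmonary, malignancy).
#' The mapping is swappable configuration: any data frame with columns
#' `prefix`, `category`, `weight`, `group` works.
#'
#' @param path Optional path to an alternative mapping CSV.
#' @return Data frame `prefix`, `category`, `weight`, `group`.
#' @export
read_charlson_mapping <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "charlson_icd10.csv", package = "sofaval",
                        mustWork = TRUE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("prefix", "category", "weight", "group") %in% names(m)))
  m
}

#' Charlson comorbidity index from ICD-10 codes
#'
#' Matches each code by prefix against the mapping (longest prefix wins),
#' sums weights over distinct matched categories, and raises the five
#' descriptive group flags. Malformed code strings are skipped (and
#' reported via the `skipped` attribute), never fatal.
#'
#' @param icd10 Data frame `admission_id`, `code`, or a character vector of
#'   codes for a single admission.
#' @param mapping A mapping as from [read_charlson_mapping()].
#' @return Data frame `admission_id`, `cci`, and logical flags `renal`,
#'   `liver`, `cardiovascular`, `pulmonary`, `malignancy`. Adding codes can
#'   never decrease `cci`.
#' @examples
#' charlson_index(c("I21", "C34"))  # cci 3, cardiovascular + malignancy
#' @export
charlson_index <- function(icd10, mapping = read_charlson_mapping()) {
  if (is.atomic(icd10)) {
    codes <- as.character(icd10[!is.na(icd10)])
    icd10 <- data.frame(admission_id = rep("x", length(codes)), code = codes)
  }
  icd10 <- as.data.frame(icd10)
  code <- toupper(gsub("[. ]", "", as.character(icd10$code)))
  ok <- grepl("^[A-Z][0-9]", code)
  skipped <- icd10$code[!ok]
  icd10 <- icd10[ok, , drop = FALSE]; code <- code[ok]

  mp <- mapping[order(-nchar(mapping$prefix)), ]
  cat_of <- rep(NA_character_, length(code))
  for (i in seq_len(nrow(mp))) {
    hit <- is.na(cat_of) & startsWith(code, mp$prefix[i])
    cat_of[hit] <- mp$category[i]
  }
  w <- stats::setNames(mp$weight, mp$category)
  g <- stats::setNames(mp$group, mp$category)
  groups <- c("renal", "liver", "cardiovascular", "pulmonary", "malignancy")

  ids <- unique(as.character(icd10$admission_id))
  dt <- data.table::data.table(admission_id = as.character(icd10$admission_id),
                               category = cat_of)[!is.na(category)]
  dt <- unique(dt)
  agg <- dt[, {
    cats <- category
    fl <- lapply(groups, function(gr) any(g[cats] %in% gr))
    c(list(cci = sum(w[cats])), stats::setNames(fl, groups))
  }, by = admission_id]
  out <- merge(data.frame(admission_id = ids), as.data.frame(agg),
               by = "admission_id", all.x = TRUE)
  out$cci[is.na(out$cci)] <- 0
  for (gr in groups) out[[gr]][is.na(out[[gr]])] <- FALSE
  attr(out, "skipped") <- skipped
  out
}

#' Suspected-infection episodes from antibiotic and culture events
#'
#' Implements the retrospective pairing convention: antibiotics labelled
#' `prophylaxis`, `single_dose`, or `intraoperative` (the latter only for
#' elective-surgical admissions when `admissions` is supplied; otherwise
#' always) are disregarded. A qualifying episode is a culture followed by an
#' antibiotic within `culture_first_h` (default 72 h), or an antibiotic
#' followed by a culture within `antibiotic_first_h` (default 24 h); episode
#' onset is the earlier event of the pair.
#'
#' @param antibiotics Data frame `admission_id`, `time_h`, optional `label`.
#' @param cultures Data frame `admission_id`, `time_h`.
#' @param admissions Optional data frame with `admission_id`,
#'   `admission_type` used to restrict the intraoperative exclusion to
#'   elective surgery.
#' @param culture_first_h,antibiotic_first_h Pairing windows in hours.
#' @return Data frame `admission_id`, `onset_h` (earliest qualifying onset
#'   per admission).
#' @export
suspected_infection <- function(antibiotics, cultures, admissions = NULL,
                                culture_first_h = 72, antibiotic_first_h = 24) {
  ab <- as.data.frame(antibiotics)
  if (!"label" %in% names(ab)) ab$label <- ""
  ab$label[is.na(ab$label)] <- ""
  drop <- ab$label %in% c("prophylaxis", "single_dose")
  intra <- ab$label == "intraoperative"
  if (!is.null(admissions)) {
    elect <- admissions$admission_id[admissions$admission_type == "elective_surgical"]
    drop <- drop | (intra & ab$admission_id %in% elect)
  } else drop <- drop | intra
  ab <- ab[!drop, , drop = FALSE]
  cu <- as.data.frame(cultures)
  if (!nrow(ab) || !nrow(cu))
    return(data.frame(admission_id = character(0), onset_h = numeric(0)))
  m <- merge(ab[c("admission_id", "time_h")], cu[c("admission_id", "time_h")],
             by = "admission_id", suffixes = c("_ab", "_cu"))
  cf <- m$time_h_ab >= m$time_h_cu & m$time_h_ab - m$time_h_cu <= culture_first_h
  af <- m$time_h_cu > m$time_h_ab & m$time_h_cu - m$time_h_ab <= antibiotic_first_h
  onset <- ifelse(cf, m$time_h_cu, ifelse(af, m$time_h_ab, NA_real_))
  m <- m[!is.na(onset), , drop = FALSE]
  onset <- onset[!is.na(onset)]
  if (!nrow(m))
    return(data.frame(admission_id = character(0), onset_h = numeric(0)))
  agg <- stats::aggregate(onset, by = list(admission_id = m$admission_id), FUN = min)
  names(agg)[2] <- "onset_h"
  agg
}

#' Sepsis at ICU admission (retrospective sepsis-3)
#'
#' An admission has sepsis at admission when a suspected-infection onset
#' falls within the configured window around ICU admission (default the
#' two-sided window \[-24 h, +24 h\]) and, when daily scores and a threshold
#' are supplied, the day-1 total score meets the acute organ-dysfunction
#' criterion (default total >= 2 against the implicit pre-ICU baseline of
#' 0). With `sofa_threshold = NULL` the infection-timing criterion alone is
#' used.
#'
#' @param episodes Output of [suspected_infection()].
#' @param admission_ids Character vector of all admission ids to label.
#' @param window_h Numeric length 2, window around admission in hours.
#' @param day1_total Optional named vector (by admission id) of day-1 total
#'   scores.
#' @param sofa_threshold Minimum day-1 total for the dysfunction criterion,
#'   or `NULL` to skip it.
#' @return Logical vector named by `admission_ids`.
#' @export
sepsis_at_admission <- function(episodes, admission_ids,
                                window_h = c(-24, 24),
                                day1_total = NULL, sofa_threshold = NULL) {
  stopifnot(length(window_h) == 2, window_h[1] <= window_h[2])
  hit <- episodes$admission_id[episodes$onset_h >= window_h[1] &
                                 episodes$onset_h <= window_h[2]]
  out <- stats::setNames(admission_ids %in% hit, admission_ids)
  if (!is.null(sofa_threshold) && !is.null(day1_total)) {
    meets <- !is.na(day1_total[admission_ids]) &
      day1_total[admission_ids] >= sofa_threshold
    out <- out & meets
  }
  out
}

#' 30-day and ICU mortality labels
#'
#' `death_30d` is true when death occurred within 30 days of ICU admission
#' (day-30 boundary inclusive); `icu_death` when death occurred between ICU
#' admission and ICU discharge. A death recorded before admission is a
#' validation error.
#'
#' @param admissions Data frame with `admission_id`, `admission_time`
#'   (`POSIXct` or `Date`), `icu_discharge_time` (may be `NA` for open
#'   stays).
#' @param deaths Data frame `admission_id`, `death_date` (`Date`).
#' @return Data frame `admission_id`, `death_30d`, `icu_death`.
#' @export
outcome_labels <- function(admissions, deaths) {
  a <- as.data.frame(admissions)
  d <- as.data.frame(deaths)
  m <- merge(a[c("admission_id", "admission_time", "icu_discharge_time")],
             d[c("admission_id", "death_date")],
             by = "admission_id", all.x = TRUE)
  adm_d <- as.Date(m$admission_time)
  dis_d <- as.Date(m$icu_discharge_time)
  dth <- as.Date(m$death_date)
  if (any(!is.na(dth) & dth < adm_d))
    stop("death date before ICU admission for admission(s): ",
         paste(utils::head(m$admission_id[!is.na(dth) & dth < adm_d], 5),
               collapse = ", "))
  death_30d <- !is.na(dth) & (as.numeric(dth - adm_d) <= 30)
  icu_death <- !is.na(dth) & !is.na(dis_d) & dth >= adm_d & dth <= dis_d
  data.frame(admission_id = m$admission_id, death_30d = death_30d,
             icu_death = icu_death)
}

#' Binomial proportion with Wilson 95% confidence interval
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf_level Confidence level.
#' @return List `p`, `ci_low`, `ci_high`, `percent` (100 * p).
#' @export
prop_ci <- function(x, n, conf_level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  p <- x / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  list(p = p, ci_low = max(0, centre - half),
       ci_high = min(1, centre + half), percent = 100 * p)
}
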