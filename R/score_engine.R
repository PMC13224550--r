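#' @import data.table
NULL

# map each domain to the aggregate variables it scores on; the first entry is
# the domain's "primary" value reported in DailyDomainRecord
.domain_vars <- list(
  respiration    = c("pf_ratio", "sf_ratio"),
  coagulation    = "platelets",
  liver          = "bilirubin",
  cardiovascular = c("map", "nee"),
  brain          = "gcs",
  renal          = c("creatinine", "urine_output")
)

.obs_variables <- c("platelets", "bilirubin", "creatinine", "urine_output",
                    "map", "gcs_total", "gcs_eye", "gcs_verbal", "gcs_motor",
                    "pao2", "fio2", "spo2")

#' Combined vasopressor dose in noradrenaline equivalents
#'
#' Converts a set of simultaneous vasopressor infusion rates into a single
#' noradrenaline-equivalent rate (µg/kg/min) by summing `rate * factor` over
#' drugs. Noradrenaline itself has factor 1; factors for other drugs are
#' configuration (the shipped defaults follow the published
#' noradrenaline-equivalence literature, e.g. dopamine 0.01,
#' phenylephrine 0.1, vasopressin 2.5 per U/min).
#'
#' @param rates Named numeric vector of infusion rates (names are drug names).
#' @param factors Named numeric vector of equivalence factors; defaults to the
#'   factors of the shipped SOFA-1 table.
#' @return A single non-negative number.
#' @examples
#' noradrenaline_equivalent(c(noradrenaline = 0.05, adrenaline = 0.05))
#' @export
noradrenaline_equivalent <- function(rates, factors = NULL) {
  if (length(rates) == 0) return(0)
  if (is.null(factors)) {
    factors <- unlist(read_score_table("sofa1")$nee_factors)
  }
  if (is.null(names(rates)) || any(!nzchar(names(rates))))
    stop("rates must be a named vector (drug names)")
  if (any(rates < 0)) stop("infusion rates must be non-negative")
  unknown <- setdiff(names(rates), names(factors))
  if (length(unknown))
    stop("no noradrenaline-equivalence factor for drug(s): ",
         paste(unknown, collapse = ", "))
  sum(rates * factors[names(rates)])
}

# Validate raw observation rows against type invariants. Returns the clean
# table plus a log of rejected rows with reasons (never silently dropped).
.validate_observations <- function(obs, table) {
  obs <- as.data.table(obs)
  req <- c("admission_id", "variable", "time_h", "value")
  miss <- setdiff(req, names(obs))
  if (length(miss)) stop("observations missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"unit" %in% names(obs)) obs[, unit := NA_character_]
  reason <- rep(NA_character_, nrow(obs))
  reason[!obs$variable %in% .obs_variables] <- "unknown variable"
  reason[is.na(reason) & (is.na(obs$time_h) | obs$time_h < 0)] <- "negative or missing time"
  reason[is.na(reason) & !is.finite(obs$value)] <- "non-finite value"

  # unit conversion to canonical units
  conv <- table$unit_conversions
  fac <- rep(1, nrow(obs))
  has_unit <- !is.na(obs$unit) & nzchar(obs$unit)
  for (v in unique(obs$variable[has_unit])) {
    idx <- which(has_unit & obs$variable == v & is.na(reason))
    if (!length(idx)) next
    cv <- conv[[v]]
    for (i in idx) {
      f <- cv[[obs$unit[i]]]
      if (is.null(f)) reason[i] <- paste0("unknown unit '", obs$unit[i],
                                          "' for ", v) else fac[i] <- f
    }
  }
  obs[, value := value * fac]

  ok <- is.na(reason)
  chk <- function(v, lo, hi, what) {
    bad <- ok & obs$variable == v & (obs$value < lo | obs$value > hi)
    reason[bad] <<- what
    ok <<- is.na(reason)
  }
  chk("fio2", 0.21, 1.0, "fio2 outside [0.21, 1]")
  chk("gcs_eye", 1, 4, "gcs_eye outside 1-4")
  chk("gcs_verbal", 1, 5, "gcs_verbal outside 1-5")
  chk("gcs_motor", 1, 6, "gcs_motor outside 1-6")
  chk("gcs_total", 3, 15, "gcs_total outside 3-15")

  errors <- data.frame(obs[!ok, .(admission_id, variable, time_h, value)],
                       reason = reason[!ok])
  list(clean = obs[ok], errors = errors)
}

# Merge overlapping/duplicate therapy intervals per (admission, therapy, drug)
# so overlapping records are never double counted; validates interval fields.
.validate_therapies <- function(ther) {
  ther <- as.data.table(ther)
  req <- c("admission_id", "therapy", "start_h", "end_h")
  miss <- setdiff(req, names(ther))
  if (length(miss)) stop("therapies missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"drug" %in% names(ther)) ther[, drug := NA_character_]
  if (!"rate" %in% names(ther)) ther[, rate := NA_real_]
  bad <- is.na(ther$start_h) | is.na(ther$end_h) | ther$start_h >= ther$end_h |
    ther$start_h < 0
  if (any(ther$therapy == "vasopressor" & (is.na(ther$rate) | ther$rate < 0)))
    stop("vasopressor intervals require a non-negative rate")
  errors <- data.frame(ther[bad, .(admission_id, therapy, start_h, end_h)],
                       reason = if (any(bad)) "invalid interval" else character(0))
  ther <- ther[!bad]
  # merge overlaps (same rate for vasopressors; others rate-free)
  setorder(ther, admission_id, therapy, drug, rate, start_h, na.last = TRUE)
  merged <- ther[, {
    o <- order(start_h)
    s <- start_h[o]; e <- end_h[o]
    keep_s <- s[1]; keep_e <- e[1]
    out_s <- numeric(0); out_e <- numeric(0)
    if (length(s) > 1) for (i in 2:length(s)) {
      if (s[i] <= keep_e) keep_e <- max(keep_e, e[i]) else {
        out_s <- c(out_s, keep_s); out_e <- c(out_e, keep_e)
        keep_s <- s[i]; keep_e <- e[i]
      }
    }
    .(start_h = c(out_s, keep_s), end_h = c(out_e, keep_e))
  }, by = .(admission_id, therapy, drug, rate)]
  list(clean = merged, errors = errors)
}

#' Assign observations and therapy intervals to 24-hour ICU days
#'
#' Windows are half-open intervals `[24(k-1), 24k)` hours since ICU
#' admission: an event at exactly 24.0 h belongs to day 2. A therapy
#' interval contributes a support flag to every day it overlaps.
#' Records with negative times are rejected into a validation log;
#' overlapping duplicate therapy intervals are merged, not double counted.
#'
#' @param observations Data frame with columns `admission_id`, `variable`,
#'   `time_h`, `value` and optionally `unit`.
#' @param therapies Data frame with columns `admission_id`, `therapy`,
#'   optional `drug` and `rate`, `start_h`, `end_h`.
#' @param n_days Maximum day index to retain (default `Inf`, the whole stay).
#' @param table A `sofa_table` (for unit conversion); defaults to the shipped
#'   SOFA-1 table.
#' @return A list with `events` (observations plus a `day` column),
#'   `therapy_days` (one row per therapy x overlapped day), and
#'   `validation_errors`.
#' @export
assign_windows <- function(observations, therapies, n_days = Inf,
                           table = read_score_table("sofa1")) {
  vo <- .validate_observations(observations, table)
  vt <- .validate_therapies(therapies)
  ev <- vo$clean
  ev[, day := floor(time_h / 24) + 1L]
  ev <- ev[day <= n_days]
  th <- vt$clean
  if (nrow(th)) {
    th[, first_day := floor(start_h / 24) + 1L]
    # [start, end) overlaps day k iff start < 24k and end > 24(k-1)
    th[, last_day := ifelse(end_h %% 24 == 0, end_h / 24,
                            floor(end_h / 24) + 1)]
    th[, last_day := pmin(as.integer(last_day), if (is.finite(n_days))
      as.integer(n_days) else as.integer(last_day))]
    th <- th[first_day <= last_day]
    therapy_days <- th[, .(day = seq.int(first_day, last_day)),
                       by = .(admission_id, therapy, drug, rate, start_h, end_h)]
  } else {
    therapy_days <- data.table(admission_id = character(0),
                               therapy = character(0), drug = character(0),
                               rate = numeric(0), start_h = numeric(0),
                               end_h = numeric(0), day = integer(0))
  }
  list(events = ev[], therapy_days = therapy_days[],
       validation_errors = rbind(vo$errors, vt$errors))
}

# Pair each PaO2 (and SpO2) with the most recent FiO2 at or before it
# (falling back to the earliest later FiO2, then to room air 0.21) and
# return per-(admission, day) worst-value aggregates of all variables.
.aggregate_grid <- function(events, therapy_days, table) {
  ev <- events
  agg_one <- function(var, fun) {
    # suppressWarnings: data.table probes j on an empty prototype when the
    # subset has zero rows, which makes min/max warn about empty input
    d <- suppressWarnings(
      ev[variable == var, .(val = fun(value)), by = .(admission_id, day)])
    setnames(d, "val", var)
    d
  }
  parts <- list(
    agg_one("platelets", min), agg_one("bilirubin", max),
    agg_one("creatinine", max), agg_one("map", min)
  )
  uo <- ev[variable == "urine_output", .(urine_output = sum(value)),
           by = .(admission_id, day)]
  parts <- c(parts, list(uo))

  # GCS: an explicit total overrides component sums within the same window
  gt <- suppressWarnings(ev[variable == "gcs_total", .(gcs_t = min(value)),
                            by = .(admission_id, day)])
  gc <- suppressWarnings(
    ev[variable %in% c("gcs_eye", "gcs_verbal", "gcs_motor"),
       .(val = min(value)), by = .(admission_id, day, variable)])
  gc <- dcast(gc, admission_id + day ~ variable, value.var = "val")
  for (cc in c("gcs_eye", "gcs_verbal", "gcs_motor"))
    if (!cc %in% names(gc)) gc[, (cc) := NA_real_]
  gc[, gcs_c := gcs_eye + gcs_verbal + gcs_motor]
  g <- merge(gt, gc[, .(admission_id, day, gcs_c)],
             by = c("admission_id", "day"), all = TRUE)
  g[, gcs := ifelse(is.na(gcs_t), gcs_c, gcs_t)]
  parts <- c(parts, list(g[!is.na(gcs), .(admission_id, day, gcs)]))

  # oxygenation ratios on temporally paired measurements
  fi <- ev[variable == "fio2", .(admission_id, ftime = time_h, fio2 = value)]
  setorder(fi, admission_id, ftime)
  pair_ratio <- function(numvar, out) {
    nu <- ev[variable == numvar,
             .(admission_id, day, time_h, num = value)]
    if (!nrow(nu)) return(NULL)
    if (nrow(fi)) {
      setkey(fi, admission_id, ftime)
      m <- fi[nu[, .(admission_id, ftime = time_h, day, num)],
              on = c("admission_id", "ftime"), roll = TRUE]
      fwd <- fi[nu[, .(admission_id, ftime = time_h)],
                on = c("admission_id", "ftime"), roll = -Inf]
      m[is.na(fio2), fio2 := fwd$fio2[is.na(m$fio2)]]
    } else {
      m <- nu[, .(admission_id, day, num, fio2 = NA_real_)]
    }
    m[is.na(fio2), fio2 := 0.21]
    if (any(m$fio2 <= 0)) stop("FiO2 of 0 encountered when forming ", out)
    r <- m[, .(val = min(num / fio2)), by = .(admission_id, day)]
    setnames(r, "val", out)
    r
  }
  pf <- pair_ratio("pao2", "pf_ratio")
  sf <- pair_ratio("spo2", "sf_ratio")
  if (!is.null(pf)) parts <- c(parts, list(pf))
  if (!is.null(sf)) parts <- c(parts, list(sf))

  # base keys: every admission-day touched by an event or a therapy
  keys <- unique(rbind(ev[, .(admission_id, day)],
                       therapy_days[, .(admission_id, day)]))
  grid <- Reduce(function(a, b) merge(a, b, by = c("admission_id", "day"),
                                      all = TRUE), parts, accumulate = FALSE)
  if (is.null(grid)) grid <- keys[0]
  grid <- merge(keys, grid, by = c("admission_id", "day"), all.x = TRUE)
  for (v in setdiff(.sofa_vars, "nee")) {
    if (!v %in% names(grid)) grid[, (v) := NA_real_]
    if (!is.numeric(grid[[v]])) set(grid, j = v, value = as.numeric(grid[[v]]))
  }

  # therapy support flags and worst-case daily noradrenaline equivalents
  td <- therapy_days
  flag_of <- function(name) {
    f <- unique(td[therapy == name, .(admission_id, day)])
    f[, (name) := TRUE]
    f
  }
  for (f in c("mechanical_ventilation", "rrt", "ecmo", "delirium_medication")) {
    grid <- merge(grid, flag_of(f), by = c("admission_id", "day"), all.x = TRUE)
  }
  factors <- unlist(table$nee_factors)
  vp <- td[therapy == "vasopressor"]
  if (nrow(vp)) {
    unknown <- setdiff(unique(vp$drug), names(factors))
    if (length(unknown))
      stop("no noradrenaline-equivalence factor for drug(s): ",
           paste(unknown, collapse = ", "))
    vp[, fac := factors[drug]]
    # worst case: per-drug maximum rate in the window, summed across drugs
    nee_d <- vp[fac > 0, .(mx = max(rate * fac)),
                by = .(admission_id, day, drug)][
      , .(nee = sum(mx)), by = .(admission_id, day)]
    vaso <- unique(vp[fac > 0 & rate > 0, .(admission_id, day)])
    vaso[, vasopressor := TRUE]
    ino <- unique(vp[fac == 0 & rate > 0, .(admission_id, day)])
    ino[, inotrope := TRUE]
    grid <- merge(grid, nee_d, by = c("admission_id", "day"), all.x = TRUE)
    grid <- merge(grid, vaso, by = c("admission_id", "day"), all.x = TRUE)
    grid <- merge(grid, ino, by = c("admission_id", "day"), all.x = TRUE)
    grid[is.na(nee), nee := 0]
  } else {
    grid[, nee := 0]
    grid[, vasopressor := FALSE]
    grid[, inotrope := FALSE]
  }
  for (f in c("mechanical_ventilation", "rrt", "ecmo", "delirium_medication",
              "vasopressor", "inotrope"))
    set(grid, which(is.na(grid[[f]])), f, FALSE)
  grid[, resp_support := mechanical_ventilation | ecmo]
  grid[]
}

#' Worst-value aggregation of one admission-day window
#'
#' Convenience wrapper exposing the within-window aggregation convention on a
#' single admission: minimum for platelets, P/F, S/F, MAP and GCS; maximum
#' for bilirubin, creatinine and noradrenaline equivalents; daily sum for
#' urine output. The P/F ratio is the lowest ratio among temporally paired
#' PaO2/FiO2 measurements (each PaO2 paired with the most recent preceding
#' FiO2).
#'
#' @inheritParams assign_windows
#' @return Data frame with one row per (admission, day) and one column per
#'   aggregate variable and support flag.
#' @export
aggregate_windows <- function(observations, therapies = NULL, n_days = Inf,
                              table = read_score_table("sofa1")) {
  if (is.null(therapies))
    therapies <- data.frame(admission_id = character(0), therapy = character(0),
                            drug = character(0), rate = numeric(0),
                            start_h = numeric(0), end_h = numeric(0))
  w <- assign_windows(observations, therapies, n_days, table)
  out <- .aggregate_grid(w$events, w$therapy_days, table)
  as.data.frame(out)
}

#' Score one organ domain from aggregates and support flags
#'
#' Applies a threshold table to a single domain: rules are evaluated
#' highest-points-first and the first match wins; no match scores 0.
#'
#' @param domain One of `"respiration"`, `"coagulation"`, `"liver"`,
#'   `"cardiovascular"`, `"brain"`, `"renal"`.
#' @param aggregate_value Numeric; either unnamed (interpreted as the
#'   domain's primary variable: P/F, platelets, bilirubin, MAP, GCS,
#'   creatinine) or a named vector of aggregate variables
#'   (e.g. `c(creatinine = 550, urine_output = 100)`). `NA` or an empty
#'   vector means the value is absent (the caller must have made an
#'   imputation decision upstream).
#' @param support_flags Character vector of active therapy flags (subset of
#'   `mechanical_ventilation`, `resp_support`, `rrt`, `ecmo`,
#'   `delirium_medication`, `vasopressor`, `inotrope`).
#' @param nee Noradrenaline-equivalent dose in µg/kg/min.
#' @param table A `sofa_table`.
#' @return Integer subscore 0--4.
#' @examples
#' tab <- read_score_table("sofa1")
#' score_domain("coagulation", 45, table = tab)   # platelets < 50 -> 3
#' score_domain("brain", 6, table = tab)          # GCS 6-9 band  -> 3
#' @export
score_domain <- function(domain, aggregate_value = NA_real_,
                         support_flags = character(0), nee = 0,
                         table = read_score_table("sofa1")) {
  stopifnot(domain %in% .sofa_domains)
  bad <- setdiff(support_flags, .sofa_flags)
  if (length(bad)) stop("unknown support flag(s): ", paste(bad, collapse = ", "))
  grid <- as.data.frame(setNames(as.list(rep(NA_real_, length(.sofa_vars))),
                                 .sofa_vars))
  if (length(aggregate_value)) {
    if (is.null(names(aggregate_value))) {
      grid[[.domain_vars[[domain]][1]]] <- unname(aggregate_value[1])
    } else {
      for (nm in names(aggregate_value)) {
        if (!nm %in% .sofa_vars) stop("unknown aggregate variable: ", nm)
        grid[[nm]] <- unname(aggregate_value[[nm]])
      }
    }
  }
  grid$nee <- nee
  for (f in .sofa_flags) grid[[f]] <- f %in% support_flags
  if ("mechanical_ventilation" %in% support_flags || "ecmo" %in% support_flags)
    grid$resp_support <- TRUE
  .score_domain_grid(domain, grid, table)[1]
}

# vectorised scoring of one domain over a grid; first (highest-points) match
.score_domain_grid <- function(domain, grid, table) {
  pts <- rep(0L, nrow(grid))
  assigned <- rep(FALSE, nrow(grid))
  for (r in table$domains[[domain]]$rules) {
    hit <- !assigned & .eval_predicate(r$when, grid)
    pts[hit] <- as.integer(r$points)
    assigned <- assigned | hit
  }
  pts
}

#' Daily SOFA scores for a cohort
#'
#' The full daily-scoring pass: validates and windows the raw records,
#' aggregates worst values per 24-h window, applies the missing-data policy,
#' and scores all six domains per admission-day under one threshold system.
#'
#' Under the default `"normal_locf"` policy, a domain with no measurement on
#' day 1 is scored from the table's configured normal values
#' (provenance `normal_imputed`); on later days the most recent aggregate
#' raw values of the domain are carried forward and re-scored
#' (provenance `locf`). Under `"complete_case"` (and `"mice_ready"`, which
#' additionally keeps the raw aggregate grid for downstream multiple
#' imputation) missing domains yield `NA` subscores and the day is flagged
#' incomplete.
#'
#' @inheritParams assign_windows
#' @param stays Optional data frame `admission_id`, `los_h` (ICU length of
#'   stay in hours). Days are emitted from 1 up to `ceiling(los_h / 24)` —
#'   never after ICU discharge. When absent, the last day with any recorded
#'   event or therapy is used.
#' @param table A `sofa_table` (see [read_score_table()]).
#' @param policy `"normal_locf"`, `"complete_case"` or `"mice_ready"`.
#' @param max_days Cap on the number of days scored (default all).
#' @return A data frame of class `sofa_daily`: one row per admission-day with
#'   the six subscores, `total`, a `complete` flag and per-domain provenance
#'   columns (`prov_*` in `measured` / `normal_imputed` / `locf` /
#'   `missing`). Attributes: `domain_records` (the aggregate grid),
#'   `validation_errors`, `system`.
#' @export
compute_daily_scores <- function(observations, therapies = NULL, stays = NULL,
                                 table = read_score_table("sofa1"),
                                 policy = c("normal_locf", "complete_case",
                                            "mice_ready"),
                                 max_days = Inf) {
  policy <- match.arg(policy)
  if (is.null(therapies))
    therapies <- data.frame(admission_id = character(0), therapy = character(0),
                            drug = character(0), rate = numeric(0),
                            start_h = numeric(0), end_h = numeric(0))
  w <- assign_windows(observations, therapies, n_days = max_days, table = table)
  ev <- w$events; td <- w$therapy_days

  # days per admission: partial days count; nothing after discharge
  if (!is.null(stays)) {
    st <- as.data.table(stays)[, .(admission_id, los_h)]
    st[, n_days := pmax(1L, as.integer(ceiling(los_h / 24)))]
    ev <- ev[st, on = "admission_id", nomatch = 0L][time_h < los_h]
    ev[, c("los_h", "n_days") := NULL]
    td <- td[st[, .(admission_id, n_days)], on = "admission_id",
             nomatch = 0L][day <= n_days]
    td[, n_days := NULL]
  } else {
    lastd <- rbind(ev[, .(d = day), by = admission_id][, .(d = max(d)), by = admission_id],
                   td[, .(d = max(day)), by = admission_id])
    st <- lastd[, .(n_days = max(d)), by = admission_id]
  }
  if (!is.null(stays)) st <- st[, .(admission_id, n_days)]
  st[, n_days := pmin(n_days, if (is.finite(max_days)) as.integer(max_days)
                      else n_days)]
  if (!nrow(st)) {
    out <- .empty_daily(table$system)
    attr(out, "validation_errors") <- w$validation_errors
    return(out)
  }

  grid0 <- .aggregate_grid(ev, td, table)
  full <- st[, .(day = seq_len(n_days)), by = admission_id]
  grid <- merge(full, grid0, by = c("admission_id", "day"), all.x = TRUE)
  for (f in c("mechanical_ventilation", "rrt", "ecmo", "delirium_medication",
              "vasopressor", "inotrope", "resp_support"))
    set(grid, which(is.na(grid[[f]])), f, FALSE)
  grid[is.na(nee), nee := 0]

  measured <- data.table(admission_id = grid$admission_id, day = grid$day)
  measured[, respiration := !is.na(grid$pf_ratio) | !is.na(grid$sf_ratio)]
  measured[, coagulation := !is.na(grid$platelets)]
  measured[, liver := !is.na(grid$bilirubin)]
  measured[, cardiovascular := !is.na(grid$map) | grid$vasopressor | grid$inotrope]
  measured[, brain := !is.na(grid$gcs)]
  measured[, renal := !is.na(grid$creatinine) | !is.na(grid$urine_output)]

  prov <- copy(measured)
  for (d in .sofa_domains) prov[[d]] <- ifelse(measured[[d]], "measured", "missing")

  if (policy == "normal_locf") {
    nv <- table$normal_values
    setorder(grid, admission_id, day)
    setorder(measured, admission_id, day)
    setorder(prov, admission_id, day)
    val_cols <- setdiff(.sofa_vars, "nee")
    for (d in .sofa_domains) {
      cols <- setdiff(.domain_vars[[d]], "nee")
      d1 <- which(grid$day == 1L & !measured[[d]])
      if (length(d1)) {
        for (cc in cols) set(grid, d1, cc, as.numeric(nv[[cc]]))
        prov[[d]][d1] <- "normal_imputed"
      }
    }
    maxd <- max(grid$day)
    if (maxd > 1) for (dd in 2:maxd) {
      cur <- which(grid$day == dd)
      if (!length(cur)) next
      prv <- cur - 1L  # rows are ordered by admission, day and days are consecutive
      for (d in .sofa_domains) {
        fill <- cur[!measured[[d]][cur]]
        if (!length(fill)) next
        for (cc in setdiff(.domain_vars[[d]], "nee"))
          set(grid, fill, cc, grid[[cc]][fill - 1L])
        prov[[d]][fill] <- "locf"
      }
    }
  }

  sub <- data.table(admission_id = grid$admission_id, day = grid$day)
  for (d in .sofa_domains) {
    s <- .score_domain_grid(d, grid, table)
    if (policy != "normal_locf") s[prov[[d]] == "missing"] <- NA_integer_
    sub[[d]] <- s
  }
  tot <- rowSums(as.matrix(as.data.frame(sub)[.sofa_domains]))
  complete <- !is.na(tot)
  out <- data.frame(sub)
  out$total <- as.integer(tot)
  out$complete <- complete
  for (d in .sofa_domains) out[[paste0("prov_", d)]] <- prov[[d]]
  out$system <- table$system
  out <- out[order(out$admission_id, out$day), ]
  rownames(out) <- NULL
  class(out) <- c("sofa_daily", "data.frame")
  attr(out, "domain_records") <- as.data.frame(grid)
  attr(out, "validation_errors") <- w$validation_errors
  attr(out, "system") <- table$system
  out
}

.empty_daily <- function(system) {
  out <- data.frame(admission_id = character(0), day = integer(0))
  for (d in .sofa_domains) out[[d]] <- integer(0)
  out$total <- integer(0)
  out$complete <- logical(0)
  for (d in .sofa_domains) out[[paste0("prov_", d)]] <- character(0)
  out$system <- character(0)
  class(out) <- c("sofa_daily", "data.frame")
  out
}

#' @export
print.sofa_daily <- function(x, ...) {
  cat("<sofa_daily> ", attr(x, "system") %||% "", ": ",
      length(unique(x$admission_id)), " admissions, ", nrow(x),
      " admission-days\n", sep = "")
  ve <- attr(x, "validation_errors")
  if (!is.null(ve) && nrow(ve)) cat("  ", nrow(ve), "records rejected at validation\n")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Day-over-day change in total score
#'
#' Signed change of the daily total relative to day 1
#' (`delta_vs_day1`, identically 0 on day 1) and relative to the preceding
#' day (`delta_vs_previous`, undefined on day 1). Set `unsigned = TRUE` for
#' absolute magnitudes.
#'
#' @param totals Numeric vector of daily totals, day 1 first.
#' @param unsigned Report `|change|` instead of the signed change.
#' @return List with `delta_vs_day1` and `delta_vs_previous`.
#' @examples
#' delta_scores(c(5, 7, 6))
#' @export
delta_scores <- function(totals, unsigned = FALSE) {
  stopifnot(length(totals) >= 1)
  d1 <- totals - totals[1]
  dp <- c(NA, diff(totals))
  if (unsigned) { d1 <- abs(d1); dp <- abs(dp) }
  list(delta_vs_day1 = d1, delta_vs_previous = dp)
}

#' Stay-level summary of daily totals
#'
#' Mean of the daily totals across all ICU days and the highest recorded
#' total during the stay.
#'
#' @param totals Numeric vector of daily totals (all ICU days, not only
#'   days 1--7).
#' @return List with `mean_score` and `max_score`.
#' @export
summarize_stay <- function(totals) {
  stopifnot(length(totals) >= 1)
  list(mean_score = mean(totals), max_score = max(totals))
}

#' Per-admission stay summaries for a daily-score table
#'
#' @param daily A `sofa_daily` table (or data frame with `admission_id`,
#'   `day`, `total`).
#' @return Data frame `admission_id`, `system`, `mean_score`, `max_score`.
#' @export
stay_summary <- function(daily) {
  dt <- as.data.table(as.data.frame(daily))
  out <- dt[!is.na(total), .(system = system[1], mean_score = mean(total),
                             max_score = max(total)), by = admission_id]
  as.data.frame(out)
}

#' Add delta columns to a daily-score table
#'
#' @inheritParams stay_summary
#' @param unsigned Use absolute changes.
#' @return The input with `delta_vs_day1` and `delta_vs_previous` columns.
#' @export
add_deltas <- function(daily, unsigned = FALSE) {
  dt <- as.data.table(as.data.frame(daily))
  setorder(dt, admission_id, day)
  dt[, `:=`(delta_vs_day1 = total - total[1],
            delta_vs_previous = total - shift(total)), by = admission_id]
  if (unsigned)
    dt[, `:=`(delta_vs_day1 = abs(delta_vs_day1),
              delta_vs_previous = abs(delta_vs_previous))]
  out <- as.data.frame(dt)
  for (a in c("domain_records", "validation_errors", "system"))
    attr(out, a) <- attr(daily, a)
  class(out) <- class(daily)
  out
}

#' Agreement on the organ-failure indicator between two systems
#'
#' For each domain, the fraction of admission-days on which the two scoring
#' systems agree about organ failure (subscore >= 2).
#'
#' @param daily_a,daily_b Daily-score tables for the same admissions/days.
#' @param day Optional day filter (e.g. `1` for day-1 agreement).
#' @return Named numeric vector of per-domain agreement proportions.
#' @export
organ_failure_agreement <- function(daily_a, daily_b, day = NULL) {
  a <- as.data.frame(daily_a); b <- as.data.frame(daily_b)
  if (!is.null(day)) { a <- a[a$day %in% day, ]; b <- b[b$day %in% day, ] }
  ka <- paste(a$admission_id, a$day); kb <- paste(b$admission_id, b$day)
  if (!setequal(ka, kb)) {
    d <- c(setdiff(ka, kb), setdiff(kb, ka))
    stop("admission-day sets differ between systems: ",
         paste(utils::head(d, 5), collapse = "; "),
         if (length(d) > 5) " ..." else "")
  }
  b <- b[match(ka, kb), ]
  vapply(.sofa_domains, function(d) {
    fa <- a[[d]] >= 2; fb <- b[[d]] >= 2
    mean(fa == fb, na.rm = TRUE)
  }, numeric(1))
}
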