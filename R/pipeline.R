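# End-to-end orchestration: score -> cohort -> reclassification -> validity,
# from a single config, with one root seed and deterministic report files.

#' Write / read a cohort input bundle as CSV files
#'
#' The on-disk interchange format: `observations.csv`, `therapies.csv`,
#' `admissions.csv`, `icd10.csv`, `antibiotics.csv`, `cultures.csv`,
#' `deaths.csv` (plus `ground_truth.csv` when present).
#'
#' @param bundle Named list of data frames (as from [simulate_cohort()]).
#' @param dir Directory.
#' @return `dir`, invisibly.
#' @export
write_input_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("observations", "therapies", "admissions", "icd10",
               "antibiotics", "cultures", "deaths", "ground_truth")) {
    if (!is.null(bundle[[nm]]))
      utils::write.csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  if (!is.null(bundle$params))
    jsonlite::write_json(bundle$params[setdiff(names(bundle$params), "")],
                         file.path(dir, "params.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  invisible(dir)
}

#' @rdname write_input_bundle
#' @export
read_input_bundle <- function(dir) {
  rd <- function(nm, required = TRUE) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) {
      if (required) stop("missing input file: ", f)
      return(NULL)
    }
    utils::read.csv(f, stringsAsFactors = FALSE)
  }
  b <- list(observations = rd("observations"), therapies = rd("therapies"),
            admissions = rd("admissions"), icd10 = rd("icd10", FALSE),
            antibiotics = rd("antibiotics", FALSE),
            cultures = rd("cultures", FALSE), deaths = rd("deaths"),
            ground_truth = rd("ground_truth", FALSE))
  if (!is.null(b$admissions$admission_time))
    b$admissions$admission_time <- as.POSIXct(b$admissions$admission_time,
                                              tz = "UTC")
  if (!is.null(b$admissions$icu_discharge_time))
    b$admissions$icu_discharge_time <-
      as.POSIXct(b$admissions$icu_discharge_time, tz = "UTC")
  if (!is.null(b$deaths$death_date))
    b$deaths$death_date <- as.Date(b$deaths$death_date)
  b
}

#' Run configuration for the end-to-end pipeline
#'
#' @param bundle In-memory input bundle, or `NULL` to read from
#'   `input_dir`.
#' @param input_dir Directory holding the CSV bundle.
#' @param tables Character vector (length >= 2) of threshold tables: shipped
#'   names (`"sofa1"`, `"sofa2"`) or YAML paths. The first is treated as the
#'   reference system in comparisons.
#' @param outcome `"death_30d"` or `"icu_death"`.
#' @param days Analysis days, a subset of 1--7.
#' @param policy Missing-data policy for scoring.
#' @param subgroup `NULL`, `"sepsis"`, `"trauma"`, or
#'   `list(admission_sofa_min = <threshold>)` for the severe-admission
#'   subgroup (threshold applied to the reference system's day-1 total).
#' @param bootstrap_B Bootstrap resamples for optimism correction (0 skips).
#' @param glmm Fit the random-intercept AIC comparison.
#' @param mice_m Number of chained-equation imputations for the sensitivity
#'   analysis (0 skips).
#' @param seed Root seed; all stage seeds derive from it.
#' @param outdir Output directory for report files.
#' @return A `run_config` list.
#' @export
run_config <- function(bundle = NULL, input_dir = NULL,
                       tables = c("sofa1", "sofa2"),
                       outcome = c("death_30d", "icu_death"), days = 1:7,
                       policy = "normal_locf", subgroup = NULL,
                       bootstrap_B = 0, glmm = FALSE, mice_m = 0,
                       seed = 1, outdir = tempfile("sofaval_run")) {
  outcome <- match.arg(outcome)
  stopifnot(all(days %in% 1:7), length(tables) >= 2)
  if (is.null(bundle) && is.null(input_dir))
    stop("either bundle or input_dir is required")
  structure(list(bundle = bundle, input_dir = input_dir, tables = tables,
                 outcome = outcome, days = days, policy = policy,
                 subgroup = subgroup, bootstrap_B = bootstrap_B,
                 glmm = glmm, mice_m = mice_m, seed = seed, outdir = outdir),
            class = "run_config")
}

#' Cohort flow table from exclusion tallies
#'
#' @param exclusions Output of [apply_exclusions()].
#' @return Data frame `step`, `n` starting at the raw input count and ending
#'   at the retained cohort (counts conserve the input total).
#' @export
flow_report <- function(exclusions) {
  t <- exclusions$tally
  out <- data.frame(step = c("raw_admissions",
                             paste0("excluded_", t$step), "retained"),
                    n = c(exclusions$n_input, t$excluded,
                          t$remaining[nrow(t)]))
  stopifnot(out$n[1] == sum(t$excluded) + out$n[nrow(out)])
  out
}

# One day x system block of the validity battery. Scores enter a univariate
# logistic model; calibration/Brier use its in-sample probabilities.
.validity_one <- function(score, labels, conf_z = stats::qnorm(0.975)) {
  fit <- stats::glm(labels ~ score, family = stats::binomial(),
                    control = list(epsilon = 1e-10, maxit = 100))
  p <- stats::fitted(fit)
  dl <- delong_inference(score, labels)
  cal <- calibration(p, labels)
  list(auroc = dl$estimate, auroc_lo = dl$ci_low, auroc_hi = dl$ci_high,
       brier = brier(p, labels)$estimate,
       slope = cal$slope, intercept = cal$intercept, prob = p, fit = fit)
}

#' Day-by-day predictive-validity battery for two scoring systems
#'
#' For each analysis day the risk set is the admissions still in the ICU on
#' that day (those with a day-`d` score); the outcome stays fixed (e.g.
#' 30-day mortality from admission). Reports per system AUROC with DeLong
#' CI, Brier score, calibration slope/intercept; the paired DeLong
#' comparison per day with Bonferroni-adjusted p-values over the reported
#' days; and per-day continuous NRI and IDI components between the two
#' systems' univariate model probabilities.
#'
#' @param daily_list Named list of two `sofa_daily` tables (reference
#'   first).
#' @param outcomes Data frame `admission_id` + outcome column.
#' @param outcome Outcome column name.
#' @param days Days to analyse.
#' @return List of data frames `daily`, `comparisons`, `nri_idi`.
#' @export
daily_validity <- function(daily_list, outcomes, outcome = "death_30d",
                           days = 1:7) {
  stopifnot(length(daily_list) == 2, !is.null(names(daily_list)))
  o <- as.data.frame(outcomes)[c("admission_id", outcome)]
  names(o)[2] <- "y"
  sysnames <- names(daily_list)
  rows <- list(); comps <- list(); nri <- list()
  m_adj <- length(days)
  for (d in days) {
    sc <- lapply(daily_list, function(x) {
      x <- as.data.frame(x)
      x <- x[x$day == d & !is.na(x$total), c("admission_id", "total")]
      merge(x, o, by = "admission_id")
    })
    both <- intersect(sc[[1]]$admission_id, sc[[2]]$admission_id)
    sc <- lapply(sc, function(x) x[match(both, x$admission_id), ])
    if (length(both) < 10 || length(unique(sc[[1]]$y)) < 2) next
    v <- lapply(sc, function(x) .validity_one(x$total, x$y))
    for (s in sysnames) {
      rows[[length(rows) + 1L]] <- data.frame(
        day = d, system = s, n = length(both), auroc = v[[s]]$auroc,
        auroc_lo = v[[s]]$auroc_lo, auroc_hi = v[[s]]$auroc_hi,
        brier = v[[s]]$brier, slope = v[[s]]$slope,
        intercept = v[[s]]$intercept)
    }
    cmp <- delong_inference(sc[[2]]$total, sc[[1]]$y,
                            scores_b = sc[[1]]$total)
    comps[[length(comps) + 1L]] <- data.frame(
      day = d, system_a = sysnames[2], system_b = sysnames[1],
      auroc_a = cmp$auroc_a, auroc_b = cmp$auroc_b, delta = cmp$delta,
      p = cmp$p, p_adj = min(1, m_adj * cmp$p), n = length(both))
    nr <- continuous_nri(v[[2]]$prob, v[[1]]$prob, sc[[1]]$y)
    id <- idi_components(v[[2]]$prob, v[[1]]$prob, sc[[1]]$y)
    nri[[length(nri) + 1L]] <- data.frame(
      day = d, nri = nr$estimate, nri_lo = nr$ci_low, nri_hi = nr$ci_high,
      nri_event = nr$event_component, nri_nonevent = nr$nonevent_component,
      idi_pos = id$idi_pos$estimate, idi_pos_lo = id$idi_pos$ci_low,
      idi_pos_hi = id$idi_pos$ci_high, idi_neg = id$idi_neg$estimate,
      idi_neg_lo = id$idi_neg$ci_low, idi_neg_hi = id$idi_neg$ci_high,
      n = length(both))
  }
  list(daily = do.call(rbind, rows), comparisons = do.call(rbind, comps),
       nri_idi = do.call(rbind, nri))
}

#' Per-domain subscore validity on a given day
#'
#' AUROC and per-point OR of each domain subscore for the outcome.
#'
#' @param daily A `sofa_daily` table.
#' @param outcomes Data frame `admission_id` + outcome column.
#' @param outcome Outcome column name.
#' @param day Analysis day.
#' @return Data frame `domain`, `auroc`, `auroc_lo`, `auroc_hi`, `or`,
#'   `or_lo`, `or_hi`, `n`.
#' @export
subscore_validity <- function(daily, outcomes, outcome = "death_30d",
                              day = 1) {
  x <- as.data.frame(daily)
  x <- x[x$day == day, ]
  o <- as.data.frame(outcomes)[c("admission_id", outcome)]
  names(o)[2] <- "y"
  x <- merge(x, o, by = "admission_id")
  out <- lapply(.sofa_domains, function(dm) {
    s <- x[[dm]]; keep <- !is.na(s)
    if (length(unique(x$y[keep])) < 2) return(NULL)
    dl <- delong_inference(s[keep], x$y[keep])
    orr <- per_point_or(s[keep], x$y[keep])
    data.frame(domain = dm, auroc = dl$estimate, auroc_lo = dl$ci_low,
               auroc_hi = dl$ci_high, or = orr$estimate,
               or_lo = orr$ci_low, or_hi = orr$ci_high, n = sum(keep))
  })
  do.call(rbind, out)
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes scoring (per threshold system), cohort construction,
#' reclassification, and the validity battery, writing all report tables to
#' `config$outdir`: `daily_scores.csv`, `stay_summary.csv`, `flow.csv`,
#' `cohort.csv`, `reclassification.csv`, `daily_or.csv`,
#' `validity_daily.csv`, `comparisons.csv`, `nri_idi.csv`,
#' `subscores.csv`, `agreement.csv`, optionally `glmm_aic.csv`, plus a
#' `manifest.json` recording the seed and configuration. Reruns with an
#' identical configuration and seed produce byte-identical files. Stage
#' failures abort with a stage-labelled error; tables already written are
#' retained.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all report tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(df, name) {
    utils::write.csv(df, file.path(config$outdir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", label, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }

  bundle <- config$bundle
  if (is.null(bundle))
    bundle <- stage("ingest", read_input_bundle(config$input_dir))

  # cohort -----------------------------------------------------------------
  res <- list()
  excl <- stage("cohort", apply_exclusions(bundle$admissions))
  res$flow <- flow_report(excl)
  emit(res$flow, "flow")
  cohort <- excl$cohort
  stays <- data.frame(admission_id = cohort$admission_id,
                      los_h = if ("los_h" %in% names(cohort)) cohort$los_h
                      else as.numeric(difftime(cohort$icu_discharge_time,
                                               cohort$admission_time,
                                               units = "hours")))

  # scoring ----------------------------------------------------------------
  tabs <- lapply(config$tables, read_score_table)
  names(tabs) <- vapply(tabs, `[[`, "", "system")
  daily_list <- stage("score", lapply(tabs, function(tb)
    compute_daily_scores(bundle$observations, bundle$therapies,
                         stays = stays, table = tb, policy = config$policy)))
  res$daily_scores <- do.call(rbind, lapply(daily_list, as.data.frame))
  emit(res$daily_scores, "daily_scores")
  res$stay_summary <- do.call(rbind, lapply(daily_list, stay_summary))
  emit(res$stay_summary, "stay_summary")

  # outcomes, comorbidity, sepsis -------------------------------------------
  out_lab <- stage("outcomes", outcome_labels(cohort, bundle$deaths))
  cci <- if (!is.null(bundle$icd10) && nrow(bundle$icd10))
    stage("comorbidity", charlson_index(bundle$icd10)) else NULL
  ref_day1 <- daily_list[[1]]
  d1tot <- stats::setNames(ref_day1$total[ref_day1$day == 1],
                           ref_day1$admission_id[ref_day1$day == 1])
  sepsis <- if (!is.null(bundle$antibiotics) && !is.null(bundle$cultures)) {
    eps <- suspected_infection(bundle$antibiotics, bundle$cultures,
                               admissions = cohort)
    sepsis_at_admission(eps, cohort$admission_id, day1_total = d1tot,
                        sofa_threshold = NULL)
  } else stats::setNames(rep(NA, nrow(cohort)), cohort$admission_id)
  cohort_tab <- merge(cohort, out_lab, by = "admission_id")
  cohort_tab$sepsis_at_admission <- unname(sepsis[cohort_tab$admission_id])
  if (!is.null(cci)) cohort_tab <- merge(cohort_tab, cci,
                                         by = "admission_id", all.x = TRUE)
  res$cohort <- cohort_tab
  emit(cohort_tab, "cohort")

  # subgroup filter ---------------------------------------------------------
  keep_ids <- cohort_tab$admission_id
  sg <- config$subgroup
  if (!is.null(sg)) {
    if (identical(sg, "sepsis")) {
      keep_ids <- cohort_tab$admission_id[isTRUE_vec(cohort_tab$sepsis_at_admission)]
    } else if (identical(sg, "trauma")) {
      keep_ids <- cohort_tab$admission_id[isTRUE_vec(cohort_tab$trauma)]
    } else if (is.list(sg) && !is.null(sg$admission_sofa_min)) {
      keep_ids <- names(d1tot)[!is.na(d1tot) & d1tot >= sg$admission_sofa_min]
    } else stop("unknown subgroup specification")
  }
  daily_sub <- lapply(daily_list, function(x) {
    y <- as.data.frame(x)[as.data.frame(x)$admission_id %in% keep_ids, ]
    y
  })
  out_sub <- cohort_tab[cohort_tab$admission_id %in% keep_ids, ]

  # reclassification --------------------------------------------------------
  rec <- stage("reclassify", reclass_records(daily_sub[[2]], daily_sub[[1]],
                                             out_sub, config$outcome))
  rec <- rec[rec$day %in% config$days, ]
  res$reclassification <- reclassification_summary(rec, config$days)
  emit(res$reclassification, "reclassification")
  res$daily_or <- as.data.frame(stage("reclassify",
                                      daily_group_or(rec, days = config$days)))
  emit(res$daily_or, "daily_or")

  # validity ----------------------------------------------------------------
  val <- stage("validate", daily_validity(daily_sub, out_sub,
                                          outcome = config$outcome,
                                          days = config$days))
  res$validity_daily <- val$daily
  res$comparisons <- val$comparisons
  res$nri_idi <- val$nri_idi
  emit(val$daily, "validity_daily")
  emit(val$comparisons, "comparisons")
  emit(val$nri_idi, "nri_idi")
  res$subscores <- stage("validate",
                         subscore_validity(daily_sub[[2]], out_sub,
                                           outcome = config$outcome, day = 1))
  emit(res$subscores, "subscores")
  res$agreement <- data.frame(
    domain = .sofa_domains,
    agreement = unname(organ_failure_agreement(
      daily_sub[[1]][daily_sub[[1]]$day == 1, ],
      daily_sub[[2]][daily_sub[[2]]$day == 1, ])))
  emit(res$agreement, "agreement")

  if (config$glmm) {
    long <- merge(as.data.frame(daily_sub[[2]]),
                  stats::setNames(out_sub[c("admission_id", config$outcome)],
                                  c("admission_id", "outcome")),
                  by = "admission_id")
    long <- long[long$day %in% config$days & !is.na(long$total), ]
    res$glmm_aic <- stage("validate", glmm_aic_comparison(long))
    emit(res$glmm_aic, "glmm_aic")
  }

  manifest <- list(seed = config$seed,
                   outcome = config$outcome, days = config$days,
                   policy = config$policy,
                   systems = names(tabs),
                   table_versions = vapply(tabs, `[[`, "", "version"),
                   n_cohort = nrow(cohort_tab),
                   n_analysis = length(keep_ids),
                   package_version = as.character(utils::packageVersion("sofaval")))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
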