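test_that("24-hour windows are half-open and therapy overlap flags all days", {
  obs <- data.frame(admission_id = "a", variable = "platelets",
                    time_h = c(23.99, 24.0, 0), value = c(100, 90, 80),
                    unit = "10^9/L")
  ther <- data.frame(admission_id = "a", therapy = "mechanical_ventilation",
                     drug = NA, rate = NA, start_h = 20, end_h = 30)
  w <- assign_windows(obs, ther)
  expect_equal(w$events$day[w$events$time_h == 23.99], 1L)
  expect_equal(w$events$day[w$events$time_h == 24.0], 2L)
  expect_setequal(w$therapy_days$day, c(1L, 2L))
})

test_that("negative times are rejected into the validation log, not dropped silently", {
  obs <- data.frame(admission_id = "a", variable = "platelets",
                    time_h = c(-1, 2), value = c(100, 90), unit = "10^9/L")
  w <- assign_windows(obs, tiny_therapies()[0, ])
  expect_equal(nrow(w$events), 1L)
  expect_equal(nrow(w$validation_errors), 1L)
  expect_match(w$validation_errors$reason, "negative")
})

test_that("overlapping duplicate therapy intervals are merged, not doubled", {
  ther <- data.frame(admission_id = "a", therapy = "mechanical_ventilation",
                     drug = NA, rate = NA,
                     start_h = c(0, 5), end_h = c(10, 20))
  w <- assign_windows(tiny_observations()[0, ], ther)
  expect_equal(nrow(w$therapy_days[w$therapy_days$day == 1, ]), 1L)
})

test_that("window partition: every event lands in exactly one day", {
  set.seed(42)
  ra <- random_admission_events("a", n_days = 4, n_events = 200)
  w <- assign_windows(ra$observations, ra$therapies)
  expect_equal(nrow(w$events), 200L)
  expect_true(all(w$events$time_h >= 24 * (w$events$day - 1) &
                    w$events$time_h < 24 * w$events$day))
})

test_that("noradrenaline equivalents sum rate x factor and reject unknown drugs", {
  expect_equal(noradrenaline_equivalent(c(noradrenaline = 0.10)), 0.10)
  expect_equal(noradrenaline_equivalent(numeric(0)), 0)
  expect_equal(noradrenaline_equivalent(c(noradrenaline = 0.05,
                                          adrenaline = 0.05)), 0.10)
  expect_error(noradrenaline_equivalent(c(unobtainium = 1)), "unobtainium")
})

test_that("worst-value aggregation follows the per-variable direction", {
  obs <- data.frame(
    admission_id = "a",
    variable = c(rep("platelets", 3), rep("bilirubin", 2),
                 rep("urine_output", 3)),
    time_h = c(1, 2, 3, 4, 5, 6, 7, 8),
    value = c(80, 45, 120, 30, 50, 100, 150, 200),
    unit = c(rep("10^9/L", 3), rep("umol/L", 2), rep("mL", 3)))
  g <- aggregate_windows(obs)
  expect_equal(g$platelets, 45)
  expect_equal(g$bilirubin, 50)
  expect_equal(g$urine_output, 450)
})

test_that("P/F uses the temporally paired measurement with the lowest ratio", {
  obs <- data.frame(
    admission_id = "a",
    variable = c("fio2", "pao2", "fio2", "pao2"),
    time_h = c(1, 2, 5, 6),
    value = c(0.21, 90, 1.0, 90),
    unit = c("fraction", "mmHg", "fraction", "mmHg"))
  g <- aggregate_windows(obs)
  expect_equal(g$pf_ratio, 90)  # 90/1.0 beats 90/0.21
})

test_that("unit conversion normalises mg/dL inputs to micromol/L", {
  obs <- data.frame(admission_id = "a", variable = "bilirubin",
                    time_h = 1, value = 2, unit = "mg/dL")
  g <- aggregate_windows(obs)
  expect_equal(g$bilirubin, 34.2)
})

test_that("domain scoring matches the shipped SOFA-1 reference bands", {
  expect_equal(score_domain("coagulation", 45, table = sofa1_tab), 3L)
  expect_equal(score_domain("brain", 6, table = sofa1_tab), 3L)
  expect_equal(score_domain("cardiovascular", 65, table = sofa1_tab), 1L)
  expect_equal(score_domain("cardiovascular", 80, nee = 0.2,
                            table = sofa1_tab), 4L)
  expect_equal(score_domain("respiration", 150,
                            support_flags = "mechanical_ventilation",
                            table = sofa1_tab), 3L)
  expect_equal(score_domain("respiration", 150, table = sofa1_tab), 2L)
  expect_equal(score_domain("renal", c(creatinine = 80, urine_output = 100),
                            table = sofa1_tab), 4L)
})

test_that("SOFA-2 support-flag rules award points from RRT, ECMO and delirium", {
  expect_equal(score_domain("renal", c(creatinine = 70),
                            support_flags = "rrt", table = sofa2_tab), 4L)
  expect_equal(score_domain("respiration", 400, support_flags = "ecmo",
                            table = sofa2_tab), 4L)
  expect_equal(score_domain("brain", 15, support_flags = "delirium_medication",
                            table = sofa2_tab), 1L)
  expect_equal(score_domain("brain", 15, table = sofa2_tab), 0L)
})

test_that("daily scoring imputes normal on day 1 and carries forward after", {
  obs <- data.frame(admission_id = "a", variable = "platelets", time_h = 2,
                    value = 45, unit = "10^9/L")
  ds <- compute_daily_scores(obs, stays = data.frame(admission_id = "a",
                                                     los_h = 40),
                             table = sofa1_tab)
  d1 <- ds[ds$day == 1, ]; d2 <- ds[ds$day == 2, ]
  expect_equal(d1$coagulation, 3L)
  expect_equal(d1$total, 3L)
  expect_equal(d1$prov_liver, "normal_imputed")
  expect_equal(d2$coagulation, 3L)
  expect_equal(d2$prov_coagulation, "locf")
})

test_that("complete-case policy yields NA subscores and incomplete days", {
  obs <- data.frame(admission_id = "a", variable = "platelets", time_h = 2,
                    value = 45, unit = "10^9/L")
  ds <- compute_daily_scores(obs, stays = data.frame(admission_id = "a",
                                                     los_h = 30),
                             table = sofa1_tab, policy = "complete_case")
  expect_true(is.na(ds$liver[1]))
  expect_true(is.na(ds$total[1]))
  expect_false(ds$complete[1])
  expect_equal(ds$coagulation[1], 3L)
})

test_that("invalid imputation policy and empty stays are handled per contract", {
  obs <- tiny_observations()
  expect_error(compute_daily_scores(obs, policy = "impute_everything"))
  ds <- compute_daily_scores(obs[0, ], stays = data.frame(
    admission_id = character(0), los_h = numeric(0)))
  expect_equal(nrow(ds), 0L)
})

test_that("no scores are emitted after ICU discharge", {
  obs <- data.frame(admission_id = "a", variable = "platelets",
                    time_h = c(2, 30, 60), value = c(45, 50, 60),
                    unit = "10^9/L")
  ds <- compute_daily_scores(obs, stays = data.frame(admission_id = "a",
                                                     los_h = 50),
                             table = sofa1_tab)
  expect_equal(max(ds$day), 3L)  # ceiling(50/24) = 3 (partial day counts)
  expect_equal(nrow(ds), 3L)
})

test_that("engine equals the straight-line oracle on randomized admissions", {
  set.seed(7)
  for (rep in 1:12) {
    n_adm <- sample(1:5, 1)
    obs <- list(); ther <- list()
    for (i in seq_len(n_adm)) {
      ra <- random_admission_events(paste0("a", i), n_days = 3,
                                    n_events = sample(10:40, 1))
      obs[[i]] <- ra$observations; ther[[i]] <- ra$therapies
    }
    obs <- do.call(rbind, obs); ther <- do.call(rbind, ther)
    stays <- data.frame(admission_id = paste0("a", seq_len(n_adm)),
                        los_h = 72)
    ds <- compute_daily_scores(obs, ther, stays = stays, table = sofa1_tab,
                               policy = "complete_case")
    for (i in seq_len(n_adm)) for (d in 1:3) {
      id <- paste0("a", i)
      o <- oracle_sofa1_day(obs, ther, id, d)
      row <- ds[ds$admission_id == id & ds$day == d, ]
      for (dm in names(o)) {
        got <- row[[dm]]
        if (is.na(got)) got <- 0L  # unmeasured domain under complete case
        expect_equal(got, unname(o[dm]), ignore_attr = TRUE,
                     label = sprintf("%s day %s %s (rep %d)", id, d, dm, rep))
      }
    }
  }
})

test_that("totals equal subscore sums and stay within 0-24", {
  sim <- simulate_cohort(sim_params(n_admissions = 150, seed = 3))
  ds <- compute_daily_scores(sim$observations, sim$therapies,
                             stays = sim$admissions[c("admission_id", "los_h")],
                             table = sofa2_tab)
  doms <- c("respiration", "coagulation", "liver", "cardiovascular",
            "brain", "renal")
  expect_true(all(ds$total >= 0 & ds$total <= 24))
  expect_true(all(as.matrix(ds[doms]) >= 0 & as.matrix(ds[doms]) <= 4))
  expect_equal(ds$total, as.integer(rowSums(ds[doms])))
  # provenance invariants
  for (dm in doms) {
    pv <- ds[[paste0("prov_", dm)]]
    expect_true(all(pv[ds$day == 1] %in% c("measured", "normal_imputed")))
    expect_true(all(pv[ds$day > 1] %in% c("measured", "locf")))
  }
})

test_that("imputation pass is idempotent: rescoring scored aggregates changes nothing", {
  sim <- simulate_cohort(sim_params(n_admissions = 80, seed = 5))
  st <- sim$admissions[c("admission_id", "los_h")]
  ds1 <- compute_daily_scores(sim$observations, sim$therapies, stays = st,
                              table = sofa1_tab)
  ds2 <- compute_daily_scores(sim$observations, sim$therapies, stays = st,
                              table = sofa1_tab)
  expect_identical(as.data.frame(ds1), as.data.frame(ds2))
})

test_that("monotonicity: worsening a raw value never lowers the subscore", {
  set.seed(11)
  dirs <- c(platelets = -1, bilirubin = 1, map = -1, gcs = -1,
            creatinine = 1, pf_ratio = -1, urine_output = -1)
  prim <- list(coagulation = "platelets", liver = "bilirubin",
               cardiovascular = "map", brain = "gcs", renal = "creatinine",
               respiration = "pf_ratio")
  for (tab in list(sofa1_tab, sofa2_tab)) {
    for (dm in names(prim)) {
      v <- prim[[dm]]
      vals <- sort(runif(40, 1, 500), decreasing = dirs[v] < 0)
      if (v == "gcs") vals <- sort(sample(3:15, 13), decreasing = TRUE)
      sc <- vapply(vals, function(x)
        score_domain(dm, stats::setNames(x, v), table = tab), integer(1))
      expect_true(all(diff(sc) >= 0),
                  label = paste(tab$system, dm, "monotone"))
    }
  }
})

test_that("delta and stay summaries follow their definitions", {
  d <- delta_scores(c(5, 7, 6))
  expect_equal(d$delta_vs_day1, c(0, 2, 1))
  expect_equal(d$delta_vs_previous, c(NA, 2, -1))
  expect_equal(delta_scores(c(4))$delta_vs_day1, 0)
  du <- delta_scores(c(5, 7, 6), unsigned = TRUE)
  expect_equal(du$delta_vs_previous, c(NA, 2, 1))
  expect_equal(summarize_stay(c(5, 7, 6)), list(mean_score = 6, max_score = 7))
  expect_equal(summarize_stay(c(3)), list(mean_score = 3, max_score = 3))
  expect_equal(summarize_stay(c(0, 0, 0)), list(mean_score = 0, max_score = 0))
})

test_that("stay summaries satisfy mean <= max across a simulated cohort", {
  sim <- simulate_cohort(sim_params(n_admissions = 100, seed = 9))
  ds <- compute_daily_scores(sim$observations, sim$therapies,
                             stays = sim$admissions[c("admission_id", "los_h")],
                             table = sofa1_tab)
  ss <- stay_summary(ds)
  expect_true(all(ss$mean_score <= ss$max_score + 1e-12))
  wd <- add_deltas(ds)
  expect_true(all(wd$delta_vs_day1[wd$day == 1] == 0))
})

test_that("organ-failure agreement compares the subscore >= 2 indicator", {
  base <- data.frame(admission_id = "a", day = 1, respiration = 2,
                     coagulation = 0, liver = 0, cardiovascular = 0,
                     brain = 0, renal = 0)
  other <- base
  expect_equal(unname(organ_failure_agreement(base, base)), rep(1, 6))
  other$respiration <- 1
  expect_equal(unname(organ_failure_agreement(base, other)["respiration"]), 0)
  other$respiration <- 3
  expect_equal(unname(organ_failure_agreement(base, other)["respiration"]), 1)
  other$admission_id <- "b"
  expect_error(organ_failure_agreement(base, other), "differ")
})
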