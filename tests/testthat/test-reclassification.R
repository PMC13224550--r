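test_that("day classification is a sign comparison with equal as reference", {
  g <- classify_day(c(5, 6, 9), c(6, 6, 6))
  expect_equal(as.character(g), c("sofa2_lower", "equal", "sofa2_higher"))
  expect_equal(levels(g)[1], "equal")
})

test_that("per-day proportions sum to one and use Wilson intervals", {
  rec <- data.frame(admission_id = sprintf("a%02d", 1:4), day = 1,
                    group = factor(c("equal", "equal", "equal",
                                     "sofa2_higher"),
                                   levels = c("equal", "sofa2_higher",
                                              "sofa2_lower")),
                    outcome = c(FALSE, TRUE, FALSE, TRUE))
  s <- reclassification_summary(rec, days = 1)
  expect_equal(s$proportion, c(0.75, 0.25, 0))
  expect_equal(sum(s$proportion), 1, tolerance = 1e-12)
  expect_false(any(is.na(s$ci_low) | is.na(s$ci_high)))
  # 50/100 case against the closed-form Wilson interval
  rec2 <- data.frame(admission_id = sprintf("b%03d", 1:100), day = 1,
                     group = factor(rep(c("equal", "sofa2_higher"), 50),
                                    levels = levels(rec$group)),
                     outcome = FALSE)
  s2 <- reclassification_summary(rec2, days = 1)
  expect_equal(round(s2$ci_low[1], 3), 0.404)
  expect_equal(round(s2$ci_high[1], 3), 0.596)
  # missing day warns and is omitted
  expect_warning(reclassification_summary(rec, days = 1:2), "day 2")
  # degenerate single-group day keeps finite CIs
  rec3 <- rec; rec3$group[] <- "equal"
  s3 <- reclassification_summary(rec3, days = 1)
  expect_equal(s3$proportion[1], 1)
  expect_false(any(is.na(s3$ci_low)))
})

make_records <- function(day, n_by_group, deaths_by_group) {
  out <- list()
  for (g in names(n_by_group)) {
    n <- n_by_group[[g]]; dth <- deaths_by_group[[g]]
    out[[g]] <- data.frame(
      admission_id = sprintf("%s_d%d_%04d", g, day, seq_len(n)),
      day = day,
      group = factor(g, levels = c("equal", "sofa2_higher", "sofa2_lower")),
      outcome = rep(c(TRUE, FALSE), c(dth, n - dth)))
  }
  do.call(rbind, out)
}

test_that("saturated interaction model reproduces the 2x2 odds ratio", {
  rec <- make_records(1, list(equal = 1000, sofa2_higher = 200),
                      list(equal = 100, sofa2_higher = 50))
  fit <- daily_group_or(rec, days = 1, m_adjust = 1)
  expect_equal(fit$or[fit$group == "sofa2_higher"], 3.0, tolerance = 1e-6)
  # identical mortality -> OR 1
  rec2 <- make_records(1, list(equal = 200, sofa2_higher = 200),
                       list(equal = 30, sofa2_higher = 30))
  fit2 <- daily_group_or(rec2, days = 1, m_adjust = 1)
  expect_equal(fit2$or[1], 1.0, tolerance = 1e-8)
  # two identical days -> identical per-day ORs
  rec3 <- rbind(make_records(1, list(equal = 300, sofa2_lower = 150),
                             list(equal = 30, sofa2_lower = 10)),
                make_records(2, list(equal = 300, sofa2_lower = 150),
                             list(equal = 30, sofa2_lower = 10)))
  fit3 <- daily_group_or(rec3, days = 1:2, m_adjust = 1)
  ors <- fit3$or[fit3$group == "sofa2_lower"]
  expect_equal(ors[1], ors[2], tolerance = 1e-6)
})

test_that("interaction-model ORs equal closed-form 2x2 ORs on random tables", {
  set.seed(31)
  for (rep in 1:25) {
    days <- 1:sample(2:3, 1)
    recs <- list(); expected <- list()
    for (d in days) {
      ns <- list(equal = sample(50:300, 1),
                 sofa2_higher = sample(50:300, 1),
                 sofa2_lower = sample(50:300, 1))
      dth <- lapply(ns, function(n) sample(seq(5, n - 5), 1))
      recs[[d]] <- make_records(d, ns, dth)
      expected[[d]] <- c(
        sofa2_higher = or_2x2(dth$sofa2_higher, ns$sofa2_higher,
                              dth$equal, ns$equal),
        sofa2_lower = or_2x2(dth$sofa2_lower, ns$sofa2_lower,
                             dth$equal, ns$equal))
    }
    fit <- daily_group_or(do.call(rbind, recs), days = days, m_adjust = 1)
    for (d in days) for (g in c("sofa2_higher", "sofa2_lower")) {
      got <- fit$or[fit$day == d & fit$group == g]
      expect_equal(got, unname(expected[[d]][g]), tolerance = 1e-6)
    }
  }
})

test_that("Bonferroni adjustment widens CIs and caps p at one", {
  rec <- make_records(1, list(equal = 500, sofa2_higher = 300),
                      list(equal = 60, sofa2_higher = 55))
  raw <- daily_group_or(rec, days = 1, m_adjust = 1)
  adj <- daily_group_or(rec, days = 1, m_adjust = 14)
  expect_equal(adj$or, raw$or)
  expect_lt(adj$ci_low, raw$ci_low)
  expect_gt(adj$ci_high, raw$ci_high)
  expect_equal(adj$p_adj, pmin(1, 14 * adj$p))
  expect_equal(bonferroni(0.01, 7), 0.07)
  expect_equal(bonferroni(0.5, 7), 1)
  expect_equal(bonferroni(0.3, 1), 0.3)
  expect_equal(bonferroni_level(0.05, 14), 1 - 0.05 / 14)
})

test_that("a day lacking a group is reported absent, and a missing reference errors", {
  rec <- rbind(make_records(1, list(equal = 100, sofa2_higher = 50),
                            list(equal = 10, sofa2_higher = 8)),
               make_records(2, list(equal = 100), list(equal = 10)))
  fit <- daily_group_or(rec, days = 1:2, m_adjust = 1)
  d2h <- fit[fit$day == 2 & fit$group == "sofa2_higher", ]
  expect_true(is.na(d2h$or))
  expect_equal(d2h$n, 0L)
  bad <- make_records(1, list(sofa2_higher = 50), list(sofa2_higher = 8))
  expect_error(daily_group_or(bad, days = 1), "reference")
})

test_that("margin fixture reproduces the printed day-1 reclassification ORs", {
  fx <- fixture_from_margins(29820, c(0.245, 0.153, 0.602),
                             c(0.143, 0.203, 0.128))
  expect_equal(nrow(fx), 29820L)
  rec <- data.frame(admission_id = fx$admission_id, day = 1,
                    group = fx$group, outcome = fx$died)
  fit <- daily_group_or(rec, days = 1, m_adjust = 1)
  expect_equal(fit$or[fit$group == "sofa2_higher"], 1.52, tolerance = 0.02)
  expect_equal(fit$or[fit$group == "sofa2_lower"], 0.88, tolerance = 0.02)
})
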