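test_that("AUROC matches hand-enumerable cases and the tie convention", {
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_equal(auroc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "event")
})

test_that("AUROC equals the all-pairs concordance oracle on random instances", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(4:200, 1)
    scores <- sample(0:24, n, replace = TRUE)
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), auroc_bruteforce(scores, labels))
  }
})

test_that("DeLong agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  n <- 150
  x <- rnorm(n); y <- rbinom(n, 1, plogis(x)); x2 <- x + rnorm(n)
  d <- delong_inference(x, y)
  pr <- pROC::roc(y, x, quiet = TRUE, direction = "<")
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(d$estimate, as.numeric(pROC::auc(pr)))
  expect_equal(c(d$ci_low, d$ci_high), ci[c(1, 3)], tolerance = 1e-8)
  cmp <- delong_inference(x, y, scores_b = x2)
  pr2 <- pROC::roc(y, x2, quiet = TRUE, direction = "<")
  rt <- pROC::roc.test(pr, pr2, method = "delong", paired = TRUE)
  expect_equal(cmp$p, rt$p.value, tolerance = 1e-8)
})

test_that("paired DeLong: identical classifiers give delta 0 and p 1; variance near bootstrap", {
  set.seed(9)
  x <- rnorm(12); y <- c(0, 1, rbinom(10, 1, 0.5))
  same <- delong_inference(x, y, scores_b = x)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  # single-AUROC variance against a seeded bootstrap on a small instance
  set.seed(77)
  n <- 30
  x <- round(runif(n), 2)
  y <- rbinom(n, 1, plogis(2 * x - 1))
  d <- delong_inference(x, y)
  set.seed(123)
  boots <- replicate(20000, {
    i <- sample(n, n, replace = TRUE)
    if (length(unique(y[i])) < 2) NA else auroc(x[i], y[i])
  })
  bv <- var(boots, na.rm = TRUE)
  expect_lt(abs(d$se^2 - bv) / bv, 0.10)
})

test_that("perfect separation yields a degenerate but finite DeLong interval", {
  d <- delong_inference(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(d$estimate, 1)
  expect_equal(d$se, 0)
  expect_equal(d$ci_high, 1)
})

test_that("Brier score is the mean squared probability error", {
  expect_equal(brier(c(0, 1, 0), c(0, 1, 0))$estimate, 0)
  expect_equal(brier(rep(0.5, 10), rep(c(0, 1), 5))$estimate, 0.25)
  expect_equal(brier(c(0.2, 0.6), c(0, 1))$estimate, 0.10)
})

test_that("in-sample calibration of a univariate logistic fit is (0, 1)", {
  set.seed(17)
  for (i in 1:5) {
    n <- 400
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-1 + 0.8 * x))
    if (length(unique(y)) < 2) next
    p <- fitted(glm(y ~ x, family = binomial()))
    cal <- calibration(p, y)
    expect_lt(abs(cal$intercept), 1e-6)
    expect_lt(abs(cal$slope - 1), 1e-6)
  }
})

test_that("calibration slope recovers 2 when true logits double model logits", {
  set.seed(2024)
  n <- 50000
  lp <- rnorm(n, -1.5, 1)
  y <- rbinom(n, 1, plogis(2 * lp))
  cal <- calibration(plogis(lp), y)
  expect_equal(cal$slope, 2, tolerance = 0.05)
  # independence limit: permuted labels drive the slope to 0
  yp <- sample(y)
  cal0 <- calibration(plogis(lp), yp)
  expect_lt(abs(cal0$slope), 0.05)
  # boundary probabilities are clipped with a warning
  expect_warning(calibration(c(0, 0.5, 1, 0.4), c(0, 1, 1, 0)), "clipped")
})

test_that("optimism correction: constant metric has zero optimism; determinism holds", {
  set.seed(3)
  dat <- data.frame(x = rnorm(60), y = rbinom(60, 1, 0.4))
  const <- optimism_correct(dat, fit_fn = function(d) NULL,
                            metric_fn = function(m, d) 0.42, B = 20,
                            seed = 7, outcome_col = "y")
  expect_equal(const$optimism, 0)
  expect_equal(const$estimate, const$apparent)
  fit_fn <- function(d) glm(y ~ x, family = binomial(), data = d)
  metric_fn <- function(m, d) auroc(predict(m, newdata = d), d$y)
  a <- optimism_correct(dat, fit_fn, metric_fn, B = 30, seed = 11,
                        outcome_col = "y")
  b <- optimism_correct(dat, fit_fn, metric_fn, B = 30, seed = 11,
                        outcome_col = "y")
  expect_identical(a, b)
  expect_true(a$optimism_corrected)
})

test_that("optimism of a strongly-signalled large-sample logistic AUROC is tiny", {
  set.seed(19)
  n <- 10000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 1.5 * x))
  dat <- data.frame(x = x, y = y)
  oc <- optimism_correct(dat,
                         fit_fn = function(d) glm(y ~ x, family = binomial(),
                                                  data = d),
                         metric_fn = function(m, d)
                           auroc(predict(m, newdata = d), d$y),
                         B = 40, seed = 5, outcome_col = "y")
  expect_lt(abs(oc$optimism), 0.005)
})

test_that("continuous NRI enumerates movement directions and is antisymmetric", {
  expect_equal(continuous_nri(c(0.2, 0.8), c(0.3, 0.6), c(0, 1))$estimate, 2)
  expect_equal(continuous_nri(c(0.2, 0.8), c(0.3, 0.6), c(1, 0))$estimate, -2)
  same <- continuous_nri(c(0.3, 0.6), c(0.3, 0.6), c(0, 1))
  expect_equal(same$estimate, 0)
  set.seed(23)
  p1 <- runif(50); p2 <- runif(50); y <- rep(c(0, 1), 25)
  a <- continuous_nri(p1, p2, y)$estimate
  b <- continuous_nri(p2, p1, y)$estimate
  expect_equal(a, -b)
  expect_true(a >= -2 && a <= 2)
})

test_that("IDI components are conditional mean probability changes", {
  r <- idi_components(c(0.2, 0.8), c(0.3, 0.6), c(0, 1))
  expect_equal(r$idi_pos$estimate, 0.2)
  expect_equal(r$idi_neg$estimate, 0.1)
  r0 <- idi_components(c(0.3, 0.6), c(0.3, 0.6), c(0, 1))
  expect_equal(r0$idi_pos$estimate, 0)
  expect_equal(r0$idi_neg$estimate, 0)
})

test_that("per-point OR of a binary score equals the 2x2 contingency OR", {
  set.seed(29)
  score <- rep(c(0, 1), c(300, 200))
  y <- c(rbinom(300, 1, 0.1), rbinom(200, 1, 0.25))
  expected <- or_2x2(sum(y[score == 1]), 200, sum(y[score == 0]), 300)
  got <- per_point_or(score, y)
  expect_equal(got$estimate, expected, tolerance = 1e-6)
  # null limit
  y2 <- rbinom(5000, 1, 0.2)
  s2 <- sample(0:10, 5000, replace = TRUE)
  or0 <- per_point_or(s2, y2)
  expect_gt(or0$ci_high, 1); expect_lt(or0$ci_low, 1)
  expect_false(or0$separation)
})

test_that("cluster-robust logistic SEs behave under degenerate and duplicated clustering", {
  set.seed(37)
  n <- 300
  d <- data.frame(x = rnorm(n), id = seq_len(n))
  d$y <- rbinom(n, 1, plogis(0.5 * d$x))
  fit1 <- cluster_robust_logistic(y ~ x, d, "id")
  g <- glm(y ~ x, family = binomial(), data = d)
  # with one observation per cluster the sandwich reduces to HC robust SEs
  # (up to the G/(G-1) cluster degrees-of-freedom adjustment)
  hc <- sqrt(diag(sandwich::vcovHC(g, type = "HC0")) * n / (n - 1))
  expect_equal(unname(fit1$coefficients[, "robust_se"]), unname(hc),
               tolerance = 1e-10)
  expect_equal(fit1$aic, -2 * fit1$loglik + 2 * fit1$k)
  # duplicating clusters: coefficients unchanged, cluster SEs not shrunk by sqrt(2)
  d2 <- rbind(d, d)
  fit2 <- cluster_robust_logistic(y ~ x, d2, c(d$id, d$id))
  expect_equal(fit2$coefficients[, "estimate"],
               fit1$coefficients[, "estimate"], tolerance = 1e-8)
  naive1 <- sqrt(diag(vcov(g)))
  naive2 <- sqrt(diag(vcov(glm(y ~ x, family = binomial(), data = d2))))
  expect_equal(unname(naive2 / naive1), rep(1 / sqrt(2), 2), tolerance = 1e-6)
  expect_equal(fit2$coefficients[, "robust_se"],
               fit1$coefficients[, "robust_se"], tolerance = 1e-6)
  expect_error(cluster_robust_logistic(y ~ x, d, rep(1, n)), "clusters")
})

test_that("cluster-robust CIs attain nominal coverage over seeded simulations", {
  # clusters of perfectly duplicated observations: the marginal logistic
  # model is correct, within-cluster correlation is maximal, and naive SEs
  # would be badly anticonservative
  set.seed(41)
  hits <- 0; B <- 150
  for (b in seq_len(B)) {
    x0 <- rnorm(150)
    y0 <- rbinom(150, 1, plogis(-0.5 + 0.6 * x0))
    d <- data.frame(x = rep(x0, each = 4), y = rep(y0, each = 4))
    f <- cluster_robust_logistic(y ~ x, d, rep(1:150, each = 4))
    ci <- f$coefficients["x", c("ci_low", "ci_high")]
    if (ci[1] <= 0.6 && 0.6 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / B, 0.90)
  expect_lte(hits / B, 0.99)
})

test_that("random-intercept logistic collapses to ordinary logistic at zero variance", {
  set.seed(43)
  n <- 1500
  d <- data.frame(x = rnorm(n), admission_id = rep(1:150, each = 10))
  d$y <- rbinom(n, 1, plogis(-0.3 + 0.7 * d$x))  # no cluster effect
  m <- random_intercept_logistic(y ~ x + (1 | admission_id), d)
  g <- glm(y ~ x, family = binomial(), data = d)
  expect_lt(abs(m$loglik - as.numeric(logLik(g))), 1e-3)
  expect_equal(m$aic, -2 * m$loglik + 2 * m$k)
  expect_lt(m$sd_intercept, 0.05)
})

test_that("AIC identity and the three-model comparison table", {
  expect_equal(-2 * (-100) + 2 * 3, 206)
  set.seed(47)
  id <- rep(1:80, each = 4)
  u <- rnorm(80, 0, 1)[id]
  day <- rep(1:4, 80)
  doms <- matrix(sample(0:4, 320 * 6, TRUE), 320, 6,
                 dimnames = list(NULL, c("respiration", "coagulation",
                                         "liver", "cardiovascular", "brain",
                                         "renal")))
  total <- rowSums(doms)
  y <- rbinom(320, 1, plogis(-2 + 0.15 * total + u))
  d <- data.frame(admission_id = id, day = day, total = total, doms,
                  outcome = y)
  cmp <- glmm_aic_comparison(d)
  expect_equal(cmp$aic, -2 * cmp$loglik + 2 * cmp$k)
  expect_lt(cmp$aic[cmp$model == "total_time"],
            cmp$aic[cmp$model == "null"])
})

test_that("chained-equation imputation is deterministic, complete-data invariant, and MCAR-consistent", {
  set.seed(53)
  n <- 600
  x1 <- rnorm(n); x2 <- 0.7 * x1 + rnorm(n, 0, 0.5)
  y <- rbinom(n, 1, plogis(x1))
  full <- data.frame(x1 = x1, x2 = x2, y = y)
  # no missing values: output identical to input
  out0 <- mice_impute(full, m = 3, seed = 1)
  expect_identical(out0[[1]], full)
  # determinism
  dat <- full
  dat$x2[sample(n, 120)] <- NA
  a <- mice_impute(dat, m = 3, seed = 9)
  b <- mice_impute(dat, m = 3, seed = 9)
  expect_identical(a, b)
  # entirely missing variable is dropped with a warning
  dat2 <- dat; dat2$x3 <- NA_real_
  expect_warning(mice_impute(dat2, m = 2, seed = 1), "x3")
  # MCAR: pooled AUROC of x2 for y close to complete-data AUROC
  auc_full <- auroc(full$x2, full$y)
  pooled <- mice_sensitivity(dat, function(d) {
    dl <- delong_inference(d$x2, d$y)
    list(estimate = dl$estimate, variance = dl$se^2)
  }, m = 5, seed = 31)
  expect_equal(pooled$estimate, auc_full, tolerance = 0.03)
  expect_true(pooled$ci_low <= auc_full && auc_full <= pooled$ci_high)
})

test_that("Rubin pooling combines within- and between-imputation variance", {
  est <- c(0.70, 0.72, 0.71)
  v <- c(0.001, 0.001, 0.001)
  p <- pool_rubin(est, v)
  expect_equal(p$estimate, mean(est))
  tot <- mean(v) + (1 + 1 / 3) * var(est)
  expect_gt(p$ci_high - p$ci_low, 2 * 1.96 * sqrt(mean(v)))
  expect_equal(p$within, mean(v))
  expect_equal(p$between, var(est))
})
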