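# Predictive-validity battery: discrimination, calibration, reclassification
# indices, and multiplicity adjustment.

metric_result <- function(metric, estimate, ci_low = NA_real_,
                          ci_high = NA_real_, p = NA_real_, n = NA_integer_,
                          adjusted = FALSE, optimism_corrected = FALSE,
                          extra = NULL) {
  out <- list(metric = metric, estimate = estimate, ci_low = ci_low,
              ci_high = ci_high, p = p, n = n, adjusted = adjusted,
              optimism_corrected = optimism_corrected)
  if (!is.null(extra)) out <- c(out, extra)
  structure(out, class = "metric_result")
}

#' @export
print.metric_result <- function(x, digits = 4, ...) {
  cat("<metric_result> ", x$metric, ": ", round(x$estimate, digits), sep = "")
  if (!is.na(x$ci_low))
    cat(" (95% CI ", round(x$ci_low, digits), "-", round(x$ci_high, digits),
        ")", sep = "")
  if (!is.na(x$p)) cat(", p = ", signif(x$p, 3), sep = "")
  cat(", n = ", x$n, sep = "")
  if (x$optimism_corrected) cat(" [optimism-corrected]")
  cat("\n")
  invisible(x)
}

.check_labels <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (sum(labels) == 0L || sum(labels) == length(labels))
    stop("labels must contain at least one event and one non-event")
  labels
}

#' Area under the ROC curve (Mann--Whitney estimator)
#'
#' The probability that a random event outranks a random non-event, with
#' ties counting one half — identical to the AUROC of a univariate logistic
#' model of any monotone score. Inference (DeLong 95% CI) via
#' [delong_inference()].
#'
#' @param scores Numeric predictor.
#' @param labels Binary outcome (0/1 or logical).
#' @return The AUROC in \[0, 1\].
#' @examples
#' auroc(c(1, 2, 3, 4), c(0, 1, 0, 1))  # 0.75
#' @export
auroc <- function(scores, labels) {
  labels <- .check_labels(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  m <- sum(labels); n <- length(labels) - m
  r <- rank(scores)
  (sum(r[labels == 1L]) - m * (m + 1) / 2) / (m * n)
}

# midrank-based DeLong structural components (placement values)
.delong_components <- function(scores, labels) {
  x <- scores[labels == 1L]; y <- scores[labels == 0L]
  m <- length(x); n <- length(y)
  tz <- rank(c(x, y))
  tx <- rank(x); ty <- rank(y)
  v10 <- (tz[seq_len(m)] - tx) / n
  v01 <- 1 - (tz[m + seq_len(n)] - ty) / m
  auc <- sum(tz[seq_len(m)]) / (m * n) - (m + 1) / (2 * n)
  list(auc = auc, v10 = v10, v01 = v01, m = m, n = n)
}

#' DeLong inference for one AUROC or a paired comparison
#'
#' Nonparametric variance of the Mann--Whitney AUROC from the DeLong
#' structural components, giving a Wald confidence interval; with a second
#' paired score vector, the covariance of the two AUROCs and a paired
#' z-test of the difference.
#'
#' @param scores_a Numeric predictor.
#' @param labels Shared binary outcome.
#' @param scores_b Optional second predictor on the same subjects.
#' @param conf_level Confidence level.
#' @return For one score, a `metric_result` for the AUROC. For two, a list
#'   of class `delong_comparison` with `auroc_a`, `auroc_b`, `delta`,
#'   `se_delta`, `p`, `ci_low`, `ci_high`.
#' @export
delong_inference <- function(scores_a, labels, scores_b = NULL,
                             conf_level = 0.95) {
  labels <- .check_labels(labels)
  stopifnot(length(scores_a) == length(labels))
  za <- .delong_components(scores_a, labels)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  var1 <- function(z) {
    s10 <- if (z$m > 1) stats::var(z$v10) else 0
    s01 <- if (z$n > 1) stats::var(z$v01) else 0
    s10 / z$m + s01 / z$n
  }
  if (is.null(scores_b)) {
    v <- var1(za)
    se <- sqrt(v)
    return(metric_result("auroc_delong", za$auc,
                         max(0, za$auc - zq * se), min(1, za$auc + zq * se),
                         n = length(labels),
                         extra = list(se = se)))
  }
  stopifnot(length(scores_b) == length(labels))
  zb <- .delong_components(scores_b, labels)
  cov10 <- if (za$m > 1) stats::cov(za$v10, zb$v10) else 0
  cov01 <- if (za$n > 1) stats::cov(za$v01, zb$v01) else 0
  vd <- var1(za) + var1(zb) - 2 * (cov10 / za$m + cov01 / za$n)
  delta <- za$auc - zb$auc
  se <- sqrt(max(vd, 0))
  p <- if (se == 0) as.numeric(delta != 0) else 2 * stats::pnorm(-abs(delta / se))
  if (se == 0 && delta == 0) p <- 1
  structure(list(auroc_a = za$auc, auroc_b = zb$auc, delta = delta,
                 se_delta = se, p = p,
                 ci_low = delta - zq * se, ci_high = delta + zq * se,
                 n = length(labels)),
            class = "delong_comparison")
}

#' @export
print.delong_comparison <- function(x, digits = 4, ...) {
  cat("<DeLong paired comparison> AUROC a = ", round(x$auroc_a, digits),
      ", b = ", round(x$auroc_b, digits), ", delta = ",
      round(x$delta, digits), " (95% CI ", round(x$ci_low, digits), "-",
      round(x$ci_high, digits), "), p = ", signif(x$p, 3), "\n", sep = "")
  invisible(x)
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and the binary
#' outcome.
#'
#' @param probabilities Predicted probabilities in \[0, 1\].
#' @param labels Binary outcome.
#' @return A `metric_result`.
#' @export
brier <- function(probabilities, labels) {
  stopifnot(length(probabilities) == length(labels),
            all(probabilities >= 0 & probabilities <= 1))
  labels <- as.integer(labels)
  metric_result("brier", mean((probabilities - labels)^2),
                n = length(labels))
}

#' Calibration intercept and slope
#'
#' Calibration-in-the-large (the intercept of a logistic model of the
#' outcome with the model logit as an offset) and the calibration slope
#' (the coefficient of a logistic refit of the outcome on the model logit).
#' Probabilities of exactly 0 or 1 are clipped at `eps` with a warning
#' before the logit transform. Evaluated in-sample on the fitting data,
#' maximum-likelihood score equations force intercept 0 and slope 1.
#'
#' @param probabilities Model probabilities.
#' @param labels Binary outcome.
#' @param eps Clipping bound for the logit transform.
#' @return List with `intercept` and `slope`.
#' @export
calibration <- function(probabilities, labels, eps = 1e-12) {
  labels <- .check_labels(labels)
  if (any(probabilities <= 0 | probabilities >= 1)) {
    warning("probabilities at 0/1 clipped at eps = ", eps, " before logit")
    probabilities <- pmin(pmax(probabilities, eps), 1 - eps)
  }
  lp <- stats::qlogis(probabilities)
  # suppressWarnings: extreme logits trigger benign fitted-0/1 precision
  # warnings in glm.fit without affecting the coefficient estimates
  slope_fit <- suppressWarnings(
    stats::glm(labels ~ lp, family = stats::binomial(),
               control = list(epsilon = 1e-12, maxit = 100)))
  int_fit <- suppressWarnings(
    stats::glm(labels ~ 1 + offset(lp), family = stats::binomial(),
               control = list(epsilon = 1e-12, maxit = 100)))
  list(intercept = unname(stats::coef(int_fit)[1]),
       slope = unname(stats::coef(slope_fit)[2]))
}

#' Harrell bootstrap optimism correction
#'
#' For a model-fitting function and a performance metric, estimates the
#' optimism of the apparent (in-sample) performance by refitting the model
#' on bootstrap resamples, evaluating each refit on its own resample and on
#' the original data, and averaging the difference. The corrected estimate
#' is apparent minus mean optimism; the CI is the percentile interval of the
#' test performances (each refit evaluated on the original data), shifted is
#' not applied. Resamples whose outcome is single-class are redrawn, up to a
#' capped retry count.
#'
#' @param data Data frame passed to `fit_fn`.
#' @param fit_fn Function `data -> model`.
#' @param metric_fn Function `(model, data) -> numeric scalar`.
#' @param B Number of bootstrap resamples (>= 2).
#' @param seed Integer seed; identical data + seed give identical results.
#' @param outcome_col Name of the binary outcome column used for the
#'   single-class retry check (`NULL` disables the check).
#' @param conf_level CI level.
#' @return A `metric_result` with `optimism` and `apparent` fields.
#' @export
optimism_correct <- function(data, fit_fn, metric_fn, B = 500, seed = 1,
                             outcome_col = NULL, conf_level = 0.95) {
  stopifnot(B >= 2)
  set.seed(seed)
  apparent <- metric_fn(fit_fn(data), data)
  n <- nrow(data)
  opt <- test_perf <- numeric(B)
  for (b in seq_len(B)) {
    for (try in 1:25) {
      idx <- sample.int(n, n, replace = TRUE)
      if (is.null(outcome_col)) break
      y <- data[[outcome_col]][idx]
      if (length(unique(y)) > 1) break
      if (try == 25) stop("could not draw a two-class bootstrap resample")
    }
    boot <- data[idx, , drop = FALSE]
    fit_b <- fit_fn(boot)
    perf_boot <- metric_fn(fit_b, boot)
    perf_orig <- metric_fn(fit_b, data)
    opt[b] <- perf_boot - perf_orig
    test_perf[b] <- perf_orig
  }
  a <- (1 - conf_level) / 2
  ci <- stats::quantile(test_perf, c(a, 1 - a), names = FALSE, type = 7)
  metric_result("optimism_corrected", apparent - mean(opt),
                ci[1], ci[2], n = n, optimism_corrected = TRUE,
                extra = list(apparent = apparent, optimism = mean(opt),
                             B = B))
}

#' Continuous net reclassification improvement
#'
#' `NRI = [P(up | event) - P(down | event)] +
#' [P(down | non-event) - P(up | non-event)]` where up/down are strict
#' movements of the predicted probability from the old to the new model;
#' ties contribute to neither direction. Range \[-2, 2\]; antisymmetric
#' under swapping the models. The CI uses the standard large-sample
#' variance of the two net proportions.
#'
#' @param p_new,p_old Paired predicted probabilities.
#' @param labels Binary outcome.
#' @return A `metric_result` with `event_component` and
#'   `nonevent_component`.
#' @export
continuous_nri <- function(p_new, p_old, labels) {
  labels <- .check_labels(labels)
  stopifnot(length(p_new) == length(labels), length(p_old) == length(labels))
  d <- p_new - p_old
  ev <- labels == 1L
  up_e <- mean(d[ev] > 0); dn_e <- mean(d[ev] < 0)
  up_n <- mean(d[!ev] > 0); dn_n <- mean(d[!ev] < 0)
  comp_e <- up_e - dn_e
  comp_n <- dn_n - up_n
  nri <- comp_e + comp_n
  ne <- sum(ev); nn <- sum(!ev)
  v <- (up_e + dn_e - comp_e^2) / ne + (up_n + dn_n - comp_n^2) / nn
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(0.975)
  p <- if (se == 0) NA_real_ else 2 * stats::pnorm(-abs(nri / se))
  metric_result("continuous_nri", nri, nri - z * se, nri + z * se, p = p,
                n = length(labels),
                extra = list(event_component = comp_e,
                             nonevent_component = comp_n))
}

#' Integrated discrimination improvement components
#'
#' `IDI+` is the mean probability change (new minus old) among events;
#' `IDI-` the mean change (old minus new) among non-events.
#'
#' @inheritParams continuous_nri
#' @return List of two `metric_result`s, `idi_pos` and `idi_neg`, each with
#'   a normal-approximation CI.
#' @export
idi_components <- function(p_new, p_old, labels) {
  labels <- .check_labels(labels)
  stopifnot(length(p_new) == length(labels), length(p_old) == length(labels))
  d <- p_new - p_old
  one <- function(x, name) {
    se <- if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
    z <- stats::qnorm(0.975)
    metric_result(name, mean(x), mean(x) - z * se, mean(x) + z * se,
                  n = length(x))
  }
  list(idi_pos = one(d[labels == 1L], "idi_pos"),
       idi_neg = one(-d[labels == 0L], "idi_neg"))
}

#' Odds ratio per one-point increase of a score
#'
#' `exp` of the slope of a univariate logistic regression of the outcome on
#' the score, with a Wald confidence interval. Complete or quasi-complete
#' separation is flagged (`separation = TRUE`) rather than silently
#' reported.
#'
#' @param score Numeric score.
#' @param labels Binary outcome.
#' @param conf_level CI level.
#' @return A `metric_result` with `log_or`, `se`, `separation`.
#' @export
per_point_or <- function(score, labels, conf_level = 0.95) {
  labels <- .check_labels(labels)
  stopifnot(length(score) == length(labels))
  fit <- suppressWarnings(stats::glm(labels ~ score,
                                     family = stats::binomial(),
                                     control = list(epsilon = 1e-10,
                                                    maxit = 100)))
  b <- stats::coef(fit)[2]
  se <- sqrt(stats::vcov(fit)[2, 2])
  sep <- !fit$converged || abs(b) > 15 || se > 100
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- 2 * stats::pnorm(-abs(b / se))
  metric_result("per_point_or", exp(unname(b)),
                exp(unname(b) - zq * se), exp(unname(b) + zq * se), p = p,
                n = length(labels),
                extra = list(log_or = unname(b), se = unname(se),
                             separation = sep))
}

#' Bonferroni adjustment
#'
#' p-values map to `min(1, m p)`; for interval estimation the per-comparison
#' confidence level becomes `1 - alpha / m` (see `bonferroni_level()`).
#'
#' @param p Numeric vector of p-values.
#' @param m Number of comparisons in the family (>= 1).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, m * p)
}

#' @rdname bonferroni
#' @param alpha Family-wise level.
#' @export
bonferroni_level <- function(alpha = 0.05, m = 1) 1 - alpha / m
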