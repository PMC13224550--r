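# Model-based components of the validity battery: cluster-robust logistic
# models for repeated admission-days, random-intercept logistic models
# compared by AIC, and the chained-equations multiple-imputation hook.

model_fit <- function(label, coefficients, loglik, k, extra = NULL) {
  out <- list(label = label, coefficients = coefficients,
              loglik = loglik, k = k, aic = -2 * loglik + 2 * k)
  if (!is.null(extra)) out <- c(out, extra)
  structure(out, class = "sofa_model_fit")
}

#' @export
print.sofa_model_fit <- function(x, digits = 4, ...) {
  cat("<model fit> ", x$label, ": logLik = ", round(x$loglik, 2),
      ", k = ", x$k, ", AIC = ", round(x$aic, 2), "\n", sep = "")
  print(round(x$coefficients, digits))
  invisible(x)
}

#' Logistic regression with cluster-robust standard errors
#'
#' Ordinary logistic point estimates with a sandwich covariance aggregated
#' at the cluster (admission) level, for analyses pooling repeated
#' admission-days — e.g. the subscore-by-ICU-day interaction model. With one
#' observation per cluster this reduces to heteroskedasticity-robust (HC)
#' standard errors.
#'
#' @param formula Model formula (binary response).
#' @param data Long data frame of admission-days.
#' @param cluster Cluster identifiers (vector, or a column name in `data`).
#' @return A `sofa_model_fit` with a coefficient table (`estimate`,
#'   `robust_se`, `z`, `p`, `ci_low`, `ci_high`), log-likelihood, and AIC.
#' @export
cluster_robust_logistic <- function(formula, data, cluster) {
  if (is.character(cluster) && length(cluster) == 1)
    cluster <- data[[cluster]]
  if (length(unique(cluster)) < 2) stop("need at least 2 clusters")
  fit <- stats::glm(formula, family = stats::binomial(), data = data)
  V <- sandwich::vcovCL(fit, cluster = cluster, type = "HC0")
  b <- stats::coef(fit)
  se <- sqrt(diag(V))
  z <- b / se
  tab <- cbind(estimate = b, robust_se = se, z = z,
               p = 2 * stats::pnorm(-abs(z)),
               ci_low = b - stats::qnorm(0.975) * se,
               ci_high = b + stats::qnorm(0.975) * se)
  ll <- as.numeric(stats::logLik(fit))
  model_fit(paste(deparse(formula), collapse = ""), tab, ll,
            attr(stats::logLik(fit), "df"),
            extra = list(glm_fit = fit, vcov_cluster = V,
                         n_clusters = length(unique(cluster))))
}

#' Random-intercept logistic model
#'
#' Mixed-effects logistic regression with a random intercept per ICU
#' admission (fitted by Laplace/adaptive-quadrature via `lme4::glmer`),
#' giving conditional (within-admission) associations. Non-convergence is
#' reported through the `converged` and `messages` fields, never silently.
#'
#' @param formula An `lme4` formula including a random-intercept term, e.g.
#'   `outcome ~ score + day + (1 | admission_id)`.
#' @param data Long data frame.
#' @param nAGQ Number of adaptive Gauss--Hermite quadrature points.
#' @return A `sofa_model_fit` with fixed-effect table, `sd_intercept`,
#'   log-likelihood and AIC.
#' @export
random_intercept_logistic <- function(formula, data, nAGQ = 1) {
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(formula, data = data, family = stats::binomial(),
                nAGQ = nAGQ),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  tab <- cbind(estimate = b, se = se, z = b / se,
               p = 2 * stats::pnorm(-abs(b / se)))
  vc <- lme4::VarCorr(fit)
  sd_int <- attr(vc[[1]], "stddev")[1]
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  conv <- length(fit@optinfo$conv$lme4) == 0
  model_fit(paste(deparse(formula), collapse = ""), tab, ll, k,
            extra = list(glmer_fit = fit, sd_intercept = unname(sd_int),
                         converged = conv, messages = msgs))
}

#' Compare the three standard mixed-model specifications by AIC
#'
#' Fits (i) a null model with a random intercept only, (ii) a model adding
#' the total score and ICU-day, and (iii) a model with ICU-day and the six
#' individual subscores, all with a random intercept per admission, and
#' tabulates their AIC.
#'
#' @param data Long admission-day data with columns `outcome`, `total`,
#'   `day`, the six domain subscores, and `admission_id`.
#' @param nAGQ Quadrature points passed on.
#' @return Data frame `model`, `loglik`, `k`, `aic`, plus the fits as the
#'   `fits` attribute.
#' @export
glmm_aic_comparison <- function(data, nAGQ = 1) {
  f1 <- outcome ~ (1 | admission_id)
  f2 <- outcome ~ total + day + (1 | admission_id)
  f3 <- stats::as.formula(paste(
    "outcome ~ day +", paste(.sofa_domains, collapse = " + "),
    "+ (1 | admission_id)"))
  fits <- list(null = random_intercept_logistic(f1, data, nAGQ),
               total_time = random_intercept_logistic(f2, data, nAGQ),
               subscores_time = random_intercept_logistic(f3, data, nAGQ))
  out <- data.frame(model = names(fits),
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    k = vapply(fits, `[[`, 0, "k"),
                    aic = vapply(fits, `[[`, 0, "aic"))
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

# Bayesian linear regression imputation of one variable (chained-equations
# "norm" step): posterior draw of (beta, sigma), then draw the missing values.
.impute_norm_draw <- function(y, X) {
  obs <- !is.na(y)
  Xo <- X[obs, , drop = FALSE]; yo <- y[obs]
  keep <- c(TRUE, apply(Xo[, -1, drop = FALSE], 2,
                        function(cc) stats::sd(cc) > 0))
  Xo <- Xo[, keep, drop = FALSE]
  qrX <- qr(Xo)
  bhat <- qr.coef(qrX, yo)
  bhat[is.na(bhat)] <- 0
  res <- yo - Xo %*% bhat
  df <- max(length(yo) - ncol(Xo), 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  R <- qr.R(qrX)
  Ri <- tryCatch(backsolve(R, diag(ncol(Xo))), error = function(e) NULL)
  if (is.null(Ri)) {
    bstar <- bhat
  } else {
    bstar <- bhat + sqrt(sigma2) * (Ri %*% stats::rnorm(ncol(Xo)))
  }
  Xm <- X[!obs, keep, drop = FALSE]
  as.numeric(Xm %*% bstar + stats::rnorm(sum(!obs), 0, sqrt(sigma2)))
}

#' Multiple imputation by chained equations (normal-model steps)
#'
#' A compact chained-equations imputer for numeric tables: each variable
#' with missing values is imputed in turn from all other variables by
#' Bayesian linear regression (posterior draws of coefficients and residual
#' variance, then draws of the missing values), cycling `maxit` times, and
#' the whole process is repeated `m` times from independent starts.
#' Variables that are entirely missing are dropped with a warning.
#' Identical seed and input give identical imputations.
#'
#' @param data Data frame; only numeric columns are imputed, others are
#'   carried through unchanged.
#' @param m Number of completed data sets (>= 2).
#' @param maxit Chained-equation cycles per data set.
#' @param seed Integer seed.
#' @return List of `m` completed data frames.
#' @export
mice_impute <- function(data, m = 5, maxit = 5, seed = 1) {
  stopifnot(m >= 2)
  set.seed(seed)
  num <- names(data)[vapply(data, is.numeric, TRUE)]
  all_miss <- num[vapply(num, function(v) all(is.na(data[[v]])), TRUE)]
  if (length(all_miss)) {
    warning("dropping entirely missing variable(s): ",
            paste(all_miss, collapse = ", "))
    data <- data[setdiff(names(data), all_miss)]
    num <- setdiff(num, all_miss)
  }
  targets <- num[vapply(num, function(v) anyNA(data[[v]]), TRUE)]
  if (!length(targets)) return(replicate(m, data, simplify = FALSE))
  lapply(seq_len(m), function(i) {
    comp <- data
    # initial fill: random draws from the observed margin
    for (v in targets) {
      mis <- is.na(comp[[v]])
      comp[[v]][mis] <- sample(comp[[v]][!mis], sum(mis), replace = TRUE)
    }
    for (it in seq_len(maxit)) {
      for (v in targets) {
        preds <- setdiff(num, v)
        X <- cbind(1, as.matrix(comp[preds]))
        y <- data[[v]]           # original missingness pattern
        comp[[v]][is.na(y)] <- .impute_norm_draw(
          ifelse(is.na(y), NA, comp[[v]]), X)
      }
    }
    comp
  })
}

#' Pool estimates across imputations by Rubin's rules
#'
#' @param estimates Numeric vector of per-imputation point estimates.
#' @param variances Numeric vector of per-imputation squared standard
#'   errors.
#' @param conf_level CI level.
#' @return A `metric_result` with the pooled estimate, total-variance CI
#'   (t reference with Rubin's degrees of freedom), and the between/within
#'   variance split.
#' @export
pool_rubin <- function(estimates, variances, conf_level = 0.95) {
  m <- length(estimates)
  stopifnot(m >= 2, length(variances) == m)
  qbar <- mean(estimates)
  ubar <- mean(variances)
  b <- stats::var(estimates)
  t <- ubar + (1 + 1 / m) * b
  if (t == 0) {
    return(metric_result("rubin_pooled", qbar, qbar, qbar, n = m,
                         extra = list(between = b, within = ubar)))
  }
  r <- (1 + 1 / m) * b / ubar
  df <- if (b == 0) Inf else (m - 1) * (1 + 1 / r)^2
  tq <- stats::qt(1 - (1 - conf_level) / 2, df)
  metric_result("rubin_pooled", qbar, qbar - tq * sqrt(t),
                qbar + tq * sqrt(t), n = m,
                extra = list(between = b, within = ubar, df = df))
}

#' Multiple-imputation sensitivity analysis for a validity metric
#'
#' Imputes the domain-day table `m` times with [mice_impute()], applies a
#' metric function to each completed table, and pools by Rubin's rules.
#'
#' @param data Domain-day table with missingness.
#' @param metric_fn Function `completed_data -> list(estimate, variance)`.
#' @param m,maxit,seed Passed to [mice_impute()].
#' @return A pooled `metric_result` (see [pool_rubin()]), with the
#'   per-imputation estimates in `$estimates`.
#' @export
mice_sensitivity <- function(data, metric_fn, m = 5, maxit = 5, seed = 1) {
  completed <- mice_impute(data, m = m, maxit = maxit, seed = seed)
  res <- lapply(completed, metric_fn)
  est <- vapply(res, function(r) r$estimate, numeric(1))
  v <- vapply(res, function(r) r$variance, numeric(1))
  out <- pool_rubin(est, v)
  out$estimates <- est
  out
}

#' @importFrom stats qt var cov
NULL
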