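## stratum_estimate constructor: one fitted observational or genetic model
new_stratum_estimate <- function(beta, se, n, model, sex = "all", region = "both",
                                 cohort = NA_character_, extra = list()) {
  if (!is.finite(se) || se <= 0)
    stop_mrwell("standard error must be positive and finite", class = "mrwell_numerical_error")
  z <- beta / se
  est <- c(list(beta = unname(beta), se = unname(se), n = n, model = model,
                sex = sex, region = region, cohort = cohort,
                p = 2 * pnorm(abs(z), lower.tail = FALSE)), extra)
  class(est) <- "stratum_estimate"
  est
}

#' @export
print.stratum_estimate <- function(x, ...) {
  cat(sprintf("%s estimate [%s, %s]: beta = %.4f (SE %.4f, 95%% CI %.4f to %.4f), n = %d, P = %.3g\n",
              x$model, x$sex, x$region, x$beta, x$se,
              x$beta - 1.96 * x$se, x$beta + 1.96 * x$se, as.integer(x$n), x$p))
  invisible(x)
}

#' Observational association of an outcome with the exposure
#'
#' Ordinary least squares of a (numerically coded ordinal) outcome on the
#' exposure expressed in SD units, plus covariates. The exposure SD used for
#' scaling is computed within the analysed complete-case sample unless a
#' fixed external SD is supplied.
#'
#' @param exposure numeric vector (e.g. BMI in kg/m2).
#' @param outcome numeric vector (ordinal outcomes treated as numeric).
#' @param covariates covariate specification: `NULL`, a data.frame, or
#'   column names resolved against `data`.
#' @param data optional data.frame for resolving covariate names.
#' @param exposure_sd optional fixed SD; default: sample SD of the analysed
#'   exposure values.
#' @param ... stratum labels (`sex`, `region`, `cohort`) forwarded to the
#'   returned estimate.
#' @return a `stratum_estimate` with `model = "observational"`.
#' @export
observational_fit <- function(exposure, outcome, covariates = NULL, data = NULL,
                              exposure_sd = NULL, ...) {
  covmat <- covariate_matrix(covariates, data)
  keep <- complete.cases(exposure, outcome, covmat)
  x <- exposure[keep]; y <- outcome[keep]
  covmat <- if (is.null(covmat)) NULL else covmat[keep, , drop = FALSE]
  n <- length(x)
  if (n < (ncol(covmat) %||% 0) + 3)
    stop_mrwell("too few complete cases", class = "mrwell_numerical_error")
  s <- exposure_sd %||% sd(x)
  X <- cbind(`(Intercept)` = 1, x_sd = x / s, covmat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop_mrwell("singular design; collinear column(s): ",
                paste(colnames(X)[qrX$pivot[-seq_len(qrX$rank)]], collapse = ", "),
                class = "mrwell_numerical_error")
  }
  b <- qr.coef(qrX, y)
  res <- qr.resid(qrX, y)
  sigma2 <- sum(res^2) / (n - ncol(X))
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(pmax(sigma2 * diag(XtXinv), 0))
  new_stratum_estimate(b["x_sd"], se[2], n, model = "observational",
                       extra = list(exposure_sd = s), ...)
}

#' Two-stage least-squares Mendelian randomisation estimate
#'
#' Stage 1 regresses the exposure (in SD units) on the genetic risk score
#' plus covariates; stage 2 regresses the outcome on the stage-1 fitted
#' exposure plus the same covariates. The reported standard error is the
#' proper instrumental-variable one: the residual variance is computed from
#' the *observed* exposure (`y - X b`), not the stage-2 fitted values, and
#' the coefficient covariance is `sigma2 (X'P_Z X)^{-1}`. With a single
#' instrument and no covariates the estimate equals the Wald ratio.
#'
#' @param grs a [grs_result] or numeric instrument vector.
#' @param exposure,outcome numeric vectors.
#' @param covariates covariate specification (both stages use the same set).
#' @param data optional data.frame for resolving covariate names.
#' @param exposure_sd optional fixed SD for per-SD scaling.
#' @param f_warn_threshold stage-1 partial F below this emits a
#'   weak-instrument warning (default 10).
#' @param ... stratum labels forwarded to the estimate.
#' @return a `stratum_estimate` with `model = "tsls"`; carries the stage-1
#'   `f_statistic` and the `exposure_sd` used.
#' @export
tsls_fit <- function(grs, exposure, outcome, covariates = NULL, data = NULL,
                     exposure_sd = NULL, f_warn_threshold = 10, ...) {
  g <- if (inherits(grs, "grs_result")) grs$grs_s else as.numeric(grs)
  covmat <- covariate_matrix(covariates, data)
  keep <- complete.cases(g, exposure, outcome, covmat)
  g <- g[keep]; x <- exposure[keep]; y <- outcome[keep]
  covmat <- if (is.null(covmat)) NULL else covmat[keep, , drop = FALSE]
  n <- length(x)
  s <- exposure_sd %||% sd(x)
  x_sd <- x / s

  Z <- cbind(`(Intercept)` = 1, g = g, covmat)      # instruments + exogenous
  X <- cbind(`(Intercept)` = 1, x_sd = x_sd, covmat) # regressors
  k <- ncol(X)
  if (n < k + 2) stop_mrwell("too few complete cases", class = "mrwell_numerical_error")
  qrZ <- qr(Z)
  Xhat <- qr.fitted(qrZ, X)                          # P_Z X
  A <- crossprod(Xhat, X)                            # X'P_Z X (just-identified: square)
  b <- solve(A, crossprod(Xhat, y))
  res <- y - X %*% b                                 # residuals from observed exposure
  sigma2 <- sum(res^2) / (n - k)
  V <- sigma2 * solve(A)
  se <- sqrt(diag(V))[match("x_sd", colnames(X))]

  ## stage-1 partial F for the instrument
  X0 <- cbind(rep(1, n), covmat)
  rss0 <- sum(qr.resid(qr(X0), x_sd)^2)
  rss1 <- sum(qr.resid(qrZ, x_sd)^2)
  f1 <- (rss0 - rss1) / (rss1 / (n - ncol(Z)))
  if (f1 < f_warn_threshold)
    warning(sprintf("weak instrument: stage-1 F = %.2f", f1), call. = FALSE)

  new_stratum_estimate(b[match("x_sd", colnames(X))], se, n, model = "tsls",
                       extra = list(f_statistic = f1, exposure_sd = s), ...)
}

#' Fixed-effects (inverse-variance) meta-analysis
#'
#' Pools stratum estimates with weights `w_i = 1/SE_i^2`:
#' pooled beta `= sum(w b) / sum(w)`, pooled SE `= 1/sqrt(sum(w))`,
#' Cochran's `Q = sum(w (b - pooled)^2)` on `k - 1` degrees of freedom, with
#' the heterogeneity P from the upper chi-square tail.
#'
#' @param estimates list of `stratum_estimate` objects, or a data.frame with
#'   `beta` and `se` columns.
#' @return object of class `meta_result`: `beta`, `se`, `p`, `q`, `df`,
#'   `i_squared` (percentage), `p_heterogeneity`, `k`, `n`.
#' @export
meta_fixed <- function(estimates) {
  df <- as_estimate_table(estimates)
  if (nrow(df) == 0) stop_mrwell("no estimates to pool", class = "mrwell_validation_error")
  if (any(df$se <= 0)) stop_mrwell("all SEs must be > 0", class = "mrwell_validation_error")
  w <- 1 / df$se^2
  beta <- sum(w * df$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- sum(w * (df$beta - beta)^2)
  dof <- nrow(df) - 1L
  res <- list(beta = beta, se = se,
              p = 2 * pnorm(abs(beta / se), lower.tail = FALSE),
              q = q, df = dof,
              i_squared = if (dof >= 1) i_squared_from_q(q, dof) else NA_real_,
              p_heterogeneity = if (dof >= 1) pchisq(q, dof, lower.tail = FALSE) else NA_real_,
              k = nrow(df),
              n = if ("n" %in% names(df)) sum(df$n, na.rm = TRUE) else NA_integer_)
  class(res) <- "meta_result"
  res
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("fixed-effects meta: beta = %.4f (SE %.4f), k = %d, Q = %.3f (df %d), I2 = %.1f%%, P_het = %.3g\n",
              x$beta, x$se, x$k, x$q, x$df,
              ifelse(is.na(x$i_squared), NaN, x$i_squared), x$p_heterogeneity))
  invisible(x)
}

i_squared_from_q <- function(q, df) {
  if (q <= 0) return(0)
  max(0, (q - df) / q) * 100
}

#' I-squared heterogeneity statistic
#'
#' `I2 = max(0, (Q - df) / Q) * 100`, the percentage of variability across
#' stratum estimates attributable to heterogeneity rather than chance.
#' Returns 0 when Q is 0.
#'
#' @param meta a `meta_result`, or a numeric Q (with `df` supplied).
#' @param df degrees of freedom (only when `meta` is numeric).
#' @return percentage in \[0, 100\].
#' @export
i_squared <- function(meta, df = NULL) {
  if (inherits(meta, "meta_result")) return(i_squared_from_q(meta$q, meta$df))
  if (is.null(df) || df < 1) stop_mrwell("df must be >= 1", class = "mrwell_config_error")
  i_squared_from_q(meta, df)
}

#' Back-calculate a standard error from a printed confidence interval
#'
#' `SE = (upper - lower) / (2 z)` with `z` the standard-normal quantile for
#' the interval's confidence level (1.96 for 95%). This is how published
#' betas with CIs are converted to the SEs the Fisher z comparison needs.
#'
#' @param lower,upper interval bounds.
#' @param level confidence level (default 0.95).
#' @return standard error.
#' @export
ci_to_se <- function(lower, upper, level = 0.95) {
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop_mrwell("interval bounds must be finite", class = "mrwell_validation_error")
  if (any(upper <= lower))
    stop_mrwell("upper bound must exceed lower bound", class = "mrwell_validation_error")
  (upper - lower) / (2 * qnorm((1 + level) / 2))
}

#' Fisher z test for a difference between two independent estimates
#'
#' \deqn{z = (\beta_1 - \beta_2) / \sqrt{SE_1^2 + SE_2^2}}
#' with the two-sided P computed through the normal survival function, which
#' stays accurate for extremely small values (well below 1e-300); the
#' base-10 log of P is also returned for display of values beyond double
#' underflow.
#'
#' @param est1,est2 `stratum_estimate`-like objects (anything with `beta`
#'   and `se`), or `cf_result` objects when comparing quadratic terms via
#'   [compare_nonlinear()].
#' @return object of class `diff_test`: `z`, `p`, `log10_p`, `beta1`,
#'   `beta2`, `se1`, `se2`.
#' @export
fisher_z_diff <- function(est1, est2) {
  b1 <- est1$beta; s1 <- est1$se
  b2 <- est2$beta; s2 <- est2$se
  if (s1 <= 0 || s2 <= 0)
    stop_mrwell("both SEs must be > 0", class = "mrwell_validation_error")
  z <- (b1 - b2) / sqrt(s1^2 + s2^2)
  log_p <- pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)
  res <- list(z = z, p = min(1, 2 * pnorm(abs(z), lower.tail = FALSE)),
              log10_p = log_p / log(10),
              beta1 = b1, beta2 = b2, se1 = s1, se2 = s2)
  class(res) <- "diff_test"
  res
}

#' @export
print.diff_test <- function(x, ...) {
  cat(sprintf("Fisher z difference: z = %.3f, two-sided P = %.3g (log10 P = %.2f)\n",
              x$z, x$p, x$log10_p))
  invisible(x)
}
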