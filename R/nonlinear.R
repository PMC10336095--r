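## Gaussian AIC with the error variance profiled at its MLE.
## k counts intercept + slope terms + covariates (not the variance), so that
## models on the same data are compared on a single consistent convention.
gaussian_aic <- function(rss, n, k) {
  n * log(rss / n) + n * (1 + log(2 * pi)) + 2 * k
}

## least-squares fit of y on columns `terms` plus covariates; returns the
## pieces every non-linear model here needs
.ls_fit <- function(terms, y, covmat = NULL) {
  X <- cbind(`(Intercept)` = 1, terms, covmat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop_mrwell("singular design in non-linear fit", class = "mrwell_numerical_error")
  b <- qr.coef(qrX, y)
  res <- qr.resid(qrX, y)
  rss <- sum(res^2)
  n <- length(y)
  k <- ncol(X)
  sigma2 <- rss / (n - k)
  XtXinv <- chol2inv(qr.R(qrX))
  list(coef = b, se = sqrt(pmax(sigma2 * diag(XtXinv), 0)),
       rss = rss, n = n, k = k,
       loglik = -0.5 * (n * log(rss / n) + n * (1 + log(2 * pi))),
       aic = gaussian_aic(rss, n, k),
       fitted = drop(X %*% b))
}

#' Quadratic regression of an outcome on the exposure
#'
#' Fits `y ~ (x - c) + (x - c)^2 + covariates` with `c = mean(x)`; centring
#' before squaring reduces the collinearity between the linear and quadratic
#' columns. Coefficients are reported on the centred scale with the centre
#' stored. The AIC uses the Gaussian likelihood with the variance profiled
#' at its MLE, the same convention as the fractional-polynomial fits, so
#' this fit is directly comparable with (and identical to) the degree-2
#' fractional polynomial at powers (1, 2).
#'
#' @param x,y exposure and outcome vectors.
#' @param covariates covariate specification.
#' @param data optional data.frame for covariate names.
#' @return list (class `quadratic_fit`): `beta_linear`, `beta_quadratic`,
#'   `se_linear`, `se_quadratic`, `p_quadratic`, `aic`, `loglik`, `centre`,
#'   `n`, `fitted`.
#' @export
fit_quadratic <- function(x, y, covariates = NULL, data = NULL) {
  covmat <- covariate_matrix(covariates, data)
  keep <- complete.cases(x, y, covmat)
  x <- x[keep]; y <- y[keep]
  covmat <- if (is.null(covmat)) NULL else covmat[keep, , drop = FALSE]
  if (length(x) < (ncol(covmat) %||% 0) + 4)
    stop_mrwell("too few observations for a quadratic fit", class = "mrwell_numerical_error")
  ctr <- mean(x)
  xc <- x - ctr
  fit <- .ls_fit(cbind(x = xc, x2 = xc^2), y, covmat)
  tq <- fit$coef["x2"] / fit$se[3]
  structure(list(beta_linear = unname(fit$coef["x"]),
                 beta_quadratic = unname(fit$coef["x2"]),
                 se_linear = fit$se[2], se_quadratic = fit$se[3],
                 p_quadratic = 2 * pnorm(abs(tq), lower.tail = FALSE),
                 aic = fit$aic, loglik = fit$loglik, centre = ctr,
                 n = fit$n, k = fit$k, fitted = fit$fitted),
            class = "quadratic_fit")
}

#' Plain linear regression with the package's AIC convention
#'
#' Convenience wrapper fitting `y ~ x + covariates` with the same Gaussian
#' profiled-variance AIC as the quadratic and fractional-polynomial fits,
#' so all candidate shapes are compared on one scale.
#'
#' @inheritParams fit_quadratic
#' @return list: `beta`, `se`, `aic`, `loglik`, `n`, `k`, `fitted`.
#' @export
fit_linear <- function(x, y, covariates = NULL, data = NULL) {
  covmat <- covariate_matrix(covariates, data)
  keep <- complete.cases(x, y, covmat)
  x <- x[keep]; y <- y[keep]
  covmat <- if (is.null(covmat)) NULL else covmat[keep, , drop = FALSE]
  fit <- .ls_fit(cbind(x = x), y, covmat)
  list(beta = unname(fit$coef["x"]), se = fit$se[2],
       aic = fit$aic, loglik = fit$loglik, n = fit$n, k = fit$k,
       fitted = fit$fitted)
}

#' The fractional-polynomial power set
#' @export
fp_powers <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Fractional-polynomial basis transform
#'
#' For a single power, returns `x^p` (natural log for `p = 0`). For a pair
#' of powers, returns the two-column degree-2 basis; a repeated power
#' `(p, p)` uses the standard convention `(x^p, x^p log x)`.
#'
#' @param x positive numeric vector (after any shift/scale preprocessing).
#' @param p a single power or a length-2 vector of powers from the FP set.
#' @return numeric vector (degree 1) or two-column matrix (degree 2).
#' @export
fp_transform <- function(x, p) {
  if (any(x <= 0))
    stop_mrwell("fractional polynomials need strictly positive x", class = "mrwell_domain_error")
  h <- function(pw) if (pw == 0) log(x) else x^pw
  if (length(p) == 1) return(h(p))
  if (p[1] == p[2]) cbind(h(p[1]), h(p[1]) * log(x))
  else cbind(h(p[1]), h(p[2]))
}

## fit one FP model (degree 1 or 2) on preprocessed x; returns fp_model
.fp_fit <- function(xs, y, p, covmat, scaling) {
  basis <- fp_transform(xs, p)
  fit <- .ls_fit(cbind(basis), y, covmat)
  nterm <- if (length(p) == 1) 1L else 2L
  term_se <- fit$se[1 + seq_len(nterm)]
  term_b <- fit$coef[1 + seq_len(nterm)]
  structure(list(degree = nterm, powers = p,
                 coefficients = unname(term_b), intercept = unname(fit$coef[1]),
                 term_se = unname(term_se),
                 aic = fit$aic, loglik = fit$loglik, n = fit$n, k = fit$k,
                 scaling = scaling, fitted = fit$fitted),
            class = "fp_model")
}

#' @export
print.fp_model <- function(x, ...) {
  cat(sprintf("FP%d model, powers (%s): AIC = %.2f, n = %d\n",
              x$degree, paste(x$powers, collapse = ", "), x$aic, x$n))
  invisible(x)
}

## shared preprocessing: divide by the sample mean so a BMI-like exposure is
## strictly positive and of order 1 before powering
.fp_preprocess <- function(x) {
  sc <- mean(x)
  if (sc <= 0 || any(x <= 0))
    stop_mrwell("exposure must be strictly positive for FP models", class = "mrwell_domain_error")
  list(xs = x / sc, scaling = sc)
}

#' First-degree fractional-polynomial search
#'
#' Fits the eight single-power models with powers from
#' `(-2, -1, -0.5, 0, 0.5, 1, 2, 3)` (0 meaning natural log) to the
#' mean-scaled exposure and returns the minimum-AIC model, with the full
#' AIC table attached as `aic_table`. A fit that fails is skipped with a
#' warning; if every fit fails, an error is raised.
#'
#' @param x,y exposure and outcome.
#' @param covariates covariate specification.
#' @param data optional data.frame for covariate names.
#' @return the best `fp_model` (attribute-free access via `$aic_table`).
#' @export
fp1_search <- function(x, y, covariates = NULL, data = NULL) {
  covmat <- covariate_matrix(covariates, data)
  keep <- complete.cases(x, y, covmat)
  x <- x[keep]; y <- y[keep]
  covmat <- if (is.null(covmat)) NULL else covmat[keep, , drop = FALSE]
  pre <- .fp_preprocess(x)
  fits <- list()
  for (p in fp_powers) {
    f <- tryCatch(.fp_fit(pre$xs, y, p, covmat, pre$scaling),
                  error = function(e) { warning("FP1 power ", p, " failed: ",
                                                conditionMessage(e)); NULL })
    if (!is.null(f)) fits[[length(fits) + 1]] <- f
  }
  if (!length(fits)) stop_mrwell("all FP1 fits failed", class = "mrwell_numerical_error")
  tab <- data.frame(p1 = vapply(fits, function(f) f$powers[1], numeric(1)),
                    aic = vapply(fits, function(f) f$aic, numeric(1)))
  best <- select_by_aic(fits)$best
  best$aic_table <- tab
  best
}

#' Second-degree fractional-polynomial search
#'
#' Fits all 36 power combinations — the 28 unordered distinct pairs plus the
#' 8 repeated powers (which add an `x^p log x` term) — and returns the
#' minimum-AIC model. The pair (1, 2) is exactly a quadratic regression.
#' The chosen model is flagged `collapsible = TRUE` when one of its two
#' terms is statistically indistinguishable from zero (two-sided P > 0.05),
#' i.e. the FP2 effectively reduces to an FP1.
#'
#' @inheritParams fp1_search
#' @return the best `fp_model` with `$aic_table` and `$collapsible`.
#' @export
fp2_search <- function(x, y, covariates = NULL, data = NULL) {
  covmat <- covariate_matrix(covariates, data)
  keep <- complete.cases(x, y, covmat)
  x <- x[keep]; y <- y[keep]
  covmat <- if (is.null(covmat)) NULL else covmat[keep, , drop = FALSE]
  pre <- .fp_preprocess(x)
  combos <- fp2_power_pairs()
  fits <- list()
  for (i in seq_len(nrow(combos))) {
    p <- as.numeric(combos[i, ])
    f <- tryCatch(.fp_fit(pre$xs, y, p, covmat, pre$scaling),
                  error = function(e) { warning("FP2 powers (", p[1], ", ", p[2],
                                                ") failed: ", conditionMessage(e)); NULL })
    if (!is.null(f)) fits[[length(fits) + 1]] <- f
  }
  if (!length(fits)) stop_mrwell("all FP2 fits failed", class = "mrwell_numerical_error")
  tab <- data.frame(p1 = vapply(fits, function(f) f$powers[1], numeric(1)),
                    p2 = vapply(fits, function(f) f$powers[2], numeric(1)),
                    aic = vapply(fits, function(f) f$aic, numeric(1)))
  best <- select_by_aic(fits)$best
  zt <- abs(best$coefficients) / best$term_se
  best$collapsible <- any(2 * pnorm(zt, lower.tail = FALSE) > 0.05)
  best$aic_table <- tab
  best
}

#' All 36 degree-2 power combinations
#' @return data.frame with columns `p1 <= p2`.
#' @export
fp2_power_pairs <- function() {
  pairs <- expand.grid(p1 = fp_powers, p2 = fp_powers)
  pairs <- pairs[pairs$p1 <= pairs$p2, ]
  rownames(pairs) <- NULL
  pairs
}

#' Select the best model by AIC
#'
#' Minimum AIC wins; exact ties are broken toward fewer parameters, then
#' toward lower powers (for FP models). All models must be fitted on the
#' same data (checked via n).
#'
#' @param models list of fitted models each carrying `aic`, `k` (or a
#'   parameter count derivable from coefficients), and `n`.
#' @return list with `best` (the winning model) and `table` (AIC comparison).
#' @export
select_by_aic <- function(models) {
  if (length(models) < 2 && length(models) != 1)
    stop_mrwell("need at least one model", class = "mrwell_config_error")
  ns <- vapply(models, function(m) m$n %||% NA_integer_, numeric(1))
  if (length(unique(ns[!is.na(ns)])) > 1)
    stop_mrwell("models were fitted on differing samples; AIC not comparable",
                class = "mrwell_comparability_error")
  aics <- vapply(models, function(m) m$aic, numeric(1))
  ks <- vapply(models, function(m) m$k %||% (length(m$coefficients) + 1), numeric(1))
  pw <- vapply(models, function(m) sum(m$powers %||% 0), numeric(1))
  ord <- order(aics, ks, pw)
  list(best = models[[ord[1]]],
       table = data.frame(model = seq_along(models), aic = aics, k = ks)[ord, ])
}

#' Control-function non-linear Mendelian randomisation
#'
#' Stage 1 regresses the standardised exposure on the genetic risk score
#' plus covariates and keeps the residuals; stage 2 regresses the outcome on
#' the exposure, its square, the covariates, and the stage-1 residual. The
#' residual term absorbs the unmeasured confounding shared by exposure and
#' outcome, so the stage-2 coefficients on the exposure terms are the causal
#' estimates. The exposure enters in cohort-SD units (centred and scaled),
#' so coefficients read as effect per SD and per SD-squared.
#'
#' Standard errors: because the stage-1 residual is a generated regressor,
#' the default is a nonparametric bootstrap over individuals that re-runs
#' both stages in each resample. `se_method = "naive"` uses the stage-2 OLS
#' standard errors directly — much faster and accurate for the quadratic
#' term in the regimes this package simulates, but not guaranteed in
#' general.
#'
#' @param grs a [grs_result] or numeric instrument vector.
#' @param exposure,outcome numeric vectors.
#' @param covariates covariate specification (used in both stages).
#' @param data optional data.frame for covariate names.
#' @param degree 2 (default) fits linear + quadratic terms; 1 fits the
#'   linear term only (in which case the estimate equals TSLS exactly).
#' @param se_method `"bootstrap"` (default) or `"naive"`.
#' @param n_boot bootstrap replicates (default 500).
#' @param seed seed for the bootstrap resampling.
#' @return object of class `cf_result`: `beta` / `se` (linear term, so the
#'   object drops into [fisher_z_diff()]), `beta_quadratic`, `se_quadratic`,
#'   `p_quadratic`, `rho` / `se_rho` (residual-control coefficient),
#'   `f_statistic` (stage 1), `n`, `n_boot`, `se_method`.
#' @export
control_function <- function(grs, exposure, outcome, covariates = NULL,
                             data = NULL, degree = 2,
                             se_method = c("bootstrap", "naive"),
                             n_boot = 500, seed = 1L) {
  se_method <- match.arg(se_method)
  g <- if (inherits(grs, "grs_result")) grs$grs_s else as.numeric(grs)
  covmat <- covariate_matrix(covariates, data)
  keep <- complete.cases(g, exposure, outcome, covmat)
  g <- g[keep]; x <- exposure[keep]; y <- outcome[keep]
  covmat <- if (is.null(covmat)) NULL else covmat[keep, , drop = FALSE]
  n <- length(x)

  cf_once <- function(idx) {
    gi <- g[idx]; xi <- x[idx]; yi <- y[idx]
    ci <- if (is.null(covmat)) NULL else covmat[idx, , drop = FALSE]
    xs <- (xi - mean(xi)) / sd(xi)
    s1 <- .ls_fit(cbind(g = gi), xs, ci)
    r <- xs - s1$fitted
    terms <- if (degree == 2) cbind(x = xs, x2 = xs^2, r = r)
             else cbind(x = xs, r = r)
    s2 <- .ls_fit(terms, yi, ci)
    list(s1 = s1, s2 = s2)
  }

  full <- cf_once(seq_len(n))
  s2 <- full$s2
  b_lin <- unname(s2$coef["x"]);  se_lin <- s2$se[2]
  if (degree == 2) {
    b_quad <- unname(s2$coef["x2"]); se_quad <- s2$se[3]
    b_rho <- unname(s2$coef["r"]);  se_rho <- s2$se[4]
  } else {
    b_quad <- NA_real_; se_quad <- NA_real_
    b_rho <- unname(s2$coef["r"]); se_rho <- s2$se[3]
  }

  ## stage-1 F for instrument relevance
  xs_all <- (x - mean(x)) / sd(x)
  rss0 <- sum((xs_all - mean(xs_all))^2)
  if (!is.null(covmat)) rss0 <- sum(qr.resid(qr(cbind(1, covmat)), xs_all)^2)
  rss1 <- sum((xs_all - full$s1$fitted)^2)
  f1 <- (rss0 - rss1) / (rss1 / (n - full$s1$k))
  if (f1 < 10) warning(sprintf("weak instrument: stage-1 F = %.2f", f1), call. = FALSE)

  if (se_method == "bootstrap") {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    draws <- matrix(NA_real_, n_boot, if (degree == 2) 3 else 2)
    fails <- 0L
    for (bb in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      est <- tryCatch({
        f <- cf_once(idx)
        if (degree == 2) f$s2$coef[c("x", "x2", "r")] else f$s2$coef[c("x", "r")]
      }, error = function(e) NULL)
      if (is.null(est)) fails <- fails + 1L else draws[bb, ] <- est
    }
    if (fails / n_boot > 0.05)
      stop_mrwell("bootstrap failure rate above 5%", class = "mrwell_numerical_error")
    bse <- apply(draws, 2, sd, na.rm = TRUE)
    se_lin <- bse[1]
    if (degree == 2) { se_quad <- bse[2]; se_rho <- bse[3] } else se_rho <- bse[2]
  }

  p_quad <- if (degree == 2) 2 * pnorm(abs(b_quad / se_quad), lower.tail = FALSE) else NA_real_
  structure(list(beta = b_lin, se = se_lin,
                 beta_quadratic = b_quad, se_quadratic = se_quad,
                 p_quadratic = p_quad,
                 rho = b_rho, se_rho = se_rho,
                 f_statistic = f1, n = n,
                 n_boot = if (se_method == "bootstrap") n_boot else 0L,
                 se_method = se_method),
            class = "cf_result")
}

#' @export
print.cf_result <- function(x, ...) {
  cat(sprintf("control-function fit (n = %d, stage-1 F = %.1f, SEs: %s):\n",
              x$n, x$f_statistic, x$se_method))
  cat(sprintf("  linear    %.4f (SE %.4f)\n", x$beta, x$se))
  if (!is.na(x$beta_quadratic))
    cat(sprintf("  quadratic %.4f (SE %.4f), P = %.3g\n",
                x$beta_quadratic, x$se_quadratic, x$p_quadratic))
  cat(sprintf("  residual  %.4f (SE %.4f)\n", x$rho, x$se_rho))
  invisible(x)
}

#' Compare two control-function quadratic terms across cohorts
#'
#' Applies the Fisher z difference test to the quadratic coefficients of two
#' control-function fits.
#'
#' @param cf1,cf2 `cf_result` objects with quadratic terms and SEs.
#' @return a `diff_test`.
#' @export
compare_nonlinear <- function(cf1, cf2) {
  if (is.na(cf1$beta_quadratic) || is.na(cf2$beta_quadratic))
    stop_mrwell("both fits must carry quadratic terms", class = "mrwell_validation_error")
  fisher_z_diff(list(beta = cf1$beta_quadratic, se = cf1$se_quadratic),
                list(beta = cf2$beta_quadratic, se = cf2$se_quadratic))
}
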