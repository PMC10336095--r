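#' Study orchestration configuration
#'
#' Describes how a cohort is analysed: region-stratified fits pooled by
#' fixed-effects meta-analysis (the design used for a multi-region biobank
#' with region-specific principal components), or a single joint fit (the
#' design for a homogeneous cohort).
#'
#' @param style `"region-stratified-meta"` or `"joint"`.
#' @param outcomes character vector of ordinal outcome columns to analyse.
#' @param covariates character vector of phenotype columns adjusted for in
#'   every model (sex is dropped automatically inside sex strata).
#' @param n_pcs principal components used for weight estimation and as
#'   covariates.
#' @param n_blocks jack-knife blocks for internal weight estimation.
#' @param weights optional [variant_weights] (e.g. external GWAS weights);
#'   when `NULL`, weights are block-jack-knifed from the data.
#' @param exclude_regions region labels dropped before analysis (sensitivity
#'   analyses).
#' @param min_stratum_n strata smaller than this are skipped with a logged
#'   warning and excluded from the meta-analysis (default 50).
#' @param do_fp,do_cf run the fractional-polynomial screen and the
#'   control-function non-linear MR branch.
#' @param cf_se_method,cf_boot control-function SE settings.
#' @param seed master seed (block partition, bootstrap).
#' @return object of class `study_config`.
#' @export
study_config <- function(style = c("region-stratified-meta", "joint"),
                         outcomes = "health_satisfaction",
                         covariates = "age",
                         n_pcs = 12, n_blocks = 100, weights = NULL,
                         exclude_regions = NULL, min_stratum_n = 50,
                         do_fp = FALSE, do_cf = FALSE,
                         cf_se_method = "bootstrap", cf_boot = 500,
                         seed = 1L) {
  structure(list(style = match.arg(style), outcomes = outcomes,
                 covariates = covariates, n_pcs = n_pcs, n_blocks = n_blocks,
                 weights = weights, exclude_regions = exclude_regions,
                 min_stratum_n = min_stratum_n, do_fp = do_fp, do_cf = do_cf,
                 cf_se_method = cf_se_method, cf_boot = cf_boot,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' Flat key-value YAML mirroring the arguments of [study_config()]; keys not
#' present fall back to the defaults.
#'
#' @param path YAML file path.
#' @return a [study_config].
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop_mrwell("file not found: ", path, class = "mrwell_io_error")
  vals <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop_mrwell("unknown config key(s): ", paste(bad, collapse = ", "),
                class = "mrwell_config_error")
  do.call(study_config, vals)
}

#' Drop regions from a phenotype table
#'
#' Used for sensitivity analyses that exclude a region (for instance one
#' where the lowest outcome category is too sparse to inform the model).
#'
#' @param pheno phenotype data.frame with a `region` column.
#' @param regions labels to drop (must exist).
#' @return filtered data.frame; dropped counts in attribute `excluded_n`.
#' @export
exclude_regions <- function(pheno, regions) {
  missing_r <- setdiff(regions, unique(pheno$region))
  if (length(missing_r))
    stop_mrwell("region label(s) not present: ", paste(missing_r, collapse = ", "),
                class = "mrwell_config_error")
  drop <- pheno$region %in% regions
  if (all(drop)) stop_mrwell("excluding all regions leaves an empty cohort",
                             class = "mrwell_validation_error")
  out <- pheno[!drop, , drop = FALSE]
  attr(out, "excluded_n") <- sum(drop)
  message(sum(drop), " individuals excluded from region(s): ",
          paste(regions, collapse = ", "))
  out
}

#' Flag regions with sparse outcome categories
#'
#' For each region, checks whether any outcome category's prevalence falls
#' strictly below `threshold` (so a threshold of 0 never flags). Flagged
#' regions are reported for reviewer attention; nothing is auto-excluded.
#'
#' @param pheno phenotype data.frame with `region`.
#' @param outcome ordinal outcome vector aligned to `pheno` (or the name of
#'   a column).
#' @param threshold prevalence threshold (default 0.01).
#' @return data.frame: region, smallest category prevalence, flagged.
#' @export
prevalence_screen <- function(pheno, outcome, threshold = 0.01) {
  if (is.character(outcome) && length(outcome) == 1) outcome <- pheno[[outcome]]
  levels_all <- sort(unique(outcome[!is.na(outcome)]))
  regions <- sort(unique(pheno$region))
  rows <- lapply(regions, function(r) {
    v <- outcome[pheno$region == r]
    v <- v[!is.na(v)]
    prev <- vapply(levels_all, function(l) mean(v == l), numeric(1))
    data.frame(region = r, min_prevalence = min(prev),
               flagged = min(prev) < threshold, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## fit observational + TSLS estimates on one subset of the cohort
.fit_stratum <- function(grs_score, pheno, outcome_col, covariates, idx,
                         sex_label, region_label) {
  sub <- pheno[idx, , drop = FALSE]
  covs <- setdiff(covariates, if (sex_label %in% c("male", "female")) "sex" else character())
  covs <- covs[vapply(covs, function(cc) length(unique(sub[[cc]])) > 1, logical(1))]
  if (!length(covs)) covs <- NULL
  obs <- observational_fit(sub$bmi, sub[[outcome_col]], covariates = covs, data = sub,
                           sex = sex_label, region = region_label)
  gen <- suppressWarnings(
    tsls_fit(grs_score[idx], sub$bmi, sub[[outcome_col]], covariates = covs,
             data = sub, sex = sex_label, region = region_label))
  list(observational = obs, tsls = gen)
}

#' Run the full study design on one cohort
#'
#' Filters variants, orients alleles to the trait-increasing allele, builds
#' the (jack-knifed or externally weighted) genetic risk score, then fits
#' observational and two-stage least-squares models according to the
#' configured design. For the region-stratified style every (sex x region)
#' stratum is fitted and pooled by fixed-effects meta-analysis into
#' all / male / female / urban / rural summaries with I-squared
#' heterogeneity; for the joint style those summaries are fitted directly.
#' Optional branches run the fractional-polynomial non-linearity screen and
#' the control-function non-linear MR.
#'
#' @param config a [study_config].
#' @param geno a [genotype_matrix], rows aligned to `pheno` by id.
#' @param pheno phenotype data.frame.
#' @return object of class `study_report`: `estimates` (per-stratum table),
#'   `meta` (pooled summaries with Q, I2), `fp`, `cf`, `instrument`,
#'   `skipped` (strata below the size floor), and `provenance`.
#' @export
run_study <- function(config, geno, pheno) {
  stopifnot(inherits(config, "study_config"))
  if (!identical(rownames(geno$dosage), as.character(pheno$id)))
    stop_mrwell("genotype rows and phenotype ids must align", class = "mrwell_validation_error")
  if (!is.null(config$exclude_regions)) {
    pheno <- exclude_regions(pheno, config$exclude_regions)
    keep_ids <- as.character(pheno$id)
    geno <- genotype_matrix(geno$dosage[keep_ids, , drop = FALSE],
                            geno$effect_allele, geno$other_allele,
                            geno$multiallelic, geno$drawn_freq)
  }
  geno <- maf_filter(geno)
  aligned <- align_effect_alleles(geno, pheno)
  weights <- config$weights %||%
    jackknife_weights(aligned$geno, pheno, n_blocks = config$n_blocks,
                      n_pcs = config$n_pcs, seed = derive_seed(config$seed, 11))
  grs <- compute_grs(aligned$geno, weights)
  pc_cols <- grep("^pc[0-9]+$", names(pheno), value = TRUE)
  pc_use <- head(pc_cols, config$n_pcs)
  covariates <- unique(c(config$covariates, pc_use))
  instrument <- lapply(setNames(nm = c("male", "female")), function(s)
    instrument_strength(grs, pheno, covariates = setdiff(covariates, "sex"), sex = s))

  estimates <- list(); metas <- list(); skipped <- list()
  fp <- list(); cf <- list()
  for (oc in config$outcomes) {
    if (config$style == "region-stratified-meta") {
      strata <- expand.grid(sex = c("male", "female"),
                            region = sort(unique(pheno$region)),
                            stringsAsFactors = FALSE)
      fits <- list()
      for (i in seq_len(nrow(strata))) {
        s <- strata$sex[i]; r <- strata$region[i]
        idx <- which(pheno$sex == s & pheno$region == r &
                       !is.na(pheno$bmi) & !is.na(pheno[[oc]]))
        if (length(idx) < config$min_stratum_n) {
          skipped[[length(skipped) + 1]] <- data.frame(outcome = oc, sex = s,
                                                       region = r, n = length(idx))
          next
        }
        fits[[paste(s, r)]] <- .fit_stratum(grs$grs_s, pheno, oc, covariates,
                                            idx, s, r)
      }
      if (!length(fits))
        stop_mrwell("no stratum meets the minimum size for outcome ", oc,
                    class = "mrwell_validation_error")
      sex_of <- vapply(fits, function(f) f$tsls$sex, character(1))
      region_of <- vapply(fits, function(f) f$tsls$region, character(1))
      urban_of <- vapply(region_of, function(r) pheno$urban[match(r, pheno$region)],
                         logical(1))
      pool <- function(sel, label_sex, label_region, model) {
        ests <- lapply(fits[sel], `[[`, model)
        if (!length(ests)) return(NULL)
        m <- meta_fixed(ests)
        data.frame(outcome = oc, model = model, sex = label_sex,
                   region = label_region, beta = m$beta, se = m$se, p = m$p,
                   q = m$q, df = m$df, i_squared = m$i_squared,
                   p_heterogeneity = m$p_heterogeneity, k = m$k, n = m$n)
      }
      for (model in c("observational", "tsls")) {
        metas[[length(metas) + 1]] <- pool(rep(TRUE, length(fits)), "all", "both", model)
        metas[[length(metas) + 1]] <- pool(sex_of == "male", "male", "both", model)
        metas[[length(metas) + 1]] <- pool(sex_of == "female", "female", "both", model)
        metas[[length(metas) + 1]] <- pool(urban_of, "all", "urban", model)
        metas[[length(metas) + 1]] <- pool(!urban_of, "all", "rural", model)
      }
      estimates[[oc]] <- as_estimate_table(unlist(lapply(fits, unname), recursive = FALSE))
      estimates[[oc]]$outcome <- oc
    } else {
      subsets <- list(
        list(sex = "all", region = "both", idx = seq_len(nrow(pheno))),
        list(sex = "male", region = "both", idx = which(pheno$sex == "male")),
        list(sex = "female", region = "both", idx = which(pheno$sex == "female")),
        list(sex = "all", region = "urban", idx = which(pheno$urban)),
        list(sex = "all", region = "rural", idx = which(!pheno$urban))
      )
      fits <- list()
      for (sb in subsets) {
        idx <- intersect(sb$idx, which(!is.na(pheno$bmi) & !is.na(pheno[[oc]])))
        if (length(idx) < config$min_stratum_n) {
          skipped[[length(skipped) + 1]] <- data.frame(outcome = oc, sex = sb$sex,
                                                       region = sb$region, n = length(idx))
          next
        }
        fits[[paste(sb$sex, sb$region)]] <-
          .fit_stratum(grs$grs_s, pheno, oc, covariates, idx, sb$sex, sb$region)
      }
      if (!length(fits))
        stop_mrwell("no stratum meets the minimum size for outcome ", oc,
                    class = "mrwell_validation_error")
      estimates[[oc]] <- as_estimate_table(unlist(lapply(fits, unname), recursive = FALSE))
      estimates[[oc]]$outcome <- oc
    }
    if (isTRUE(config$do_fp)) {
      keep <- !is.na(pheno$bmi) & !is.na(pheno[[oc]])
      fp[[oc]] <- list(
        linear = fit_linear(pheno$bmi[keep], pheno[[oc]][keep]),
        quadratic = fit_quadratic(pheno$bmi[keep], pheno[[oc]][keep]),
        fp1 = fp1_search(pheno$bmi[keep], pheno[[oc]][keep]),
        fp2 = fp2_search(pheno$bmi[keep], pheno[[oc]][keep])
      )
    }
    if (isTRUE(config$do_cf)) {
      cf[[oc]] <- control_function(grs, pheno$bmi, pheno[[oc]],
                                   covariates = setdiff(covariates, "sex"),
                                   data = pheno,
                                   se_method = config$cf_se_method,
                                   n_boot = config$cf_boot,
                                   seed = derive_seed(config$seed, 13))
    }
  }
  meta_df <- if (length(metas)) do.call(rbind, metas[!vapply(metas, is.null, logical(1))]) else NULL
  structure(list(
    estimates = do.call(rbind, unname(estimates)),
    meta = meta_df,
    fp = fp, cf = cf, instrument = instrument,
    skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
    provenance = list(config_hash = config_hash(unclass(config)),
                      seed = config$seed,
                      n_individuals = nrow(pheno),
                      n_variants = ncol(geno$dosage),
                      version = as.character(utils::packageVersion("mrwell")))),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report:", x$provenance$n_individuals, "individuals,",
      x$provenance$n_variants, "variants\n")
  if (!is.null(x$meta)) {
    cat("pooled genetic estimates:\n")
    print(x$meta[x$meta$model == "tsls",
                 c("outcome", "sex", "region", "beta", "se", "i_squared")],
          row.names = FALSE)
  }
  invisible(x)
}

## pull a summary (meta or joint) estimate for one stratum out of a report
.report_estimate <- function(report, outcome, sex, region, model = "tsls") {
  if (!is.null(report$meta)) {
    row <- report$meta[report$meta$outcome == outcome & report$meta$model == model &
                         report$meta$sex == sex & report$meta$region == region, ]
    if (nrow(row)) return(list(beta = row$beta[1], se = row$se[1]))
  }
  est <- report$estimates
  row <- est[est$outcome == outcome & est$model == model &
               est$sex == sex & est$region == region, ]
  if (nrow(row)) return(list(beta = row$beta[1], se = row$se[1]))
  NULL
}

#' Compare two cohort reports stratum-by-stratum
#'
#' Applies the Fisher z difference test to the genetic (TSLS) summary
#' estimates of matching strata in two study reports, and, when both
#' reports carry control-function fits, to the quadratic terms.
#'
#' @param report_a,report_b `study_report` objects.
#' @param strata data.frame with columns `sex` and `region` (default: the
#'   all/male/female/urban/rural summaries).
#' @return data.frame of comparisons (z, two-sided P, the compared betas);
#'   strata missing on either side are skipped with a warning.
#' @export
compare_cohorts <- function(report_a, report_b,
                            strata = data.frame(
                              sex = c("all", "male", "female", "all", "all"),
                              region = c("both", "both", "both", "urban", "rural"))) {
  outcomes <- intersect(unique(report_a$estimates$outcome),
                        unique(report_b$estimates$outcome))
  rows <- list()
  for (oc in outcomes) {
    for (i in seq_len(nrow(strata))) {
      s <- strata$sex[i]; r <- strata$region[i]
      ea <- .report_estimate(report_a, oc, s, r)
      eb <- .report_estimate(report_b, oc, s, r)
      if (is.null(ea) || is.null(eb)) {
        warning("stratum (", s, ", ", r, ") missing on one side; skipped")
        next
      }
      d <- fisher_z_diff(ea, eb)
      rows[[length(rows) + 1]] <- data.frame(
        outcome = oc, sex = s, region = r, test = "tsls",
        beta_a = ea$beta, beta_b = eb$beta, z = d$z, p = d$p,
        log10_p = d$log10_p)
    }
    if (!is.null(report_a$cf[[oc]]) && !is.null(report_b$cf[[oc]])) {
      d <- compare_nonlinear(report_a$cf[[oc]], report_b$cf[[oc]])
      rows[[length(rows) + 1]] <- data.frame(
        outcome = oc, sex = "all", region = "both", test = "cf_quadratic",
        beta_a = report_a$cf[[oc]]$beta_quadratic,
        beta_b = report_b$cf[[oc]]$beta_quadratic,
        z = d$z, p = d$p, log10_p = d$log10_p)
    }
  }
  do.call(rbind, rows)
}

#' Fisher z comparison from printed betas and confidence intervals
#'
#' Published stratum estimates are usually printed as a beta with a 95%
#' confidence interval. This helper back-calculates the standard errors via
#' [ci_to_se()] and applies [fisher_z_diff()], so two cohorts can be
#' compared from printed values alone, without individual-level data.
#'
#' @param beta1,lcl1,ucl1 first estimate and its CI bounds.
#' @param beta2,lcl2,ucl2 second estimate and its CI bounds.
#' @param level confidence level of the printed intervals (default 0.95).
#' @return a `diff_test`.
#' @export
compare_printed <- function(beta1, lcl1, ucl1, beta2, lcl2, ucl2, level = 0.95) {
  fisher_z_diff(list(beta = beta1, se = ci_to_se(lcl1, ucl1, level)),
                list(beta = beta2, se = ci_to_se(lcl2, ucl2, level)))
}

#' Published cohort estimates bundled with the package
#'
#' Returns the published observational and genetic (one-sample MR) effect
#' estimates of BMI on well-being, per SD higher BMI, for the East-Asian
#' (CKB) and European (UKB) ancestry cohorts, stratified by sex and
#' urban/rural region, as printed betas with 95% CIs. The back-calculated
#' standard error (`se`) is added via [ci_to_se()]. These tables exist so
#' that cross-cohort Fisher z comparisons can be reproduced without any
#' restricted individual-level data.
#'
#' @param outcome `"health_satisfaction"` or `"life_satisfaction"`.
#' @return data.frame: study, sex, region, model, beta, lcl, ucl, se.
#' @export
printed_estimates <- function(outcome = c("health_satisfaction", "life_satisfaction")) {
  outcome <- match.arg(outcome)
  fname <- c(health_satisfaction = "published_estimates_health_satisfaction.tsv",
             life_satisfaction = "published_estimates_life_satisfaction.tsv")[[outcome]]
  path <- system.file("extdata", fname, package = "mrwell", mustWork = TRUE)
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  df$se <- ci_to_se(df$lcl, df$ucl)
  df
}
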