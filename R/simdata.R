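#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the generative model behind the simulated biobank
#' cohort. The defaults describe a CKB-like East-Asian cohort: ten
#' recruitment regions, 57% female, 44% urban, 28% of individuals flagged as
#' related, a four-level health-satisfaction outcome with marginal
#' prevalences (Poor 11.6%, Fair 44.3%, Good 27.0%, Excellent 17.1%), and a
#' BMI-like exposure with mean 23.7 kg/m2 and standard deviation close to
#' 3.5 kg/m2 of which the genetic score explains roughly 3% of the variance.
#'
#' The generative model is
#' \deqn{x = \mu + \sum_i \beta_{g,i} d_i + c_x U + \epsilon_x}
#' \deqn{y^* = \beta_1 x_{sd} + \beta_2 x_{sd}^2 + c_y U + \epsilon_y}
#' where \eqn{U} is a standard-normal confounder shared by exposure and
#' outcome, \eqn{x_{sd}} is the exposure in cohort-SD units (centred and
#' scaled within the generated cohort), and the ordinal outcome is obtained
#' by cutting the latent \eqn{y^*} at empirical quantiles matching
#' `category_probs`.
#'
#' @param n_individuals number of individuals.
#' @param n_variants number of biallelic variants.
#' @param maf_range length-2 numeric in (0, 0.5]; per-variant allele
#'   frequencies are drawn uniformly in this range.
#' @param beta_g per-variant effect of one effect allele on the exposure, in
#'   exposure measurement units (kg/m2 for the BMI-like default). Recycled
#'   to `n_variants`.
#' @param beta_linear causal effect of the exposure on the latent outcome per
#'   cohort-SD of exposure.
#' @param beta_quadratic causal coefficient on squared standardised exposure.
#' @param confounder_strength_x,confounder_strength_y loadings of the shared
#'   standard-normal confounder on exposure and latent outcome.
#' @param noise_sd_x,noise_sd_y residual standard deviations (must be > 0).
#' @param exposure_mean location of the exposure (kg/m2 scale by default).
#' @param n_regions number of recruitment regions.
#' @param region_multipliers optional numeric vector of length `n_regions`;
#'   region-specific multipliers on `beta_linear`, used to inject effect
#'   heterogeneity across regions (default: all 1, homogeneous).
#' @param urban_fraction,female_fraction,related_fraction label proportions.
#'   The urban flag is carried by whole recruitment regions (the first
#'   `round(urban_fraction * n_regions)` regions are urban and individuals
#'   inherit the label), matching a design where urban/rural summaries pool
#'   entire regions.
#' @param n_categories number of ordinal outcome levels (4 for
#'   satisfaction-type scales, 6 for the happiness scale).
#' @param category_probs marginal category proportions, summing to 1, lowest
#'   category first.
#' @param n_pcs number of principal-component columns to simulate (iid
#'   standard normal, independent of genotypes by construction).
#' @param outcome_name column name for the ordinal outcome.
#' @param seed integer seed; all randomness is keyed to it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 20000,
                       n_variants = 20,
                       maf_range = c(0.05, 0.45),
                       beta_g = 0.24,
                       beta_linear = -0.18,
                       beta_quadratic = 0,
                       confounder_strength_x = 2.4,
                       confounder_strength_y = 0.5,
                       noise_sd_x = 2.4,
                       noise_sd_y = 1,
                       exposure_mean = 23.7,
                       n_regions = 10,
                       region_multipliers = NULL,
                       urban_fraction = 0.44,
                       female_fraction = 0.57,
                       related_fraction = 0.28,
                       n_categories = 4,
                       category_probs = c(0.116, 0.443, 0.270, 0.171),
                       n_pcs = 12,
                       outcome_name = "health_satisfaction",
                       seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals), n_variants = as.integer(n_variants),
    maf_range = as.numeric(maf_range),
    beta_g = rep_len(as.numeric(beta_g), n_variants),
    beta_linear = beta_linear, beta_quadratic = beta_quadratic,
    confounder_strength_x = confounder_strength_x,
    confounder_strength_y = confounder_strength_y,
    noise_sd_x = noise_sd_x, noise_sd_y = noise_sd_y,
    exposure_mean = exposure_mean,
    n_regions = as.integer(n_regions),
    region_multipliers = region_multipliers %||% rep(1, n_regions),
    urban_fraction = urban_fraction, female_fraction = female_fraction,
    related_fraction = related_fraction,
    n_categories = as.integer(n_categories),
    category_probs = as.numeric(category_probs),
    n_pcs = as.integer(n_pcs),
    outcome_name = outcome_name,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_individuals < 1L || n_variants < 1L)
      stop_mrwell("n_individuals and n_variants must be >= 1", class = "mrwell_config_error")
    if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
        maf_range[1] > maf_range[2])
      stop_mrwell("maf_range must be an increasing pair within (0, 0.5]", class = "mrwell_config_error")
    if (abs(sum(category_probs) - 1) > 1e-8)
      stop_mrwell("category_probs must sum to 1", class = "mrwell_config_error")
    if (length(category_probs) != n_categories)
      stop_mrwell("category_probs must have n_categories entries", class = "mrwell_config_error")
    if (n_categories < 2L)
      stop_mrwell("n_categories must be >= 2", class = "mrwell_config_error")
    if (noise_sd_x <= 0 || noise_sd_y <= 0)
      stop_mrwell("noise SDs must be > 0", class = "mrwell_config_error")
    if (length(region_multipliers) != n_regions)
      stop_mrwell("region_multipliers must have n_regions entries", class = "mrwell_config_error")
    for (p in c(urban_fraction, female_fraction, related_fraction))
      if (p < 0 || p > 1) stop_mrwell("fractions must lie in [0, 1]", class = "mrwell_config_error")
  })
  invisible(cfg)
}

#' Simulate a biallelic dosage matrix
#'
#' Each variant is assigned an allele frequency drawn uniformly from
#' `maf_range`; dosages are two-trial binomial draws at that frequency
#' (Hardy-Weinberg, no linkage disequilibrium). The empirical MAF of each
#' simulated variant is recorded on the returned object.
#'
#' @param n_individuals,n_variants dimensions.
#' @param maf_range length-2 numeric in (0, 0.5].
#' @param seed integer seed; output is deterministic given the seed.
#' @return a [genotype_matrix] object.
#' @export
simulate_genotypes <- function(n_individuals, n_variants, maf_range = c(0.05, 0.45),
                               seed = 1L) {
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop_mrwell("maf_range must be an increasing pair within (0, 0.5]", class = "mrwell_config_error")
  if (n_individuals < 1 || n_variants < 1)
    stop_mrwell("n_individuals and n_variants must be >= 1", class = "mrwell_config_error")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  freq <- runif(n_variants, maf_range[1], maf_range[2])
  dosage <- matrix(rbinom(n_individuals * n_variants, 2L, rep(freq, each = n_individuals)),
                  nrow = n_individuals, ncol = n_variants)
  rownames(dosage) <- sprintf("id%06d", seq_len(n_individuals))
  colnames(dosage) <- sprintf("rs%04d", seq_len(n_variants))
  genotype_matrix(dosage,
                  effect_allele = rep("A", n_variants),
                  other_allele = rep("G", n_variants),
                  drawn_freq = freq)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Discretise a latent outcome into ordinal categories
#'
#' Cutpoints are placed at empirical quantiles (order statistics, quantile
#' type 1) of the latent vector at the cumulative `category_probs`, so the
#' configured marginal prevalences are honoured at any noise level and the
#' mapping is invariant to monotone relabelling of the latent values.
#' Categories are coded `0 .. K-1`, lowest latent values mapping to 0.
#'
#' @param latent numeric vector (NA allowed; NA stays NA).
#' @param category_probs marginal proportions summing to 1.
#' @return list with `ordinal` (integer vector) and `cutpoints` (the K-1
#'   thresholds used; the category of a value is the number of cutpoints it
#'   strictly exceeds).
#' @export
latent_to_ordinal <- function(latent, category_probs) {
  if (abs(sum(category_probs) - 1) > 1e-8)
    stop_mrwell("category_probs must sum to 1", class = "mrwell_config_error")
  k <- length(category_probs)
  ok <- !is.na(latent)
  if (length(unique(latent[ok])) < k)
    stop_mrwell("fewer distinct latent values than categories", class = "mrwell_degeneracy_error")
  cuts <- quantile(latent[ok], probs = cumsum(category_probs)[-k], type = 1, names = FALSE)
  ordinal <- rep(NA_integer_, length(latent))
  ## category = number of cutpoints strictly below the value
  ordinal[ok] <- vapply(latent[ok], function(v) sum(v > cuts), integer(1))
  list(ordinal = ordinal, cutpoints = cuts)
}

#' Simulate a full cohort with known causal ground truth
#'
#' Generates genotypes, a BMI-like exposure driven by the variant score plus
#' a shared unobserved confounder, a latent well-being outcome that is a
#' linear or quadratic function of the standardised exposure plus the same
#' confounder, the ordinal outcome obtained by quantile discretisation, and
#' demographic labels (sex, region, urban flag, relatedness flag, simulated
#' principal components). Region-specific multipliers on the linear causal
#' effect allow heterogeneity across strata to be injected.
#'
#' @param config a [sim_config] object.
#' @return list with elements `genotypes` ([genotype_matrix]), `phenotypes`
#'   (data.frame: id, sex, age, region, urban, related, pc1.., bmi, latent
#'   outcome and the ordinal outcome column), and `truth` (the parameters
#'   exactly as used: per-variant `beta_g`, `beta_linear`, `beta_quadratic`,
#'   region multipliers, discretisation `cutpoints`, the confounder vector
#'   `confounder`, and the exposure centring/scale used for `x_sd`).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  n <- config$n_individuals
  geno <- simulate_genotypes(n, config$n_variants, config$maf_range,
                             seed = derive_seed(config$seed, 1))
  set.seed(derive_seed(config$seed, 2))

  u <- rnorm(n)
  score <- drop(geno$dosage %*% config$beta_g)
  bmi <- config$exposure_mean + score + config$confounder_strength_x * u +
    rnorm(n, 0, config$noise_sd_x)
  x_centre <- mean(bmi)
  x_scale <- sd(bmi)
  x_sd <- (bmi - x_centre) / x_scale

  sex <- ifelse(runif(n) < config$female_fraction, "female", "male")
  region_idx <- sample.int(config$n_regions, n, replace = TRUE)
  region <- sprintf("region%02d", region_idx)
  ## recruitment regions are themselves urban or rural; individuals inherit
  ## the label, so urban/rural summaries are unions of whole regions
  n_urban_regions <- round(config$urban_fraction * config$n_regions)
  urban <- region_idx <= n_urban_regions
  related <- runif(n) < config$related_fraction
  age <- pmin(pmax(round(rnorm(n, 53.7, 11)), 30), 79)
  pcs <- matrix(rnorm(n * config$n_pcs), n, config$n_pcs,
                dimnames = list(NULL, paste0("pc", seq_len(config$n_pcs))))

  mult <- config$region_multipliers[region_idx]
  latent <- config$beta_linear * mult * x_sd +
    config$beta_quadratic * x_sd^2 +
    config$confounder_strength_y * u +
    rnorm(n, 0, config$noise_sd_y)
  disc <- latent_to_ordinal(latent, config$category_probs)

  pheno <- data.frame(
    id = rownames(geno$dosage), sex = sex, age = age, region = region,
    urban = urban, related = related, stringsAsFactors = FALSE
  )
  pheno <- cbind(pheno, as.data.frame(pcs))
  pheno$bmi <- bmi
  pheno$wellbeing_latent <- latent
  pheno[[config$outcome_name]] <- disc$ordinal

  truth <- list(
    beta_g = config$beta_g,
    beta_linear = config$beta_linear,
    beta_quadratic = config$beta_quadratic,
    region_multipliers = config$region_multipliers,
    cutpoints = disc$cutpoints,
    confounder = u,
    exposure_centre = x_centre,
    exposure_scale = x_scale
  )
  list(genotypes = geno, phenotypes = pheno, truth = truth)
}

#' Write a simulated cohort to plain-text fixtures
#'
#' Writes the dosage matrix (individuals in rows) and the phenotype table as
#' tab-delimited files and the ground-truth parameters as JSON.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genotypes = file.path(dir, "dosages.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_dosage_matrix(cohort$genotypes, paths[["genotypes"]])
  data.table::fwrite(cohort$phenotypes, paths[["phenotypes"]], sep = "\t", na = "NA")
  truth <- cohort$truth
  truth$confounder <- NULL  # per-individual vector, not a parameter
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
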