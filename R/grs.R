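#' Rank-based inverse normal transformation
#'
#' Blom-offset RINT: values are replaced by standard-normal quantiles at
#' `(rank - 3/8) / (n + 1/4)`, using average ranks for ties. Missing values
#' stay missing and do not enter the ranking.
#'
#' @param values numeric vector with at least two distinct non-missing values.
#' @return numeric vector of the same length.
#' @export
rint <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2)
    stop_mrwell("need at least two non-missing values", class = "mrwell_degeneracy_error")
  if (length(unique(values[ok])) < 2)
    stop_mrwell("all values identical: RINT undefined", class = "mrwell_degeneracy_error")
  n <- sum(ok)
  r <- rank(values[ok], ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- qnorm((r - 3/8) / (n + 1/4))
  out
}

#' Per-variant, per-sex weight container
#'
#' Holds oriented per-variant effect sizes. For jack-knifed weights the
#' per-block coefficient matrix and each individual's block assignment are
#' carried so that [compute_grs()] can resolve the weight vector that was
#' estimated *without* that individual. Block id 0 denotes the
#' full-unrelated-sample weights (assigned to related individuals under the
#' split-sample rule).
#'
#' @param variant_id character vector.
#' @param beta numeric matrix of weights: one row for a single shared weight
#'   vector, or (for jack-knifed weights) rows indexed by block id 0..B.
#' @param effect_allele,other_allele allele labels after orientation.
#' @param source `"external"`, `"internal"` or `"jackknife"`.
#' @param block_id optional integer vector (one per individual, named by id):
#'   which row of `beta` (block id + 1) applies to that individual.
#' @param flipped logical per variant: whether the coded allele was swapped
#'   during orientation.
#' @return object of class `variant_weights`.
#' @export
variant_weights <- function(variant_id, beta, effect_allele = NULL,
                            other_allele = NULL,
                            source = c("external", "internal", "jackknife"),
                            block_id = NULL, flipped = NULL) {
  source <- match.arg(source)
  beta <- rbind(beta)
  colnames(beta) <- variant_id
  if (any(!is.finite(beta)))
    stop_mrwell("weights must be finite", class = "mrwell_validation_error")
  structure(list(variant_id = variant_id, beta = beta,
                 effect_allele = effect_allele, other_allele = other_allele,
                 source = source, block_id = block_id, flipped = flipped),
            class = "variant_weights")
}

#' Exclude rare and multiallelic variants
#'
#' Removes variants whose minor-allele frequency is strictly below
#' `threshold` (a variant at exactly the threshold is retained) and variants
#' flagged multiallelic.
#'
#' @param geno a [genotype_matrix].
#' @param threshold MAF threshold (default 0.01).
#' @return filtered [genotype_matrix] with a `removed` attribute listing the
#'   dropped variant ids.
#' @export
maf_filter <- function(geno, threshold = 0.01) {
  drop <- geno$maf < threshold | geno$multiallelic
  if (all(drop))
    stop_mrwell("all variants removed by MAF/multiallelic filter",
                class = "mrwell_empty_instrument_error")
  removed <- geno$variant_id[drop]
  out <- genotype_matrix(geno$dosage[, !drop, drop = FALSE],
                         effect_allele = geno$effect_allele[!drop],
                         other_allele = geno$other_allele[!drop],
                         multiallelic = geno$multiallelic[!drop],
                         drawn_freq = geno$drawn_freq[!drop])
  attr(out, "removed") <- removed
  out
}

## joint (or per-variant) regression of a response on all variant dosages
## plus optional covariate columns; returns the variant coefficients
.variant_regression <- function(dosage, response, covmat = NULL,
                                mode = c("joint", "per_variant")) {
  mode <- match.arg(mode)
  if (mode == "joint") {
    X <- cbind(`(Intercept)` = 1, dosage, covmat)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
      stop_mrwell("rank-deficient joint variant regression; consider pruning variants",
                  class = "mrwell_numerical_error")
    b <- qr.coef(qrX, response)
    b[colnames(dosage)]
  } else {
    vapply(seq_len(ncol(dosage)), function(j) {
      X <- cbind(1, dosage[, j], covmat)
      qr.coef(qr(X), response)[2]
    }, numeric(1))
  }
}

#' Orient variants to the trait-increasing allele
#'
#' Per sex, rank-inverse-normal-transformed BMI is regressed jointly on all
#' variant dosages; each variant is then coded so its effect allele is the
#' trait-increasing allele. When the estimated sign differs between the
#' sexes, the orientation follows the sex with the larger absolute effect.
#' Flipping replaces the dosage by `2 - d` and swaps the allele labels.
#'
#' @param geno a [genotype_matrix].
#' @param pheno phenotype data.frame with `sex` ("male"/"female") and
#'   `bmi` columns, rows aligned to `geno`.
#' @param mode `"joint"` (default) or `"per_variant"` regression.
#' @return list with `geno` (oriented [genotype_matrix]) and `orientation`
#'   (data.frame: variant, per-sex effects on the original coding, flipped).
#' @export
align_effect_alleles <- function(geno, pheno, mode = c("joint", "per_variant")) {
  mode <- match.arg(mode)
  stopifnot(nrow(geno$dosage) == nrow(pheno))
  if (length(unique(pheno$sex[!is.na(pheno$bmi)])) < 2)
    stop_mrwell("both sexes must be present for allele orientation",
                class = "mrwell_validation_error")
  per_sex <- lapply(c(male = "male", female = "female"), function(s) {
    idx <- which(pheno$sex == s & !is.na(pheno$bmi))
    .variant_regression(geno$dosage[idx, , drop = FALSE],
                        rint(pheno$bmi[idx]), mode = mode)
  })
  eff <- cbind(male = per_sex$male, female = per_sex$female)
  ## per variant: pick the sign of the larger-|effect| sex when signs disagree
  lead <- ifelse(abs(eff[, "female"]) >= abs(eff[, "male"]),
                 eff[, "female"], eff[, "male"])
  flip <- lead < 0
  dosage <- geno$dosage
  dosage[, flip] <- 2 - dosage[, flip]
  ea <- geno$effect_allele; oa <- geno$other_allele
  tmp <- ea[flip]; ea[flip] <- oa[flip]; oa[flip] <- tmp
  oriented <- genotype_matrix(dosage, effect_allele = ea, other_allele = oa,
                              multiallelic = geno$multiallelic,
                              drawn_freq = geno$drawn_freq)
  list(geno = oriented,
       orientation = data.frame(variant_id = geno$variant_id,
                                beta_male = eff[, "male"],
                                beta_female = eff[, "female"],
                                flipped = unname(flip),
                                row.names = NULL))
}

#' Estimate per-sex variant weights by multiple regression
#'
#' Regresses (raw) BMI jointly on all oriented variant dosages plus the
#' first `n_pcs` principal-component columns, within one sex, on unrelated
#' individuals. The variant coefficient vector is the weight vector.
#'
#' @param geno oriented [genotype_matrix].
#' @param pheno phenotype data.frame (`bmi`, `sex`, `related`, `pc*` columns).
#' @param n_pcs number of principal components to adjust for.
#' @param sex `"male"`, `"female"` or `"both"`.
#' @param mode `"joint"` (default) or `"per_variant"`.
#' @param unrelated_only restrict to `!related` rows (default TRUE).
#' @return named numeric weight vector (one entry per variant).
#' @export
estimate_weights <- function(geno, pheno, n_pcs = 12,
                             sex = c("both", "male", "female"),
                             mode = c("joint", "per_variant"),
                             unrelated_only = TRUE) {
  sex <- match.arg(sex)
  mode <- match.arg(mode)
  pc_cols <- grep("^pc[0-9]+$", names(pheno), value = TRUE)
  if (n_pcs > length(pc_cols))
    stop_mrwell("n_pcs = ", n_pcs, " exceeds the ", length(pc_cols),
                " available PC columns", class = "mrwell_config_error")
  keep <- !is.na(pheno$bmi)
  if (unrelated_only && "related" %in% names(pheno)) keep <- keep & !pheno$related
  if (sex != "both") keep <- keep & pheno$sex == sex
  idx <- which(keep)
  covmat <- if (n_pcs > 0) as.matrix(pheno[idx, pc_cols[seq_len(n_pcs)], drop = FALSE]) else NULL
  .variant_regression(geno$dosage[idx, , drop = FALSE], pheno$bmi[idx],
                      covmat = covmat, mode = mode)
}

#' Block jack-knife variant weights
#'
#' Splits the unrelated subset into `n_blocks` near-equal blocks by a seeded
#' random permutation. For each block, weights are estimated (per
#' [estimate_weights()]) on all unrelated individuals *outside* the block and
#' assigned to the block's members, so no individual's phenotype informs
#' their own score weights. Related individuals receive the weights estimated
#' on the full unrelated sample (block id 0, the split-sample rule).
#'
#' @param geno oriented [genotype_matrix].
#' @param pheno phenotype data.frame with `related` flag.
#' @param n_blocks number of blocks (default 100).
#' @param n_pcs principal components to adjust for.
#' @param sex stratum passed to [estimate_weights()].
#' @param seed seed for the block permutation.
#' @return a [variant_weights] object with `source = "jackknife"`,
#'   per-block coefficient rows and a per-individual `block_id`.
#' @export
jackknife_weights <- function(geno, pheno, n_blocks = 100, n_pcs = 12,
                              sex = "both", seed = 1L) {
  if (n_blocks < 2)
    stop_mrwell("n_blocks must be >= 2", class = "mrwell_config_error")
  related <- if ("related" %in% names(pheno)) pheno$related else rep(FALSE, nrow(pheno))
  unrel <- which(!related)
  if (length(unrel) < 2 * n_blocks)
    stop_mrwell("unrelated n must be at least 2 * n_blocks", class = "mrwell_config_error")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample(unrel)
  block_of_unrel <- integer(nrow(pheno))
  block_of_unrel[perm] <- rep_len(seq_len(n_blocks), length(unrel))  # near-equal blocks

  m <- ncol(geno$dosage)
  beta <- matrix(NA_real_, n_blocks + 1, m,
                 dimnames = list(NULL, geno$variant_id))
  ## row 1 = block id 0: full unrelated sample (for related individuals)
  beta[1, ] <- estimate_weights(geno, pheno, n_pcs = n_pcs, sex = sex)
  for (b in seq_len(n_blocks)) {
    keep_pheno <- pheno
    ## mark the held-out block as related so estimate_weights drops it
    keep_pheno$related <- related | block_of_unrel == b
    beta[b + 1, ] <- estimate_weights(geno, keep_pheno, n_pcs = n_pcs, sex = sex)
  }
  block_id <- block_of_unrel            # 0 for related individuals
  names(block_id) <- rownames(geno$dosage)
  variant_weights(geno$variant_id, beta,
                  effect_allele = geno$effect_allele,
                  other_allele = geno$other_allele,
                  source = "jackknife", block_id = block_id)
}

#' Weighted and standardised genetic risk scores
#'
#' Computes, per individual, the weighted score
#' \deqn{GRS_w = \sum_i \beta_i d_i}
#' and the standardised score
#' \deqn{GRS_s = n \, GRS_w / \sum_i \beta_i}
#' where n is the number of variants and the weight vector is the one
#' assigned to that individual (jack-knife block, or the single shared
#' vector for external/internal weights).
#'
#' @param geno oriented [genotype_matrix].
#' @param weights a [variant_weights] object, or a bare numeric vector of
#'   per-variant weights (treated as a shared internal weight vector).
#' @return object of class `grs_result`: list with numeric vectors `grs_w`,
#'   `grs_s`, `n_variants`, and `provenance`.
#' @export
compute_grs <- function(geno, weights) {
  if (is.numeric(weights) && is.null(dim(weights)))
    weights <- variant_weights(geno$variant_id, weights, source = "internal")
  if (!all(geno$variant_id %in% colnames(weights$beta)))
    stop_mrwell("weights must cover every retained variant", class = "mrwell_validation_error")
  B <- weights$beta[, geno$variant_id, drop = FALSE]
  n_ind <- nrow(geno$dosage)
  m <- ncol(geno$dosage)
  if (is.null(weights$block_id)) {
    w <- B[1, ]
    sum_beta <- sum(w)
    if (sum_beta == 0)
      stop_mrwell("sum of weights is zero: standardised score undefined",
                  class = "mrwell_standardisation_error")
    grs_w <- drop(geno$dosage %*% w)
    grs_s <- m * grs_w / sum_beta
  } else {
    bid <- weights$block_id[rownames(geno$dosage)]
    W <- B[bid + 1L, , drop = FALSE]        # per-individual weight rows
    sum_beta <- rowSums(W)
    if (any(sum_beta == 0))
      stop_mrwell("sum of weights is zero for some individuals",
                  class = "mrwell_standardisation_error")
    grs_w <- rowSums(geno$dosage * W)
    grs_s <- m * grs_w / sum_beta
  }
  structure(list(grs_w = unname(grs_w), grs_s = unname(grs_s),
                 individual_id = rownames(geno$dosage),
                 n_variants = m, provenance = weights$source),
            class = "grs_result")
}

#' Instrument strength: incremental R-squared and F statistic
#'
#' Compares the covariate-only linear model of BMI with the model adding the
#' standardised GRS, within one sex (or both). Returns the incremental
#' variance explained and the partial F statistic for the single added
#' regressor, which satisfy `F = R2 (n - k - 1) / (1 - R2)` when there are
#' no covariates.
#'
#' @param grs a [grs_result] (or numeric score vector).
#' @param pheno phenotype data.frame with `bmi`.
#' @param covariates covariate specification (see [covariate_matrix()]).
#' @param sex optional stratum filter (`"male"`, `"female"`, `"both"`).
#' @return list (class `instrument_diagnostics`): `r_squared`, `f_statistic`,
#'   `sex`, `n`.
#' @export
instrument_strength <- function(grs, pheno, covariates = NULL, sex = "both") {
  score <- if (inherits(grs, "grs_result")) grs$grs_s else as.numeric(grs)
  keep <- !is.na(pheno$bmi) & !is.na(score)
  if (sex != "both") keep <- keep & pheno$sex == sex
  idx <- which(keep)
  y <- pheno$bmi[idx]
  g <- score[idx]
  covmat <- covariate_matrix(covariates, pheno)
  covmat <- if (is.null(covmat)) NULL else covmat[idx, , drop = FALSE]
  n <- length(idx)
  X0 <- cbind(rep(1, n), covmat)
  X1 <- cbind(X0, g)
  if (n <= ncol(X1) + 1)
    stop_mrwell("too few observations for instrument diagnostics", class = "mrwell_numerical_error")
  rss0 <- sum(qr.resid(qr(X0), y)^2)
  rss1 <- sum(qr.resid(qr(X1), y)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- (rss0 - rss1) / tss
  df2 <- n - ncol(X1)
  f <- (rss0 - rss1) / (rss1 / df2)
  structure(list(r_squared = r2, f_statistic = f, sex = sex, n = n),
            class = "instrument_diagnostics")
}
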