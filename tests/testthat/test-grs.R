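test_that("rank inverse normal transform uses Blom offsets and average ranks", {
  out <- rint(c(5, 1, 9))
  expect_equal(out, c(0, -0.869, 0.869), tolerance = 1e-3)

  x <- c(2.5, -1, 0, 7, 3)
  expect_true(all(diff(rint(sort(x))) > 0))          # strictly rank-preserving

  tied <- rint(c(1, 1, 5, 9))
  expect_equal(tied[1], tied[2])                     # average ranks for ties

  withna <- rint(c(3, NA, 1, 2))
  expect_true(is.na(withna[2]))
  expect_equal(sum(is.na(withna)), 1L)

  expect_error(rint(rep(4, 10)), class = "mrwell_degeneracy_error")
  expect_error(rint(c(1, NA)), class = "mrwell_degeneracy_error")
})

test_that("allele orientation follows the trait-increasing allele, led by the larger-effect sex", {
  set.seed(14)
  n <- 1200
  d <- rbinom(n, 2, 0.4)
  sex <- rep(c("male", "female"), length.out = n)
  # female effect +0.05 dominates male effect -0.02: orientation from females
  bmi <- ifelse(sex == "female", 0.05 * d, -0.02 * d) + rnorm(n, 22, 0.01)
  geno <- genotype_matrix(matrix(d, n, 1, dimnames = list(sprintf("i%04d", 1:n), "v1")),
                          "A", "G")
  al <- align_effect_alleles(geno, data.frame(sex = sex, bmi = bmi))
  expect_false(al$orientation$flipped[1])
  expect_identical(al$geno$dosage, geno$dosage)

  # mirrored case: female -0.05 wins over male +0.02, so the variant flips
  bmi2 <- ifelse(sex == "female", -0.05 * d, 0.02 * d) + rnorm(n, 22, 0.01)
  al2 <- align_effect_alleles(geno, data.frame(sex = sex, bmi = bmi2))
  expect_true(al2$orientation$flipped[1])
  expect_equal(al2$geno$dosage[, 1], 2 - geno$dosage[, 1])
  expect_identical(al2$geno$effect_allele, "G")      # labels swapped
})

test_that("no orientation flips occur when all true effects are positive", {
  co <- quick_cohort(n = 20000, m = 10, seed = 8, beta_g = 0.15,
                     confounder_strength_x = 1, noise_sd_x = 1)
  al <- align_effect_alleles(co$genotypes, co$phenotypes)
  expect_false(any(al$orientation$flipped))
})

test_that("weight estimation reduces to simple regression and recovers the truth", {
  set.seed(3)
  n <- 500
  d <- rbinom(n, 2, 0.3)
  bmi <- 20 + 0.4 * d + rnorm(n)
  geno <- genotype_matrix(matrix(d, n, 1, dimnames = list(sprintf("i%03d", 1:n), "v1")),
                          "A", "G")
  ph <- data.frame(bmi = bmi, sex = "female", related = FALSE)
  w <- estimate_weights(geno, ph, n_pcs = 0)
  expect_equal(unname(w), unname(coef(lm(bmi ~ d))[2]), tolerance = 1e-10)

  # generative recovery: per-allele effect 0.1 at n = 20,000
  co <- quick_cohort(n = 20000, m = 10, seed = 16, beta_g = 0.1,
                     confounder_strength_x = 1, noise_sd_x = 1)
  w2 <- estimate_weights(co$genotypes, co$phenotypes, n_pcs = 0)
  se_approx <- sqrt(2 / (2 * 0.25 * 0.75 * 20000))   # conservative per-variant SE
  expect_true(all(abs(w2 - 0.1) < 3 * se_approx))

  # simulated PCs are independent of genotypes: adjusting leaves weights intact
  w3 <- estimate_weights(co$genotypes, co$phenotypes, n_pcs = 12)
  expect_equal(unname(w3), unname(w2), tolerance = 5e-3)

  expect_error(estimate_weights(co$genotypes, co$phenotypes, n_pcs = 40),
               class = "mrwell_config_error")
})

test_that("jack-knife weighting never lets individuals inform their own weights", {
  co <- quick_cohort(n = 900, m = 5, seed = 4, related_fraction = 0.2)
  jw <- jackknife_weights(co$genotypes, co$phenotypes, n_blocks = 3, n_pcs = 0, seed = 99)

  # leave-block-out contract: perturbing one block's phenotypes must not
  # change the weights assigned to that block
  b <- 1L
  in_block <- jw$block_id == b
  ph2 <- co$phenotypes
  ph2$bmi[in_block] <- ph2$bmi[in_block] + 50      # gross perturbation
  jw2 <- jackknife_weights(co$genotypes, ph2, n_blocks = 3, n_pcs = 0, seed = 99)
  expect_identical(jw2$block_id, jw$block_id)       # same seeded partition
  expect_equal(jw2$beta[b + 1, ], jw$beta[b + 1, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(jw2$beta[3, ], jw$beta[3, ])))  # other blocks do move

  # related individuals carry the full-unrelated-sample weights (block id 0)
  expect_true(all(jw$block_id[co$phenotypes$related] == 0))
  full <- estimate_weights(co$genotypes, co$phenotypes, n_pcs = 0)
  expect_equal(jw$beta[1, ], full, tolerance = 1e-12)

  # homogeneous data: the two half-sample weight vectors agree
  co2 <- quick_cohort(n = 6000, m = 5, seed = 6, related_fraction = 0,
                      beta_g = 0.2, confounder_strength_x = 1, noise_sd_x = 1)
  jw3 <- jackknife_weights(co2$genotypes, co2$phenotypes, n_blocks = 2, n_pcs = 0, seed = 1)
  # exchangeability oracle: each half-sample weight has SE sqrt(s2 / (v_j n/2))
  # with residual variance s2 = 2 by construction; the difference of the two
  # independent halves has sqrt(2) times that spread
  v_j <- apply(co2$genotypes$dosage, 2, var)
  se_j <- sqrt(2 / (v_j * 3000))
  expect_true(all(abs(jw3$beta[2, ] - jw3$beta[3, ]) < 3 * sqrt(2) * se_j))

  expect_error(jackknife_weights(co$genotypes, co$phenotypes, n_blocks = 1),
               class = "mrwell_config_error")
})

test_that("MAF filtering uses a strict threshold and drops multiallelic variants", {
  m <- cbind(v1 = c(0, 0, 0, 1), v2 = c(1, 1, 2, 0), v3 = c(0, 1, 0, 1))
  rownames(m) <- paste0("i", 1:4)
  g <- genotype_matrix(m, rep("A", 3), rep("G", 3),
                       multiallelic = c(FALSE, FALSE, TRUE))
  # v1 MAF = 0.125, v2 MAF = 0.5, v3 multiallelic
  kept <- maf_filter(g, threshold = 0.2)
  expect_identical(kept$variant_id, "v2")
  expect_identical(attr(kept, "removed"), c("v1", "v3"))

  # boundary: exactly at the threshold is retained
  kept2 <- maf_filter(g, threshold = 0.125)
  expect_true("v1" %in% kept2$variant_id)

  expect_error(maf_filter(g, threshold = 0.6), class = "mrwell_empty_instrument_error")
})

test_that("weighted and standardised scores follow the defining identity", {
  g1 <- genotype_matrix(matrix(2, 1, 1, dimnames = list("i1", "v1")), "A", "G")
  r1 <- compute_grs(g1, 1)
  expect_equal(r1$grs_w, 2)
  expect_equal(r1$grs_s, 2)                          # (1 x 2) / 1

  g2 <- genotype_matrix(matrix(c(1, 2), 1, 2, dimnames = list("i1", c("v1", "v2"))),
                        c("A", "A"), c("G", "G"))
  r2 <- compute_grs(g2, c(0.5, 0.5))
  expect_equal(r2$grs_w, 1.5)
  expect_equal(r2$grs_s, 3)                          # (2 x 1.5) / 1

  # uniform dosage d across variants makes the standardised score n * d
  g3 <- genotype_matrix(matrix(1, 2, 3, dimnames = list(c("i1", "i2"), paste0("v", 1:3))),
                        rep("A", 3), rep("G", 3))
  r3 <- compute_grs(g3, c(0.2, 0.5, 0.9))
  expect_equal(r3$grs_s, c(3, 3))

  expect_error(compute_grs(g2, c(0.5, -0.5)), class = "mrwell_standardisation_error")

  # identity GRS_s * sum(beta) = n * GRS_w holds per individual, including
  # under per-individual jack-knife weights
  co <- quick_cohort(n = 600, m = 4, seed = 12)
  jw <- jackknife_weights(co$genotypes, co$phenotypes, n_blocks = 3, n_pcs = 0, seed = 2)
  gr <- compute_grs(co$genotypes, jw)
  sum_beta <- rowSums(jw$beta[jw$block_id + 1L, , drop = FALSE])
  expect_equal(gr$grs_s * sum_beta, 4 * gr$grs_w, tolerance = 1e-12)
})

test_that("flipping a variant's coded allele shifts the score by a constant only", {
  co <- quick_cohort(n = 800, m = 5, seed = 19)
  w <- co$truth$beta_g
  g0 <- compute_grs(co$genotypes, w)

  flip <- co$genotypes
  flip$dosage[, 2] <- 2 - flip$dosage[, 2]
  flip <- genotype_matrix(flip$dosage, flip$effect_allele, flip$other_allele)
  w2 <- w; w2[2] <- -w2[2]
  g1 <- compute_grs(flip, w2)

  shift <- g1$grs_w - g0$grs_w
  expect_equal(max(shift) - min(shift), 0, tolerance = 1e-12)

  # downstream regression slope on the score is unchanged
  y <- co$phenotypes$bmi
  expect_equal(unname(coef(lm(y ~ g0$grs_w))[2]),
               unname(coef(lm(y ~ g1$grs_w))[2]), tolerance = 1e-10)
})

test_that("instrument diagnostics satisfy the exact F / R-squared identity", {
  co <- quick_cohort(n = 5000, m = 10, seed = 23, beta_g = 0.15,
                     confounder_strength_x = 1, noise_sd_x = 1)
  gr <- true_grs(co)
  for (s in c("male", "female")) {
    d <- instrument_strength(gr, co$phenotypes, sex = s)
    expect_gt(d$r_squared, 0)
    expect_lt(d$r_squared, 1)
    f_expected <- d$r_squared * (d$n - 2) / (1 - d$r_squared)
    expect_equal(d$f_statistic, f_expected, tolerance = 1e-10)
  }

  # score unrelated to the exposure: variance explained near zero
  set.seed(77)
  null_score <- rnorm(nrow(co$phenotypes))
  d0 <- instrument_strength(null_score, co$phenotypes)
  expect_lt(d0$r_squared, 0.002)
  expect_lt(d0$f_statistic, 10)
})
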