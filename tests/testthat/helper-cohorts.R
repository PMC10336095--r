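# shared fixture builders: everything is generated in code at test time

# small cohort with convenient overrides; defaults keep tests fast
quick_cohort <- function(n = 4000, m = 10, seed = 1, ...) {
  simulate_cohort(sim_config(n_individuals = n, n_variants = m, seed = seed, ...))
}

# genetic risk score built from the generator's true per-variant effects,
# bypassing weight estimation (for tests that target the MR machinery)
true_grs <- function(cohort) {
  compute_grs(cohort$genotypes, cohort$truth$beta_g)
}

# deterministic per-replicate seeds for simulation suites (kept below 2^31)
derive_seed_for_test <- function(block, i) {
  (block * 10007 + i * 13) %% 2147483647
}

# write a minimal dosage-bearing VCF (plain text) and return its path
write_test_vcf <- function(path, with_ds = TRUE) {
  fmt <- if (with_ds) "GT:DS" else "GT"
  gt <- function(g, d) if (with_ds) paste0(g, ":", d) else g
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (with_ds) "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3"),
    paste("1\t100\trs1\tG\tA\t.\tPASS\t.", fmt,
          gt("0/1", "0.9"), gt("1/1", "2.0"), gt("0/0", "0.1"), sep = "\t"),
    paste("1\t200\trs2\tC\tT\t.\tPASS\t.", fmt,
          gt("0/0", "0.2"), gt("0/1", "1.1"), gt("0/1", "0.8"), sep = "\t"),
    paste("1\t300\trs3\tA\tG,T\t.\tPASS\t.", fmt,
          gt("0/1", "1.0"), gt("0/0", "0.0"), gt("0/1", "1.0"), sep = "\t")
  )
  writeLines(lines, path)
  path
}
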