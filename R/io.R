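#' Construct a genotype dosage matrix
#'
#' The central genotype container: an individuals-by-variants numeric matrix
#' of effect-allele dosages in \[0, 2\] with per-variant allele labels, the
#' minor-allele frequency computed from the dosages as
#' `min(p, 1 - p)` with `p = mean(dosage) / 2`, and a multiallelic flag.
#'
#' @param dosage numeric matrix, individuals in rows (rownames = ids),
#'   variants in columns (colnames = variant ids).
#' @param effect_allele,other_allele character vectors, one per variant.
#' @param multiallelic logical vector, one per variant (default all FALSE).
#' @param drawn_freq optional numeric vector of the generative allele
#'   frequencies (recorded by the simulator).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, effect_allele, other_allele,
                            multiallelic = rep(FALSE, ncol(dosage)),
                            drawn_freq = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (anyNA(dosage) || any(dosage < 0 | dosage > 2)) {
    bad <- which(is.na(dosage) | dosage < 0 | dosage > 2, arr.ind = TRUE)[1, ]
    stop_mrwell("dosage outside [0, 2] at row ", bad[1], ", column ", bad[2],
                class = "mrwell_validation_error")
  }
  if (anyDuplicated(rownames(dosage)) || anyDuplicated(colnames(dosage)))
    stop_mrwell("individual and variant ids must be unique", class = "mrwell_validation_error")
  p <- colMeans(dosage) / 2
  obj <- list(
    dosage = dosage,
    variant_id = colnames(dosage),
    individual_id = rownames(dosage),
    effect_allele = effect_allele,
    other_allele = other_allele,
    maf = pmin(p, 1 - p),
    multiallelic = as.logical(multiallelic),
    drawn_freq = drawn_freq
  )
  class(obj) <- "genotype_matrix"
  obj
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "individuals x", ncol(x$dosage), "variants\n")
  cat("  MAF range:", sprintf("%.3f-%.3f", min(x$maf), max(x$maf)),
      "| multiallelic:", sum(x$multiallelic), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Read a dosage matrix from TSV or VCF
#'
#' The TSV layout is individuals in rows (first column `id`), one column per
#' variant, so it joins directly on the phenotype table. VCF input is parsed
#' with vcfR; per-sample dosages are taken from `dosage_field` (conventionally
#' `DS`); if that field is absent and `strict = FALSE`, hard genotype calls
#' (`GT`) are summed to a 0/1/2 dosage. Records with more than one ALT allele
#' are flagged multiallelic (and excluded later by [maf_filter()]).
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @param dosage_field VCF FORMAT field holding the dosage (default `"DS"`).
#' @param strict if `TRUE`, a VCF without `dosage_field` is an error instead
#'   of falling back to hard calls.
#' @return a [genotype_matrix].
#' @export
read_dosage_matrix <- function(path, format = c("tsv", "vcf"),
                               dosage_field = "DS", strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_mrwell("file not found: ", path, class = "mrwell_io_error")
  if (format == "tsv") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
    ids <- as.character(dt[[1]])
    m <- as.matrix(dt[, -1, drop = FALSE])
    rownames(m) <- ids
    return(genotype_matrix(m,
                           effect_allele = rep(NA_character_, ncol(m)),
                           other_allele = rep(NA_character_, ncol(m))))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  fmt_fields <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)))
  if (dosage_field %in% fmt_fields) {
    ds <- vcfR::extract.gt(vcf, element = dosage_field, as.numeric = TRUE)
  } else if (!strict) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    })
  } else {
    stop_mrwell("VCF has no '", dosage_field, "' FORMAT field", class = "mrwell_format_error")
  }
  m <- t(ds)  # vcfR returns variants x samples
  vid <- fix[, "ID"]
  vid[is.na(vid) | vid == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(vid) | vid == "."]
  colnames(m) <- vid
  genotype_matrix(m,
                  effect_allele = unname(fix[, "ALT"]),
                  other_allele = unname(fix[, "REF"]),
                  multiallelic = multi)
}

#' Write a dosage matrix as TSV (individuals in rows)
#'
#' @param geno a [genotype_matrix].
#' @param path output path.
#' @param digits decimal digits for printed dosages (round-trip precision).
#' @export
write_dosage_matrix <- function(geno, path, digits = 6) {
  df <- data.frame(id = rownames(geno$dosage),
                   round(geno$dosage, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a phenotype table
#'
#' Tab-delimited with a header; missing cells encoded as `NA`. Performs light
#' validation: positive BMI where present, unique ids.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) stop_mrwell("file not found: ", path, class = "mrwell_io_error")
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = "NA")
  if (!"id" %in% names(df)) stop_mrwell("phenotype table needs an 'id' column", class = "mrwell_validation_error")
  if (anyDuplicated(df$id)) stop_mrwell("duplicate individual ids", class = "mrwell_validation_error")
  if ("bmi" %in% names(df) && any(df$bmi <= 0, na.rm = TRUE))
    stop_mrwell("BMI must be positive where present", class = "mrwell_validation_error")
  df
}

## label ladders for the three supported recoding schemes, in ascending order
.recode_schemes <- list(
  health4 = list(levels = c("Poor", "Fair", "Good", "Excellent"),
                 codes = 0:3, missing = character()),
  life4_merged = list(
    levels = c("Very unsatisfied", "Unsatisfied",
               "Neither satisfied nor dissatisfied", "Satisfied", "Very satisfied"),
    codes = c(0L, 0L, 1L, 2L, 3L),  # bottom two merged: sparse lowest category
    missing = character()),
  happiness6 = list(
    levels = c("Extremely unhappy", "Very unhappy", "Moderately unhappy",
               "Moderately happy", "Very happy", "Extremely happy"),
    codes = 0:5,
    missing = c("Do not know", "Prefer not to answer"))
)

#' Recode a labelled well-being response to an ordinal score
#'
#' Three schemes are supported. `health4` maps Poor/Fair/Good/Excellent to
#' 0-3. `life4_merged` maps the five-level life-satisfaction ladder to 0-3,
#' merging "Very unsatisfied" into "Unsatisfied" (the lowest category is too
#' sparse to stand alone). `happiness6` maps the six-level happiness ladder
#' to 0-5 and sets "Do not know" / "Prefer not to answer" to missing. The
#' highest code always represents the most favourable response.
#'
#' @param raw character (or factor) vector of labels.
#' @param scheme one of `"health4"`, `"life4_merged"`, `"happiness6"`.
#' @return integer vector with NA for missing-coded responses.
#' @export
recode_outcome <- function(raw, scheme = c("health4", "life4_merged", "happiness6")) {
  scheme <- match.arg(scheme)
  sc <- .recode_schemes[[scheme]]
  raw <- as.character(raw)
  known <- c(sc$levels, sc$missing, NA)
  bad <- setdiff(unique(raw), known)
  if (length(bad))
    stop_mrwell("unknown label(s) for scheme '", scheme, "': ",
                paste(bad, collapse = ", "), class = "mrwell_schema_error")
  out <- sc$codes[match(raw, sc$levels)]
  out[raw %in% sc$missing] <- NA_integer_
  as.integer(out)
}

#' Write a table of estimates as TSV with a JSON mirror
#'
#' Accepts a data.frame of estimates or a list of `stratum_estimate` /
#' `meta_result` / `diff_test` objects (coerced via [as_estimate_table()]).
#' 95% confidence bounds are computed as `beta +/- 1.96 * se` where absent.
#'
#' @param estimates data.frame or list of result objects.
#' @param path output TSV path; the JSON mirror replaces the extension.
#' @return invisibly, the two paths written.
#' @export
write_results <- function(estimates, path) {
  df <- as_estimate_table(estimates)
  if (nrow(df) > 0 && all(c("beta", "se") %in% names(df))) {
    if (!"lcl" %in% names(df)) df$lcl <- df$beta - 1.96 * df$se
    if (!"ucl" %in% names(df)) df$ucl <- df$beta + 1.96 * df$se
  }
  data.table::fwrite(df, path, sep = "\t", na = "NA")
  json_path <- sub("\\.[^.]*$", ".json", path)
  if (json_path == path) json_path <- paste0(path, ".json")
  jsonlite::write_json(df, json_path, auto_unbox = FALSE, digits = NA, na = "null")
  invisible(c(tsv = path, json = json_path))
}

#' Coerce result objects to a flat estimate table
#'
#' @param estimates data.frame (returned as-is) or list of result objects
#'   carrying `beta`, `se`, `n` and label fields.
#' @return data.frame, possibly zero-row.
#' @export
as_estimate_table <- function(estimates) {
  if (is.data.frame(estimates)) return(estimates)
  if (inherits(estimates, "stratum_estimate")) estimates <- list(estimates)
  if (length(estimates) == 0)
    return(data.frame(model = character(), beta = numeric(), se = numeric(),
                      lcl = numeric(), ucl = numeric(), p = numeric(),
                      n = integer()))
  rows <- lapply(estimates, function(e) {
    data.frame(
      model = e$model %||% NA_character_,
      sex = e$sex %||% NA_character_,
      region = e$region %||% NA_character_,
      cohort = e$cohort %||% NA_character_,
      beta = e$beta, se = e$se,
      lcl = e$beta - 1.96 * e$se, ucl = e$beta + 1.96 * e$se,
      p = e$p %||% NA_real_,
      n = e$n %||% NA_integer_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
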