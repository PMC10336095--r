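## small internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mrwell <- function(..., class) {
  stop(structure(
    class = c(class, "mrwell_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

#' Convert a covariate specification to a numeric model matrix
#'
#' Accepts `NULL` (no covariates), a data.frame, or a character vector of
#' column names to be taken from `data`. Factors and characters are expanded
#' to treatment-coded dummies; the intercept column is never included here.
#'
#' @param covariates `NULL`, data.frame, or character vector of column names.
#' @param data data.frame to resolve column names against (when `covariates`
#'   is a character vector).
#' @return numeric matrix with one row per observation (zero columns if none).
#' @keywords internal
covariate_matrix <- function(covariates, data = NULL) {
  if (is.null(covariates)) return(NULL)
  if (is.character(covariates)) {
    if (is.null(data)) stop_mrwell("covariate names given without a data table", class = "mrwell_config_error")
    missing_cols <- setdiff(covariates, names(data))
    if (length(missing_cols)) {
      stop_mrwell("covariate column(s) not found: ", paste(missing_cols, collapse = ", "),
                  class = "mrwell_config_error")
    }
    covariates <- data[covariates]
  }
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) == 0L) return(NULL)
  mm <- model.matrix(~ ., data = covariates)
  mm <- mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE]
  if (ncol(mm) == 0L) NULL else mm
}

## deterministic child seeds derived from a master seed (kept < 2^31)
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 69069 + 12345 * k) %% 2147483647
}

## md5 of an R object's deparsed form, for report provenance
config_hash <- function(x) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  writeLines(deparse(x), tf)
  unname(tools::md5sum(tf))
}
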