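#' Phenotype and covariate table
#'
#' One row per sample: sample id, cohort id, disease status and any number
#' of numeric covariate columns (principal components, geographic or cohort
#' indicators). Status takes one of `CONTROL`, `PSA`, `PSC`,
#' `UNKNOWN_SUBTYPE`; the unknown-subtype label is reserved for psoriasis
#' cases whose subtype has not been assessed.
#'
#' @param df data.frame with at least `sample_id`, `cohort`, `status`.
#' @param covariates character vector naming covariate columns; defaults to
#'   every column that is not `sample_id`/`cohort`/`status`.
#' @return a `phenotype_table` (a data.frame subclass with a `covariates`
#'   attribute).
#' @export
phenotype_table <- function(df, covariates = NULL) {
  stopifnot(is.data.frame(df))
  for (col in c("sample_id", "cohort", "status")) {
    if (!col %in% names(df)) stop("phenotype table lacks column: ", col)
  }
  df$sample_id <- as.character(df$sample_id)
  df$cohort <- as.character(df$cohort)
  df$status <- as.character(df$status)
  bad <- setdiff(unique(df$status), .STATUS_LEVELS)
  if (length(bad)) stop("unknown status value(s): ", paste(bad, collapse = ", "))
  dup <- duplicated(paste(df$cohort, df$sample_id))
  if (any(dup)) stop("duplicated sample id(s) within a cohort")
  covariates <- covariates %||%
    setdiff(names(df), c("sample_id", "cohort", "status"))
  miss <- setdiff(covariates, names(df))
  if (length(miss)) stop("covariate column(s) absent: ", paste(miss, collapse = ", "))
  for (cv in covariates) {
    if (!is.numeric(df[[cv]])) stop("covariate must be numeric: ", cv)
  }
  rownames(df) <- NULL
  structure(df, covariates = covariates,
            class = c("phenotype_table", "data.frame"))
}

#' @exportS3Method base::print
print.phenotype_table <- function(x, ...) {
  tab <- table(factor(x$status, levels = .STATUS_LEVELS), x$cohort)
  cat(sprintf("phenotype_table: %d samples, %d cohort(s), covariates: %s\n",
              nrow(x), length(unique(x$cohort)),
              paste(attr(x, "covariates"), collapse = ", ")))
  print(tab)
  invisible(x)
}

pheno_covariates <- function(pheno) attr(pheno, "covariates") %||% character()

#' Write / read a phenotype table as tab-separated text
#'
#' @param pheno a [phenotype_table()].
#' @param path file path.
#' @return `read_phenotypes` returns a `phenotype_table`.
#' @export
write_phenotypes <- function(pheno, path) {
  write.table(as.data.frame(pheno), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  phenotype_table(read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE))
}
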