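#' Genotype dosage matrix with per-marker metadata
#'
#' The central genotype container: an `n_samples x n_markers` matrix of
#' imputed allele dosages in `[0, 2]` (risk-allele counts; `NA` = missing)
#' plus one metadata row per marker. Markers flagged `genotyped` carry hard
#' calls (dosages in `{0, 1, 2}`) and an imputation quality of 1.
#'
#' @param dosages numeric matrix, samples in rows (rownames = sample ids),
#'   markers in columns (colnames = marker ids).
#' @param markers data.frame with one row per column of `dosages` and columns
#'   `marker_id`, `chrom`, `pos` (1-based), `allele_risk`, `allele_nonrisk`,
#'   `imputation_r2` in (0, 1], and logical `genotyped`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, markers) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  stopifnot(is.data.frame(markers))
  required <- c("marker_id", "chrom", "pos", "allele_risk", "allele_nonrisk",
                "imputation_r2", "genotyped")
  missing_cols <- setdiff(required, names(markers))
  if (length(missing_cols)) {
    stop("marker metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(markers) != ncol(dosages)) {
    stop("markers has ", nrow(markers), " rows but dosages has ",
         ncol(dosages), " columns")
  }
  markers$marker_id <- as.character(markers$marker_id)
  markers$chrom <- norm_chrom(markers$chrom)
  if (is.null(colnames(dosages))) colnames(dosages) <- markers$marker_id
  if (!identical(colnames(dosages), markers$marker_id)) {
    stop("dosage column names do not match marker ids")
  }
  if (anyDuplicated(markers$marker_id)) stop("duplicated marker ids")
  rng <- range(dosages, na.rm = TRUE)
  if (any(is.finite(rng)) && (rng[1] < 0 || rng[2] > 2)) {
    stop("dosages must lie in [0, 2]")
  }
  if (any(markers$imputation_r2 <= 0 | markers$imputation_r2 > 1)) {
    stop("imputation_r2 must lie in (0, 1]")
  }
  gt <- which(markers$genotyped)
  if (length(gt)) {
    hard <- dosages[, gt, drop = FALSE]
    ok <- is.na(hard) | hard %in% c(0, 1, 2)
    if (!all(ok)) stop("genotyped markers must have hard-call dosages {0,1,2}")
  }
  rownames(markers) <- NULL
  structure(list(dosages = dosages, markers = markers),
            class = "genotype_matrix")
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers (%d genotyped, %d imputed)\n",
              nrow(x$dosages), ncol(x$dosages),
              sum(x$markers$genotyped), sum(!x$markers$genotyped)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param samples sample ids or row indices (NULL = all).
#' @param markers marker ids or column indices (NULL = all).
#' @return a `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(x, samples = NULL, markers = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  si <- if (is.null(samples)) seq_len(nrow(x$dosages)) else samples
  mi <- if (is.null(markers)) seq_len(ncol(x$dosages)) else markers
  if (is.character(mi)) {
    miss <- setdiff(mi, x$markers$marker_id)
    if (length(miss)) stop("unknown marker id(s): ", paste(miss, collapse = ", "))
    mi <- match(mi, x$markers$marker_id)
  }
  genotype_matrix(x$dosages[si, mi, drop = FALSE],
                 x$markers[mi, , drop = FALSE])
}

#' Minor allele frequency per marker
#'
#' Frequencies are computed from mean dosage / 2 and folded to (0, 0.5].
#'
#' @param x a [genotype_matrix()].
#' @return named numeric vector of MAFs (NA for all-missing markers).
#' @export
marker_maf <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  af <- colMeans(x$dosages, na.rm = TRUE) / 2
  pmin(af, 1 - af)
}

#' Marker ids falling inside the extended MHC window
#'
#' The window is the conventional extended MHC, chromosome 6, 25-34 Mb.
#'
#' @param markers marker metadata data.frame (or a `genotype_matrix`).
#' @return character vector of marker ids inside the window.
#' @export
mhc_markers <- function(markers) {
  if (inherits(markers, "genotype_matrix")) markers <- markers$markers
  idx <- norm_chrom(markers$chrom) == MHC_CHROM &
    markers$pos >= MHC_START & markers$pos <= MHC_END
  markers$marker_id[idx]
}
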