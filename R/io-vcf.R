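# VCF v4.2 dosage interchange. The writer is plain text formatting; the
# reader goes through VariantAnnotation so the two routes stay independent.

#' Write a genotype matrix as VCF v4.2 with DS dosages
#'
#' One biallelic record per marker: REF = non-risk allele, ALT = risk
#' allele, INFO `R2` (imputation quality) plus the `TYPED` flag for
#' genotyped markers, FORMAT `GT:DS` (hard genotypes for typed markers,
#' `./.` otherwise; DS is the risk-allele dosage). Coordinates are 1-based.
#'
#' @param g a [genotype_matrix()].
#' @param path output file path (plain text).
#' @return the path, invisibly.
#' @export
write_vcf_dosages <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  mk <- g$markers
  samples <- rownames(g$dosages)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=psasig",
    '##INFO=<ID=R2,Number=1,Type=Float,Description="Imputation quality r-squared">',
    '##INFO=<ID=TYPED,Number=0,Type=Flag,Description="Marker was directly genotyped">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Risk-allele dosage">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(g$dosages))) {
    d <- g$dosages[, j]
    info <- sprintf("R2=%.4g", mk$imputation_r2[j])
    if (mk$genotyped[j]) {
      info <- paste0(info, ";TYPED")
      gt <- ifelse(is.na(d), "./.", gt_codes[round(d) + 1])
    } else {
      gt <- rep("./.", length(d))
    }
    ds <- ifelse(is.na(d), ".", sprintf("%.4g", d))
    writeLines(paste(c(mk$chrom[j], formatC(mk$pos[j], format = "d"),
                       mk$marker_id[j],
                       mk$allele_nonrisk[j], mk$allele_risk[j], ".", "PASS",
                       info, "GT:DS", paste(gt, ds, sep = ":")),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read dosages from a VCF
#'
#' Dosages come from the `DS` FORMAT field when declared, otherwise from
#' `GT` as alternate-allele counts. Imputation quality comes from INFO
#' `R2` (1.0 with `genotyped = TRUE` when absent); the `TYPED` flag, when
#' declared, sets the genotyped flag per marker. Multi-allelic records are
#' skipped with a warning.
#'
#' @param path VCF file path.
#' @return a [genotype_matrix()] (risk allele = ALT).
#' @export
read_vcf_dosages <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  multi <- S4Vectors::elementNROWS(alt) > 1
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    vcf <- vcf[!multi]
    alt <- alt[!multi]
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  geno <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(geno)) {
    D <- geno$DS
    storage.mode(D) <- "double"
  } else if ("GT" %in% names(geno)) {
    gt <- geno$GT
    D <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    D[gt %in% c("0/0", "0|0")] <- 0
    D[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
    D[gt %in% c("1/1", "1|1")] <- 2
  } else {
    stop("VCF carries neither DS nor GT")
  }
  info <- VariantAnnotation::info(vcf)
  m <- nrow(D)
  r2 <- if ("R2" %in% names(info)) as.numeric(info$R2) else rep(1, m)
  genotyped <- if ("TYPED" %in% names(info)) {
    as.logical(info$TYPED)
  } else if (!"R2" %in% names(info)) {
    rep(TRUE, m)
  } else {
    rep(FALSE, m)
  }
  r2[is.na(r2)] <- 1
  markers <- data.frame(
    marker_id = names(rr),
    chrom = norm_chrom(as.character(GenomeInfoDb::seqnames(rr))),
    pos = GenomicRanges::start(rr),
    allele_risk = as.character(unlist(alt)),
    allele_nonrisk = as.character(VariantAnnotation::ref(vcf)),
    imputation_r2 = r2, genotyped = genotyped, stringsAsFactors = FALSE)
  genotype_matrix(t(D), markers)
}

#' Load a directory of per-cohort VCF + phenotype files as a cohort set
#'
#' Expects `<cohort>.vcf` and `<cohort>.pheno.tsv` pairs as written by the
#' `simulate` CLI stage.
#'
#' @param dir directory path.
#' @return a `cohort_set`.
#' @export
read_cohort_dir <- function(dir) {
  vcfs <- sort(list.files(dir, pattern = "\\.vcf$", full.names = TRUE))
  if (!length(vcfs)) stop("no VCF files under ", dir)
  cohorts <- list()
  for (v in vcfs) {
    nm <- sub("\\.vcf$", "", basename(v))
    ph <- file.path(dir, paste0(nm, ".pheno.tsv"))
    if (!file.exists(ph)) stop("missing phenotype table: ", ph)
    cohorts[[nm]] <- list(genotypes = read_vcf_dosages(v),
                          phenotypes = read_phenotypes(ph))
  }
  structure(cohorts, class = "cohort_set")
}

#' Write a cohort set as per-cohort VCF + phenotype TSV files
#'
#' @param cohorts a `cohort_set`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort_dir <- function(cohorts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cohorts)) {
    write_vcf_dosages(cohorts[[nm]]$genotypes, file.path(dir, paste0(nm, ".vcf")))
    write_phenotypes(cohorts[[nm]]$phenotypes,
                     file.path(dir, paste0(nm, ".pheno.tsv")))
  }
  invisible(dir)
}
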