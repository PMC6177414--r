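#' Marker quality control
#'
#' Removes markers failing minor allele frequency, call rate, or
#' Hardy-Weinberg thresholds. HWE is tested on hard calls of genotyped
#' markers only (imputed-only markers skip the HWE criterion). A per-
#' criterion filter report is attached as `attr(, "qc_report")` and logged
#' via `message()`.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param call_rate_min minimum fraction of non-missing dosages (default 0.95).
#' @param hwe_p_min minimum HWE exact-test p-value (default 1e-6).
#' @return the filtered `genotype_matrix`.
#' @export
marker_qc <- function(g, maf_min = 0.01, call_rate_min = 0.95,
                      hwe_p_min = 1e-6) {
  stopifnot(inherits(g, "genotype_matrix"))
  stopifnot(maf_min > 0, maf_min < 1, call_rate_min > 0, call_rate_min <= 1,
            hwe_p_min > 0, hwe_p_min < 1)
  m <- ncol(g$dosages)
  if (m == 0 || nrow(g$dosages) == 0) {
    warning("empty genotype matrix; nothing to filter")
    return(g)
  }
  maf <- marker_maf(g)
  call_rate <- colMeans(!is.na(g$dosages))
  fail_maf <- is.na(maf) | maf < maf_min
  fail_call <- call_rate < call_rate_min
  hwe_p <- rep(NA_real_, m)
  gt <- which(g$markers$genotyped)
  for (j in gt) {
    d <- g$dosages[, j]
    d <- d[!is.na(d)]
    if (!length(d)) next
    hwe_p[j] <- hwe_exact_p(sum(d == 0), sum(d == 1), sum(d == 2))
  }
  fail_hwe <- !is.na(hwe_p) & hwe_p < hwe_p_min
  keep <- !(fail_maf | fail_call | fail_hwe)
  report <- data.frame(
    criterion = c("maf", "call_rate", "hwe"),
    threshold = c(maf_min, call_rate_min, hwe_p_min),
    n_failed = c(sum(fail_maf), sum(fail_call), sum(fail_hwe))
  )
  message(sprintf("marker_qc: %d/%d markers retained (maf: -%d, call rate: -%d, hwe: -%d)",
                  sum(keep), m, sum(fail_maf), sum(fail_call), sum(fail_hwe)))
  out <- subset_genotypes(g, markers = which(keep))
  attr(out, "qc_report") <- report
  out
}

# single logistic Wald fit; returns beta/se/convergence for the first
# non-intercept column (the dosage term)
fit_logistic_wald <- function(y, x_marker, covars = NULL, maxit = 25) {
  X <- cbind(`(Intercept)` = 1, dosage = x_marker, covars)
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = list(maxit = maxit, epsilon = 1e-10))
  )
  cf <- fit$coefficients
  if (is.na(cf["dosage"])) {
    return(list(beta = NA_real_, se = NA_real_, converged = FALSE,
                reason = "collinear"))
  }
  # Wald variance from the unscaled covariance at the IRLS solution
  W <- fit$weights
  XtWX <- crossprod(X * sqrt(W))
  cov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  if (is.null(cov)) {
    return(list(beta = NA_real_, se = NA_real_, converged = FALSE,
                reason = "singular"))
  }
  se <- sqrt(cov[2, 2])
  converged <- isTRUE(fit$converged) && abs(cf["dosage"]) <= 15 &&
    is.finite(se) && se > 0
  list(beta = unname(cf["dosage"]), se = se, converged = converged,
       reason = if (converged) NA_character_ else "separation")
}

#' Per-cohort logistic Wald association test
#'
#' Fits, marker by marker, a logistic regression of case status on dosage
#' plus covariates (and optionally the dosages of conditioning markers), by
#' iteratively reweighted least squares, and reports the Wald statistic for
#' the dosage term. Missing dosages are handled per marker by complete-case
#' analysis. Non-convergence or separation is flagged (`converged = FALSE`,
#' p-value missing) rather than patched. Monomorphic markers are skipped
#' with reason `"monomorphic"`; conditioning markers are not themselves
#' tested.
#'
#' @param g a [genotype_matrix()].
#' @param pheno a [phenotype_table()] covering the samples of `g`.
#' @param case_label,control_label status labels coded 1 and 0.
#' @param covariate_names covariate columns of `pheno` to adjust for.
#' @param conditioning_markers marker ids whose dosages enter as covariates.
#' @param markers optional subset of marker ids to test (default: all
#'   non-conditioning markers).
#' @return an `assoc_result` data.frame: `marker_id`, `beta`, `se`,
#'   `wald_z`, `p_value`, `case_af`, `control_af`, `n_cases`, `n_controls`,
#'   `converged`, `reason`.
#' @export
logistic_wald <- function(g, pheno, case_label = "PSA",
                          control_label = "CONTROL",
                          covariate_names = character(),
                          conditioning_markers = character(),
                          markers = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  pheno <- phenotype_table(as.data.frame(pheno))
  idx <- match(rownames(g$dosages), pheno$sample_id)
  if (anyNA(idx)) stop("phenotype table lacks some genotyped samples")
  status <- pheno$status[idx]
  use <- status %in% c(case_label, control_label)
  if (sum(status[use] == case_label) < 1 || sum(status[use] == control_label) < 1) {
    stop("need at least one case and one control")
  }
  y <- as.numeric(status[use] == case_label)
  D <- g$dosages[use, , drop = FALSE]
  covars <- NULL
  if (length(covariate_names)) {
    miss <- setdiff(covariate_names, names(pheno))
    if (length(miss)) stop("unknown covariate(s): ", paste(miss, collapse = ", "))
    covars <- as.matrix(as.data.frame(pheno)[idx[use], covariate_names,
                                             drop = FALSE])
    # drop constant covariates (e.g. a cohort indicator within one cohort)
    keep <- apply(covars, 2, function(v) var(v, na.rm = TRUE) > 0)
    covars <- covars[, keep, drop = FALSE]
    if (!ncol(covars)) covars <- NULL
  }
  if (length(conditioning_markers)) {
    miss <- setdiff(conditioning_markers, g$markers$marker_id)
    if (length(miss)) {
      stop("conditioning marker(s) absent: ", paste(miss, collapse = ", "))
    }
    cond <- D[, conditioning_markers, drop = FALSE]
    colnames(cond) <- paste0("cond_", conditioning_markers)
    covars <- cbind(covars, cond)
  }
  test_ids <- markers %||% setdiff(g$markers$marker_id, conditioning_markers)
  test_ids <- setdiff(test_ids, conditioning_markers)
  mi <- match(test_ids, g$markers$marker_id)
  if (anyNA(mi)) stop("unknown marker id(s) requested")
  out <- data.frame(
    marker_id = test_ids, beta = NA_real_, se = NA_real_, wald_z = NA_real_,
    p_value = NA_real_, case_af = NA_real_, control_af = NA_real_,
    n_cases = NA_integer_, n_controls = NA_integer_, converged = FALSE,
    reason = NA_character_, stringsAsFactors = FALSE
  )
  for (k in seq_along(mi)) {
    x <- D[, mi[k]]
    cc <- !is.na(x)
    if (!is.null(covars)) cc <- cc & complete.cases(covars)
    xk <- x[cc]; yk <- y[cc]
    out$n_cases[k] <- sum(yk == 1)
    out$n_controls[k] <- sum(yk == 0)
    out$case_af[k] <- mean(xk[yk == 1]) / 2
    out$control_af[k] <- mean(xk[yk == 0]) / 2
    if (length(unique(xk)) < 2) {
      out$reason[k] <- "monomorphic"
      next
    }
    fit <- fit_logistic_wald(yk, xk,
                             if (is.null(covars)) NULL else covars[cc, , drop = FALSE])
    out$beta[k] <- fit$beta
    out$se[k] <- fit$se
    out$converged[k] <- fit$converged
    out$reason[k] <- fit$reason
    if (fit$converged) {
      out$wald_z[k] <- fit$beta / fit$se
      out$p_value[k] <- 2 * pnorm(-abs(out$wald_z[k]))
    }
  }
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Genomic inflation factor
#'
#' Lambda is the median association chi-square divided by the null
#' chi-square(1) median (0.45494).
#'
#' @param p_values numeric vector of p-values (NAs dropped).
#' @return the inflation factor lambda.
#' @export
genomic_inflation <- function(p_values) {
  p <- p_values[is.finite(p_values)]
  if (!length(p)) stop("no finite p-values")
  chi2 <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chi2) / qchisq(0.5, df = 1, lower.tail = FALSE)
}
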