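#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools per-cohort log odds ratios with weights `w_i = 1/V_i` (the METAL
#' convention): `beta_meta = sum(w_i b_i)/sum(w_i)`, `se = 1/sqrt(sum w_i)`.
#' A cohort contributes to a marker only if its estimate is usable
#' (converged, finite `beta`/`se`). With `gc_correct = TRUE`, each cohort's
#' standard errors are inflated by `sqrt(max(lambda_i, 1))` before pooling;
#' lambda is never allowed to deflate statistics. Markers present in a
#' subset of cohorts are pooled over that subset; the per-cohort direction
#' string marks unusable cohorts with `?`.
#'
#' @param results named list of `assoc_result` objects (see
#'   [logistic_wald()]), one per cohort; names define the direction-string
#'   order.
#' @param gc_correct apply per-cohort genomic control before pooling.
#' @param lambda optional named numeric vector of per-cohort inflation
#'   factors; computed from each cohort's p-values when NULL.
#' @return a `meta_result` data.frame: `marker_id`, `beta_meta`, `se_meta`,
#'   `z`, `p_value`, `direction`, `n_cohorts_used`; per-cohort lambdas are
#'   attached as `attr(, "lambda_applied")`.
#' @export
fixed_effects_meta <- function(results, gc_correct = FALSE, lambda = NULL) {
  stopifnot(is.list(results), length(results) >= 1)
  if (is.null(names(results)) || any(names(results) == "")) {
    names(results) <- sprintf("cohort%d", seq_along(results))
  }
  cohorts <- names(results)
  lam <- setNames(rep(1, length(cohorts)), cohorts)
  if (gc_correct) {
    for (nm in cohorts) {
      lam[nm] <- if (!is.null(lambda)) {
        lambda[[nm]]
      } else {
        p <- results[[nm]]$p_value
        if (any(is.finite(p))) genomic_inflation(p) else 1
      }
    }
    lam <- pmax(lam, 1)
  }
  all_ids <- unique(unlist(lapply(results, function(r) r$marker_id)))
  k <- length(cohorts)
  beta <- se <- matrix(NA_real_, length(all_ids), k,
                       dimnames = list(all_ids, cohorts))
  for (nm in cohorts) {
    r <- results[[nm]]
    i <- match(r$marker_id, all_ids)
    usable <- r$converged & is.finite(r$beta) & is.finite(r$se) & r$se > 0
    beta[i[usable], nm] <- r$beta[usable]
    se[i[usable], nm] <- r$se[usable] * sqrt(lam[nm])
  }
  w <- 1 / se^2
  sw <- rowSums(w, na.rm = TRUE)
  swb <- rowSums(w * beta, na.rm = TRUE)
  n_used <- rowSums(!is.na(beta))
  beta_meta <- ifelse(n_used > 0, swb / sw, NA_real_)
  se_meta <- ifelse(n_used > 0, 1 / sqrt(sw), NA_real_)
  z <- beta_meta / se_meta
  p <- 2 * pnorm(-abs(z))
  dir_chr <- matrix("?", length(all_ids), k)
  dir_chr[!is.na(beta) & beta >= 0] <- "+"
  dir_chr[!is.na(beta) & beta < 0] <- "-"
  direction <- apply(dir_chr, 1, paste, collapse = "")
  out <- data.frame(marker_id = all_ids, beta_meta = beta_meta,
                    se_meta = se_meta, z = z, p_value = p,
                    direction = direction, n_cohorts_used = n_used,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "lambda_applied") <- lam
  attr(out, "cohorts") <- cohorts
  class(out) <- c("meta_result", "data.frame")
  out
}

#' Indirect case-case chi-square statistic
#'
#' Compares two case-control meta-analyses (PsA vs control and PsC vs
#' control) marker by marker:
#' `chi2 = (b_PsA - b_PsC)^2 / (V_PsA + V_PsC - 2 rho sqrt(V_PsA V_PsC))`,
#' referred to a chi-square distribution with one degree of freedom. The
#' correlation `rho` between the two log odds ratios has no analytic form;
#' the default 0 is deliberately conservative (the denominator, and hence
#' the p-value, is largest at rho = 0 for rho >= 0). Markers usable in only
#' one arm are emitted with a missing p-value.
#'
#' @param psa_vs_ctl,psc_vs_ctl `meta_result` (or any data.frame with
#'   `marker_id`, `beta_meta`, `se_meta`) for the two arms.
#' @param rho assumed correlation of the two log odds ratios, in `[-1, 1]`.
#' @return an `indirect_stat` data.frame: `marker_id`, `beta_psa`,
#'   `beta_psc`, `v_psa`, `v_psc`, `rho`, `chi2`, `p_value`.
#' @export
indirect_meta <- function(psa_vs_ctl, psc_vs_ctl, rho = 0) {
  if (!is.numeric(rho) || length(rho) != 1 || rho < -1 || rho > 1) {
    stop("rho must be a single value in [-1, 1]")
  }
  ids <- union(psa_vs_ctl$marker_id, psc_vs_ctl$marker_id)
  ia <- match(ids, psa_vs_ctl$marker_id)
  ic <- match(ids, psc_vs_ctl$marker_id)
  ba <- psa_vs_ctl$beta_meta[ia]
  bc <- psc_vs_ctl$beta_meta[ic]
  va <- psa_vs_ctl$se_meta[ia]^2
  vc <- psc_vs_ctl$se_meta[ic]^2
  denom <- va + vc - 2 * rho * sqrt(va * vc)
  bad <- which(is.finite(denom) & denom <= 0)
  if (length(bad)) {
    stop("non-positive variance denominator for marker(s): ",
         paste(ids[bad], collapse = ", "))
  }
  chi2 <- (ba - bc)^2 / denom
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  out <- data.frame(marker_id = ids, beta_psa = ba, beta_psc = bc,
                    v_psa = va, v_psc = vc, rho = rho, chi2 = chi2,
                    p_value = p, stringsAsFactors = FALSE)
  class(out) <- c("indirect_stat", "data.frame")
  out
}

#' Direct case-case meta-analysis
#'
#' Fixed-effects pooling of per-cohort PsA-vs-PsC estimates. Cohorts that
#' cannot contribute a case-case estimate (e.g. a PsA-only cohort, which has
#' no PsC samples) are excluded automatically with a logged notice.
#'
#' @param results named list of per-cohort `assoc_result` objects from
#'   PsA-vs-PsC regressions; elements may be `NULL` for cohorts where the
#'   contrast is impossible.
#' @param ... passed to [fixed_effects_meta()].
#' @return a `meta_result` over the eligible cohorts.
#' @export
direct_case_case_meta <- function(results, ...) {
  eligible <- vapply(results, function(r) {
    !is.null(r) && nrow(r) > 0 &&
      any(r$n_cases > 0 & r$n_controls > 0, na.rm = TRUE)
  }, logical(1))
  if (!any(eligible)) stop("no cohort with both PsA and PsC samples")
  dropped <- names(results)[!eligible]
  if (length(dropped)) {
    message("direct_case_case_meta: excluding cohort(s) without both subtypes: ",
            paste(dropped, collapse = ", "))
  }
  fixed_effects_meta(results[eligible], ...)
}

#' Read / write METAL-style summary files
#'
#' Whitespace-delimited summary-statistic interchange with columns
#' `MarkerName Allele1 Allele2 Effect StdErr P-value Direction` (Allele1 is
#' the effect/risk allele). `read_metal` harmonizes effects to the risk
#' alleles of `markers` when supplied: rows whose alleles are swapped
#' relative to the reference have their effect sign flipped; rows whose
#' alleles cannot be matched exactly are dropped with a warning (strand
#' ambiguity is not second-guessed).
#'
#' @param meta a `meta_result` (for writing).
#' @param markers marker metadata data.frame with `marker_id`,
#'   `allele_risk`, `allele_nonrisk` (used for writing and harmonizing).
#' @param path file path.
#' @return `read_metal` returns a `meta_result`-like data.frame.
#' @export
write_metal <- function(meta, markers, path) {
  i <- match(meta$marker_id, markers$marker_id)
  if (anyNA(i)) stop("marker metadata lacks some meta-analysis markers")
  df <- data.frame(
    MarkerName = meta$marker_id,
    Allele1 = markers$allele_risk[i],
    Allele2 = markers$allele_nonrisk[i],
    Effect = meta$beta_meta,
    StdErr = meta$se_meta,
    `P-value` = meta$p_value,
    Direction = meta$direction %||% strrep("+", 1),
    check.names = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metal
#' @export
read_metal <- function(path, markers = NULL) {
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  need <- c("MarkerName", "Allele1", "Allele2", "Effect", "StdErr")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("METAL file lacks column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(marker_id = df$MarkerName,
                    allele_risk = toupper(df$Allele1),
                    allele_nonrisk = toupper(df$Allele2),
                    beta_meta = df$Effect, se_meta = df$StdErr,
                    p_value = df[["P-value"]] %||%
                      (2 * pnorm(-abs(df$Effect / df$StdErr))),
                    direction = df$Direction %||% NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(markers)) {
    i <- match(out$marker_id, markers$marker_id)
    known <- !is.na(i)
    same <- known & out$allele_risk == toupper(markers$allele_risk[i]) &
      out$allele_nonrisk == toupper(markers$allele_nonrisk[i])
    flipped <- known & out$allele_risk == toupper(markers$allele_nonrisk[i]) &
      out$allele_nonrisk == toupper(markers$allele_risk[i])
    out$beta_meta[flipped] <- -out$beta_meta[flipped]
    tmp <- out$allele_risk[flipped]
    out$allele_risk[flipped] <- out$allele_nonrisk[flipped]
    out$allele_nonrisk[flipped] <- tmp
    drop <- known & !(same | flipped)
    if (any(drop)) {
      warning(sum(drop), " marker(s) dropped: alleles do not match reference")
      out <- out[!drop, , drop = FALSE]
    }
  }
  class(out) <- c("meta_result", "data.frame")
  out
}
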