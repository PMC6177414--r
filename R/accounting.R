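# Small arithmetic helpers for cohort/signature accounting. These let the
# published sample and marker counts be recomputed into the derived
# percentages a study report quotes.

#' Percent increase of a count over a previous count
#'
#' @param new,old nonnegative counts (old > 0).
#' @return `100 * (new - old) / old`.
#' @export
percent_increase <- function(new, old) {
  stopifnot(old > 0)
  100 * (new - old) / old
}

#' Percentage share of a count within a total
#'
#' @param count,total nonnegative counts (total > 0).
#' @return `100 * count / total`.
#' @export
percent_share <- function(count, total) {
  stopifnot(total > 0)
  100 * count / total
}

#' Derived accounting percentages for a subtype signature study
#'
#' Recomputes, from raw counts, the derived figures a study of this design
#' reports: sample-size percent increases over a previous study (overall
#' and for GWAS-coverage samples) and the composition of the selected
#' marker signature (share outside the MHC, share genotyped in at least
#' one cohort).
#'
#' @param psa_new,psa_old,psc_new,psc_old total PsA/PsC sample counts, new
#'   and previous.
#' @param gwas_psa_new,gwas_psa_old,gwas_psc_new,gwas_psc_old counts of
#'   samples with GWAS coverage.
#' @param n_signature signature size (number of selected markers).
#' @param n_mhc_with,n_mhc_without MHC-window markers in the signature,
#'   selected with and without the Immunochip cohort.
#' @param n_genotyped_with signature markers genotyped in at least one
#'   cohort (selection including the Immunochip cohort).
#' @return named list `t1`..`t7` of percentages.
#' @export
signature_accounting <- function(psa_new, psa_old, psc_new, psc_old,
                                 gwas_psa_new, gwas_psa_old,
                                 gwas_psc_new, gwas_psc_old,
                                 n_signature, n_mhc_with, n_mhc_without,
                                 n_genotyped_with) {
  list(
    t1 = percent_increase(psa_new, psa_old),
    t2 = percent_increase(psc_new, psc_old),
    t3 = percent_increase(gwas_psa_new, gwas_psa_old),
    t4 = percent_increase(gwas_psc_new, gwas_psc_old),
    t5 = percent_share(n_signature - n_mhc_with, n_signature),
    t6 = percent_share(n_signature - n_mhc_without, n_signature),
    t7 = percent_share(n_genotyped_with, n_signature)
  )
}
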