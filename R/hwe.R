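#' Exact test for Hardy-Weinberg equilibrium
#'
#' Exact p-value from the conditional distribution of the heterozygote count
#' given allele counts (the standard recurrence used in GWAS QC; mid-p
#' correction off). Probabilities are accumulated over all heterozygote
#' counts with probability not exceeding that of the observed count.
#'
#' @param n_hom1 count of one homozygote class.
#' @param n_het heterozygote count.
#' @param n_hom2 count of the other homozygote class.
#' @return exact two-sided p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_hom1, n_het, n_hom2) {
  stopifnot(is_count(c(n_hom1, n_het, n_hom2)))
  n <- n_hom1 + n_het + n_hom2
  if (n == 0) return(1)
  # rare allele count
  rare <- 2 * min(n_hom1, n_hom2) + n_het
  # heterozygote counts share the parity of the rare allele count
  het_values <- seq(rare %% 2, min(rare, 2 * n - rare), by = 2)
  if (length(het_values) == 1) return(1)
  # unnormalized probabilities by recurrence from the smallest het count
  lp <- numeric(length(het_values))
  for (i in seq_along(het_values)[-1]) {
    h <- het_values[i]
    # P(h) / P(h-2) = 4 * n_rare_hom(h-2) * n_common_hom(h-2) / (h * (h-1))
    hom_r_prev <- (rare - het_values[i - 1]) / 2
    hom_c_prev <- n - het_values[i - 1] - hom_r_prev
    lp[i] <- lp[i - 1] + log(4) + log(hom_r_prev) + log(hom_c_prev) -
      log(h) - log(h - 1)
  }
  prob <- exp(lp - max(lp))
  prob <- prob / sum(prob)
  obs <- match(n_het, het_values)
  if (is.na(obs)) stop("inconsistent genotype counts")
  min(1, sum(prob[prob <= prob[obs] * (1 + 1e-12)]))
}
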