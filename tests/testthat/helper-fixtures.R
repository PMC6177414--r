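# Shared fixture builders. Everything is generated in code; no stored data.

# small two-cohort world with a clear subtype signal
tiny_cohorts <- function(seed = 7, n = 150, n_markers = 50,
                         effect_subtype = 0.7, ...) {
  cfg <- sim_config(n_cohorts = 2, n_control = n, n_psa = n, n_psc = n,
                    n_markers = n_markers, n_shared_loci = 4, n_psa_loci = 2,
                    n_psc_loci = 2, effect_size_subtype = effect_subtype,
                    seed = seed, ...)
  simulate_cohorts(cfg)
}

# bare genotype matrix around given dosages
make_gm <- function(dosages, genotyped = FALSE, r2 = NULL, chrom = NULL,
                    pos = NULL) {
  m <- ncol(dosages)
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- sprintf("m%03d", seq_len(m))
  }
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("s%04d", seq_len(nrow(dosages)))
  }
  genotype_matrix(dosages, data.frame(
    marker_id = colnames(dosages),
    chrom = chrom %||% rep("1", m),
    pos = pos %||% seq(1e6, by = 1e5, length.out = m),
    allele_risk = "A", allele_nonrisk = "G",
    imputation_r2 = r2 %||% rep(1, m),
    genotyped = rep_len(genotyped, m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# phenotype table for a single cohort from a status vector
make_pheno <- function(status, sample_id = NULL, cohort = "c1", ...) {
  extra <- list(...)
  df <- data.frame(sample_id = sample_id %||% sprintf("s%04d", seq_along(status)),
                   cohort = cohort, status = status,
                   stringsAsFactors = FALSE)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  phenotype_table(df)
}

# brute-force AUROC over all case-control pairs (independent oracle)
auroc_bruteforce <- function(scores, labels, positive = "PSA") {
  pos <- which(as.character(labels) == positive)
  neg <- which(as.character(labels) != positive)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# exact HWE p-value by direct enumeration of the conditional distribution
# (log-factorial form, independent of the package's recurrence)
hwe_enum_p <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  n_a <- 2 * n_hom1 + n_het
  n_b <- 2 * n - n_a
  hets <- seq(min(n_a, n_b) %% 2, min(n_a, n_b), by = 2)
  logp <- vapply(hets, function(h) {
    na_hom <- (n_a - h) / 2
    nb_hom <- (n_b - h) / 2
    lgamma(n + 1) - lgamma(na_hom + 1) - lgamma(h + 1) - lgamma(nb_hom + 1) +
      h * log(2) + lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  sum(prob[prob <= prob[match(n_het, hets)] * (1 + 1e-12)])
}
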