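#' Configuration for the multi-cohort genotype simulator
#'
#' Describes the generative world every downstream stage is tested against:
#' several case-control cohorts sharing a marker panel, psoriasis risk driven
#' by shared loci on an additive-logistic liability, subtype (PsA vs PsC)
#' assigned by a second logistic on subtype-specific loci plus one strong
#' MHC-like locus, mild population structure, and imputation-style dosage
#' noise calibrated to a per-marker r-squared.
#'
#' Per-cohort counts may be vectors (recycled to `n_cohorts`); the default
#' design has three cohorts, the first containing PsA cases but no PsC
#' (mirroring a PsA-only GWAS cohort).
#'
#' @param n_cohorts number of cohorts.
#' @param n_control,n_psa,n_psc,n_unknown per-cohort sample counts
#'   (controls, PsA cases, PsC cases, psoriasis cases of unknown subtype).
#' @param n_markers marker panel size (shared across cohorts).
#' @param maf_range range of simulated minor allele frequencies, in (0, 0.5].
#' @param n_shared_loci,n_psa_loci,n_psc_loci counts of psoriasis-shared,
#'   PsA-specific and PsC-specific causal loci (disjoint marker sets).
#' @param effect_size_shared,effect_size_subtype log odds ratios of shared
#'   and subtype-specific loci.
#' @param mhc_effect log odds ratio of the designated MHC-like locus in the
#'   subtype model (it belongs to both subtype sets, pushing toward PsA).
#' @param n_subpops subpopulations per cohort (population structure).
#' @param fst_like_shift allele-frequency perturbation between subpopulations.
#' @param struct_effect log-odds shift on disease risk for subpopulation 1
#'   (the confounder that genomic control / PC covariates must absorb).
#' @param imputation_r2_range range of per-marker imputation quality r2.
#' @param frac_genotyped fraction of markers emitted as hard-called
#'   (genotyped, r2 = 1) per cohort.
#' @param prevalence marginal psoriasis probability used to centre the
#'   liability intercept (controls only sampling efficiency).
#' @param seed master seed; all randomness derives from it.
#' @return a validated `sim_config` object.
#' @export
sim_config <- function(n_cohorts = 3,
                       n_control = 1000,
                       n_psa = 500,
                       n_psc = c(0, 500, 500),
                       n_unknown = 0,
                       n_markers = 500,
                       maf_range = c(0.05, 0.5),
                       n_shared_loci = 20,
                       n_psa_loci = 5,
                       n_psc_loci = 5,
                       effect_size_shared = 0.3,
                       effect_size_subtype = 0.3,
                       mhc_effect = 0.8,
                       n_subpops = 2,
                       fst_like_shift = 0.02,
                       struct_effect = 0.3,
                       imputation_r2_range = c(0.7, 1),
                       frac_genotyped = 0.2,
                       prevalence = 0.35,
                       seed = 1L) {
  cfg <- list(
    n_cohorts = as.integer(n_cohorts),
    n_control = rep_len(as.integer(n_control), n_cohorts),
    n_psa = rep_len(as.integer(n_psa), n_cohorts),
    n_psc = rep_len(as.integer(n_psc), n_cohorts),
    n_unknown = rep_len(as.integer(n_unknown), n_cohorts),
    n_markers = as.integer(n_markers),
    maf_range = as.numeric(maf_range),
    n_shared_loci = as.integer(n_shared_loci),
    n_psa_loci = as.integer(n_psa_loci),
    n_psc_loci = as.integer(n_psc_loci),
    effect_size_shared = as.numeric(effect_size_shared),
    effect_size_subtype = as.numeric(effect_size_subtype),
    mhc_effect = as.numeric(mhc_effect),
    n_subpops = as.integer(n_subpops),
    fst_like_shift = as.numeric(fst_like_shift),
    struct_effect = as.numeric(struct_effect),
    imputation_r2_range = as.numeric(imputation_r2_range),
    frac_genotyped = as.numeric(frac_genotyped),
    prevalence = as.numeric(prevalence),
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_cohorts < 1) stop("config error: need at least one cohort")
    if (!is_count(c(n_control, n_psa, n_psc, n_unknown, n_markers,
                    n_shared_loci, n_psa_loci, n_psc_loci, n_subpops))) {
      stop("config error: counts must be nonnegative integers")
    }
    # the MHC-like locus occupies one extra marker of its own
    if (n_shared_loci + n_psa_loci + n_psc_loci + 1 > n_markers) {
      stop("config error: causal locus counts exceed n_markers")
    }
    if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2]) {
      stop("config error: maf_range must lie within (0, 0.5]")
    }
    if (length(imputation_r2_range) != 2 || imputation_r2_range[1] <= 0 ||
        imputation_r2_range[2] > 1 ||
        imputation_r2_range[1] > imputation_r2_range[2]) {
      stop("config error: imputation_r2_range must lie within (0, 1]")
    }
    if (n_subpops < 1) stop("config error: n_subpops must be >= 1")
    if (frac_genotyped < 0 || frac_genotyped > 1) {
      stop("config error: frac_genotyped must lie in [0, 1]")
    }
    if (prevalence <= 0 || prevalence >= 1) {
      stop("config error: prevalence must lie in (0, 1)")
    }
  })
  class(cfg) <- "sim_config"
  cfg
}

# draw the marker panel (positions, alleles, causal designations, frequencies)
sim_marker_panel <- function(cfg) {
  m <- cfg$n_markers
  marker_id <- sprintf("mk%05d", seq_len(m))
  chrom <- as.character(sample(1:22, m, replace = TRUE))
  pos <- sample.int(130e6, m, replace = TRUE) + 1e6
  # keep ordinary chromosome-6 markers outside the MHC window, then plant
  # the designated MHC-like locus inside it
  on6 <- chrom == MHC_CHROM & pos >= MHC_START & pos <= MHC_END
  pos[on6] <- pos[on6] + 10e6
  alleles <- t(replicate(m, sample(c("A", "C", "G", "T"), 2)))
  n_causal <- cfg$n_shared_loci + cfg$n_psa_loci + cfg$n_psc_loci + 1
  causal <- sample.int(m, n_causal)
  shared_idx <- causal[seq_len(cfg$n_shared_loci)]
  psa_idx <- causal[cfg$n_shared_loci + seq_len(cfg$n_psa_loci)]
  psc_idx <- causal[cfg$n_shared_loci + cfg$n_psa_loci + seq_len(cfg$n_psc_loci)]
  mhc_idx <- causal[n_causal]
  chrom[mhc_idx] <- MHC_CHROM
  pos[mhc_idx] <- 31e6
  maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  # symmetric subpopulation allele-frequency perturbation
  shift_dir <- sample(c(-1, 1), m, replace = TRUE)
  z <- if (cfg$n_subpops == 1) 0 else seq(-1, 1, length.out = cfg$n_subpops)
  p_sub <- vapply(seq_len(cfg$n_subpops), function(k) {
    clip(maf + shift_dir * z[k] * cfg$fst_like_shift, 0.005, 0.995)
  }, numeric(m)) # m x n_subpops
  beta_cc <- numeric(m)
  beta_cc[shared_idx] <- cfg$effect_size_shared
  beta_sub <- numeric(m)
  beta_sub[psa_idx] <- cfg$effect_size_subtype
  beta_sub[psc_idx] <- -cfg$effect_size_subtype
  beta_sub[mhc_idx] <- cfg$mhc_effect
  list(markers = data.frame(marker_id = marker_id, chrom = chrom, pos = pos,
                            allele_risk = alleles[, 1],
                            allele_nonrisk = alleles[, 2],
                            stringsAsFactors = FALSE),
       maf = maf, p_sub = p_sub, beta_cc = beta_cc, beta_sub = beta_sub,
       shared_idx = shared_idx, psa_idx = psa_idx, psc_idx = psc_idx,
       mhc_idx = mhc_idx)
}

# emit imputation-style dosages: posterior-mean-like shrinkage toward 2*maf
# plus Gaussian jitter sized so that corr^2(dosage, genotype) ~= r2
emit_dosages <- function(G, maf, r2, genotyped) {
  n <- nrow(G)
  m <- ncol(G)
  w <- 1 - r2
  var_g <- 2 * maf * (1 - maf)
  sd_noise <- (1 - w) * sqrt(var_g * (1 - r2) / r2)
  D <- sweep(G, 2, 1 - w, `*`)
  D <- sweep(D, 2, w * 2 * maf, `+`)
  D <- D + sweep(matrix(rnorm(n * m), n, m), 2, sd_noise, `*`)
  D <- clip(D, 0, 2)
  if (any(genotyped)) D[, genotyped] <- G[, genotyped, drop = FALSE]
  D
}

#' Simulate multi-cohort case-control genotype and phenotype data
#'
#' Draws individuals by rejection sampling against the liability model until
#' each cohort's quotas (controls, PsA, PsC, unknown-subtype cases) are
#' filled, then emits imputed-style dosages. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a `cohort_set`: named list with one element per cohort, each a
#'   list with `genotypes` ([genotype_matrix()]) and `phenotypes`
#'   ([phenotype_table()]); the generating truth (causal indices, effect
#'   vectors, true subtype of unknown-status samples) is stored in
#'   `attr(x, "truth")`.
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    panel <- sim_marker_panel(config)
    m <- config$n_markers
    b0 <- qlogis(config$prevalence) -
      sum(panel$beta_cc * 2 * panel$maf) -
      config$struct_effect / config$n_subpops
    a0 <- -sum(panel$beta_sub * 2 * panel$maf)
    cohorts <- list()
    unknown_truth <- list()
    for (ci in seq_len(config$n_cohorts)) {
      cname <- sprintf("cohort%d", ci)
      set.seed(derive_seed(config$seed, ci))
      quota <- c(CONTROL = config$n_control[ci], PSA = config$n_psa[ci],
                 PSC = config$n_psc[ci], UNKNOWN_SUBTYPE = config$n_unknown[ci])
      n_total <- sum(quota)
      G <- matrix(0L, n_total, m)
      status <- character(n_total)
      true_subtype <- character(n_total)
      subpop <- integer(n_total)
      filled <- c(CONTROL = 0L, PSA = 0L, PSC = 0L, UNKNOWN_SUBTYPE = 0L)
      slot <- 0L
      guard <- 0L
      while (any(filled < quota)) {
        guard <- guard + 1L
        if (guard > 4000L) stop("rejection sampling failed to fill quotas")
        B <- 2048L
        sp <- sample.int(config$n_subpops, B, replace = TRUE)
        Gb <- matrix(0L, B, m)
        for (k in seq_len(config$n_subpops)) {
          rows <- which(sp == k)
          if (!length(rows)) next
          Gb[rows, ] <- matrix(
            rbinom(length(rows) * m, 2L, rep(panel$p_sub[, k], each = length(rows))),
            length(rows), m)
        }
        eta_cc <- b0 + as.numeric(Gb %*% panel$beta_cc) +
          config$struct_effect * (sp == 1)
        case <- rbinom(B, 1L, plogis(eta_cc)) == 1L
        eta_sub <- a0 + as.numeric(Gb %*% panel$beta_sub)
        is_psa <- rbinom(B, 1L, plogis(eta_sub)) == 1L
        lab <- ifelse(!case, "CONTROL", ifelse(is_psa, "PSA", "PSC"))
        for (i in seq_len(B)) {
          want <- lab[i]
          take <- NA_character_
          if (filled[want] < quota[want]) {
            take <- want
          } else if (want != "CONTROL" &&
                     filled["UNKNOWN_SUBTYPE"] < quota["UNKNOWN_SUBTYPE"]) {
            take <- "UNKNOWN_SUBTYPE"
          }
          if (is.na(take)) next
          slot <- slot + 1L
          filled[take] <- filled[take] + 1L
          G[slot, ] <- Gb[i, ]
          status[slot] <- take
          true_subtype[slot] <- if (take == "CONTROL") "CONTROL" else lab[i]
          subpop[slot] <- sp[i]
          if (slot == n_total && all(filled >= quota)) break
        }
      }
      r2 <- runif(m, config$imputation_r2_range[1], config$imputation_r2_range[2])
      genotyped <- runif(m) < config$frac_genotyped
      r2[genotyped] <- 1
      D <- emit_dosages(G, panel$maf, r2, genotyped)
      sample_id <- sprintf("%s_s%05d", cname, seq_len(n_total))
      rownames(D) <- sample_id
      colnames(D) <- panel$markers$marker_id
      markers <- panel$markers
      markers$imputation_r2 <- r2
      markers$genotyped <- genotyped
      gm <- genotype_matrix(D, markers)
      pheno <- phenotype_table(data.frame(
        sample_id = sample_id, cohort = cname, status = status,
        pc1 = as.numeric(subpop == 1), stringsAsFactors = FALSE),
        covariates = "pc1")
      cohorts[[cname]] <- list(genotypes = gm, phenotypes = pheno)
      unk <- status == "UNKNOWN_SUBTYPE"
      if (any(unk)) {
        unknown_truth[[cname]] <- data.frame(
          sample_id = sample_id[unk], cohort = cname,
          true_subtype = true_subtype[unk], stringsAsFactors = FALSE)
      }
    }
    truth <- list(
      marker_id = panel$markers$marker_id,
      shared = panel$markers$marker_id[panel$shared_idx],
      psa_specific = panel$markers$marker_id[panel$psa_idx],
      psc_specific = panel$markers$marker_id[panel$psc_idx],
      mhc = panel$markers$marker_id[panel$mhc_idx],
      beta_cc = setNames(panel$beta_cc, panel$markers$marker_id),
      beta_subtype = setNames(panel$beta_sub, panel$markers$marker_id),
      maf = setNames(panel$maf, panel$markers$marker_id),
      unknown_truth = if (length(unknown_truth)) {
        do.call(rbind, unname(unknown_truth))
      } else {
        NULL
      }
    )
    structure(cohorts, class = "cohort_set", truth = truth, config = config)
  })
}

#' @exportS3Method base::print
print.cohort_set <- function(x, ...) {
  cat(sprintf("cohort_set: %d cohort(s)\n", length(x)))
  for (nm in names(x)) {
    ph <- x[[nm]]$phenotypes
    cat(sprintf("  %s: %d samples (%s), %d markers\n", nm, nrow(ph),
                paste(sprintf("%s=%d", names(table(ph$status)), table(ph$status)),
                      collapse = ", "),
                ncol(x[[nm]]$genotypes$dosages)))
  }
  invisible(x)
}

#' Generating truth of a simulated cohort set
#'
#' @param x a `cohort_set` from [simulate_cohorts()].
#' @return list with planted causal marker ids and effect vectors.
#' @export
sim_truth <- function(x) attr(x, "truth")

#' Pool subtype samples of a cohort set into a feature matrix
#'
#' Stacks the dosage rows of all (or selected) cohorts for samples whose
#' status is in `statuses`, restricted to `markers`.
#'
#' @param cohorts a `cohort_set`.
#' @param markers marker ids to keep (NULL = all).
#' @param statuses statuses to keep (default PSA and PSC).
#' @param samples optional sample-id whitelist.
#' @param cohort_names cohorts to use (NULL = all).
#' @return list with `x` (matrix), `status`, `cohort`, `sample_id`.
#' @export
pool_samples <- function(cohorts, markers = NULL,
                         statuses = c("PSA", "PSC"), samples = NULL,
                         cohort_names = NULL) {
  stopifnot(inherits(cohorts, "cohort_set"))
  cohort_names <- cohort_names %||% names(cohorts)
  xs <- list(); st <- list(); co <- list(); id <- list()
  for (nm in cohort_names) {
    ph <- cohorts[[nm]]$phenotypes
    keep <- ph$status %in% statuses
    if (!is.null(samples)) keep <- keep & ph$sample_id %in% samples
    if (!any(keep)) next
    gm <- cohorts[[nm]]$genotypes
    mi <- markers %||% gm$markers$marker_id
    xs[[nm]] <- gm$dosages[keep, mi, drop = FALSE]
    st[[nm]] <- ph$status[keep]
    co[[nm]] <- ph$cohort[keep]
    id[[nm]] <- ph$sample_id[keep]
  }
  if (!length(xs)) stop("no samples matching the requested statuses")
  list(x = do.call(rbind, xs), status = unlist(st, use.names = FALSE),
       cohort = unlist(co, use.names = FALSE),
       sample_id = unlist(id, use.names = FALSE))
}
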