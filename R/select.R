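# Stepwise conditional meta-analysis feature selection.

# per-cohort association for one arm, silently skipping cohorts where the
# contrast is impossible (e.g. the PsA-only cohort for the PsC arm)
assoc_by_cohort <- function(cohorts, case_label, control_label,
                            covariates = NULL, conditioning = character(),
                            markers = NULL, samples = NULL) {
  out <- list()
  for (nm in names(cohorts)) {
    ph <- cohorts[[nm]]$phenotypes
    gm <- cohorts[[nm]]$genotypes
    keep <- rep(TRUE, nrow(ph))
    if (!is.null(samples)) keep <- ph$sample_id %in% samples
    # true controls are never part of the case split, so a sample whitelist
    # (ensemble/LOCO mode) restricts cases only; case-case contrasts
    # (control_label != CONTROL) respect the whitelist for both sides
    if (control_label == "CONTROL") keep <- keep | ph$status == "CONTROL"
    ids <- ph$sample_id[keep & ph$status %in% c(case_label, control_label)]
    if (sum(ph$status[ph$sample_id %in% ids] == case_label) < 1 ||
        sum(ph$status[ph$sample_id %in% ids] == control_label) < 1) {
      out[nm] <- list(NULL)
      next
    }
    gsub <- subset_genotypes(gm, samples = match(ids, rownames(gm$dosages)))
    cov_names <- covariates %||% pheno_covariates(ph)
    out[[nm]] <- logistic_wald(gsub, ph, case_label = case_label,
                               control_label = control_label,
                               covariate_names = cov_names,
                               conditioning_markers = conditioning,
                               markers = markers)
  }
  out
}

#' Indirect PsA-vs-PsC scan across cohorts
#'
#' Runs PsA-vs-control and PsC-vs-control association per cohort
#' (optionally conditioning on previously selected markers), pools each arm
#' by fixed-effects meta-analysis, and computes the indirect case-case
#' chi-square.
#'
#' @param cohorts a `cohort_set`.
#' @param covariates covariate names (NULL = each cohort's declared ones).
#' @param conditioning marker ids conditioned on.
#' @param markers marker ids to test (NULL = all).
#' @param samples optional case sample-id whitelist (controls always used).
#' @param rho assumed log-OR correlation for the indirect statistic.
#' @param gc_correct apply per-cohort genomic control before pooling.
#' @return an `indirect_stat` data.frame (see [indirect_meta()]); the two
#'   arm `meta_result`s are attached as attributes `psa_meta`, `psc_meta`.
#' @export
indirect_scan <- function(cohorts, covariates = NULL,
                          conditioning = character(), markers = NULL,
                          samples = NULL, rho = 0, gc_correct = FALSE) {
  arms <- lapply(c(PSA = "PSA", PSC = "PSC"), function(case) {
    res <- assoc_by_cohort(cohorts, case, "CONTROL", covariates,
                           conditioning, markers, samples)
    res <- res[!vapply(res, is.null, logical(1))]
    if (!length(res)) stop("no cohort usable for the ", case, " arm")
    fixed_effects_meta(res, gc_correct = gc_correct)
  })
  out <- indirect_meta(arms$PSA, arms$PSC, rho = rho)
  attr(out, "psa_meta") <- arms$PSA
  attr(out, "psc_meta") <- arms$PSC
  out
}

#' Median cross-validated AUROC for a marker block
#'
#' Pools PSA/PSC samples across cohorts, restricts to the selected markers,
#' and runs one round of stratified k-fold cross-validation with the named
#' classifier; returns the median of the per-fold AUROCs. Folds lacking a
#' class are skipped with a warning.
#'
#' @param cohorts a `cohort_set`.
#' @param markers selected marker ids (>= 1).
#' @param classifier registry entry (default ridge).
#' @param n_folds folds (default 10).
#' @param samples optional sample-id whitelist.
#' @param seed seed for the fold shuffle.
#' @return median fold AUROC.
#' @export
block_auroc <- function(cohorts, markers, classifier = "ridge",
                        n_folds = 10, samples = NULL, seed = 1L) {
  stopifnot(length(markers) >= 1)
  pool <- pool_samples(cohorts, markers = markers, samples = samples)
  y <- pool$status
  if (length(unique(y)) < 2) stop("both subtypes must be present")
  with_seed(seed, {
    fold <- .strat_folds(y, n_folds)
    aucs <- vapply(seq_len(n_folds), function(f) {
      tr <- fold != f
      if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2) {
        warning("fold ", f, " lacks one class; skipped")
        return(NA_real_)
      }
      m <- train_classifier(classifier, pool$x[tr, , drop = FALSE], y[tr],
                            seed = seed)
      auroc(predict_classifier(m, pool$x[!tr, , drop = FALSE]), y[!tr])
    }, numeric(1))
    if (all(is.na(aucs))) stop("every fold lacked one class")
    median(aucs, na.rm = TRUE)
  })
}

#' Stepwise conditional meta-analysis feature selection
#'
#' Fixes a candidate pool from the unconditional indirect PsA-vs-PsC scan
#' (markers with p <= `p_pool_max`), then iteratively appends the marker
#' with the smallest conditional indirect p-value, conditioning on all
#' previously selected markers. After every `block_size` additions the
#' median cross-validated AUROC of the selected set is evaluated; selection
#' stops when the gain over the previous block is below `min_gain` on
#' `patience` consecutive blocks (plateau), or at `max_markers`, or when
#' the pool is exhausted, or when separation prevents any further
#' conditional fit. Markers whose conditional fit fails in every cohort are
#' removed from the pool. Ties on the minimal conditional p are broken by
#' genomic coordinate, then marker id.
#'
#' @param cohorts a `cohort_set`.
#' @param p_pool_max unconditional-p threshold for the candidate pool.
#' @param block_size markers per evaluation block (default 10).
#' @param min_gain minimal AUROC gain per block (default 0.002, i.e. 0.2%).
#' @param patience consecutive low-gain blocks before stopping (default 3).
#' @param max_markers marker budget (default 200).
#' @param classifier registry entry used by the block evaluator.
#' @param n_folds folds for the block evaluator.
#' @param covariates covariate names (NULL = per-cohort declared ones).
#' @param samples optional sample-id whitelist (selection in ensemble mode
#'   must never touch held-out samples).
#' @param rho,gc_correct passed to [indirect_scan()].
#' @param seed seed for the block evaluator.
#' @return a `conditional_path`: list with `steps` (marker per step with
#'   conditional chi2/p), `blocks` (median CV AUROC trace), `stop_reason`
#'   in `{auroc_plateau, max_markers, pool_exhausted, separation}`, and
#'   `pool` (the initial candidate ids).
#' @export
stepwise_select <- function(cohorts, p_pool_max = 0.05, block_size = 10,
                            min_gain = 0.002, patience = 3,
                            max_markers = 200, classifier = "ridge",
                            n_folds = 10, covariates = NULL, samples = NULL,
                            rho = 0, gc_correct = FALSE, seed = 1L) {
  uncond <- indirect_scan(cohorts, covariates = covariates,
                          samples = samples, rho = rho,
                          gc_correct = gc_correct)
  pool <- uncond$marker_id[is.finite(uncond$p_value) &
                             uncond$p_value <= p_pool_max]
  if (!length(pool)) {
    stop("no candidates at p <= ", p_pool_max, " in the unconditional scan")
  }
  meta <- cohorts[[1]]$genotypes$markers
  coord <- meta[match(pool, meta$marker_id), c("chrom", "pos")]
  selected <- character()
  steps <- list()
  blocks <- list()
  prev_median <- NA_real_
  low_gain_run <- 0L
  stop_reason <- NULL
  remaining <- pool
  while (is.null(stop_reason)) {
    if (!length(remaining)) {
      stop_reason <- "pool_exhausted"
      break
    }
    cond <- indirect_scan(cohorts, covariates = covariates,
                          conditioning = selected, markers = remaining,
                          samples = samples, rho = rho,
                          gc_correct = gc_correct)
    usable <- is.finite(cond$p_value)
    if (!any(usable)) {
      # every remaining candidate failed its conditional fit
      stop_reason <- "separation"
      break
    }
    # drop permanently failed candidates (separation / collinearity)
    failed <- cond$marker_id[!usable]
    remaining <- setdiff(remaining, failed)
    cand <- cond[usable, , drop = FALSE]
    ci <- match(cand$marker_id, pool)
    o <- order(cand$p_value, coord$chrom[ci], coord$pos[ci], cand$marker_id)
    pick <- cand[o[1], , drop = FALSE]
    selected <- c(selected, pick$marker_id)
    remaining <- setdiff(remaining, pick$marker_id)
    steps[[length(steps) + 1]] <- data.frame(
      step = length(selected), marker_id = pick$marker_id,
      chi2 = pick$chi2, p_value = pick$p_value, stringsAsFactors = FALSE)
    if (length(selected) %% block_size == 0) {
      med <- block_auroc(cohorts, selected, classifier = classifier,
                         n_folds = n_folds, samples = samples,
                         seed = derive_seed(seed, length(selected)))
      gain <- if (is.na(prev_median)) NA_real_ else med - prev_median
      blocks[[length(blocks) + 1]] <- data.frame(
        block = length(blocks) + 1L, n_markers = length(selected),
        median_auroc = med, gain = gain)
      if (!is.na(gain) && gain < min_gain) {
        low_gain_run <- low_gain_run + 1L
        if (low_gain_run >= patience) stop_reason <- "auroc_plateau"
      } else {
        low_gain_run <- 0L
      }
      prev_median <- med
    }
    if (is.null(stop_reason) && length(selected) >= max_markers) {
      stop_reason <- "max_markers"
    }
  }
  structure(list(
    steps = if (length(steps)) do.call(rbind, steps) else
      data.frame(step = integer(), marker_id = character(),
                 chi2 = numeric(), p_value = numeric()),
    blocks = if (length(blocks)) do.call(rbind, blocks) else
      data.frame(block = integer(), n_markers = integer(),
                 median_auroc = numeric(), gain = numeric()),
    stop_reason = stop_reason, pool = pool,
    selected = selected), class = "conditional_path")
}

#' @exportS3Method base::print
print.conditional_path <- function(x, ...) {
  cat(sprintf("conditional_path: %d marker(s) selected from a pool of %d (stop: %s)\n",
              length(x$selected), length(x$pool), x$stop_reason))
  if (nrow(x$blocks)) {
    cat("block AUROC trace:\n")
    print(x$blocks, row.names = FALSE)
  }
  invisible(x)
}
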