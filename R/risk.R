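#' Class-conditional score densities
#'
#' Gaussian kernel density estimates of the classifier score within each
#' subtype, fitted on cross-validation scores only (never on test or
#' unknown-sample scores). Bandwidth follows Silverman's rule per class.
#'
#' @param cv_scores numeric classifier scores from cross-validation.
#' @param cv_labels matching labels (PSA/PSC).
#' @param bandwidth_rule bandwidth selector passed to [stats::density()]
#'   (default `"nrd0"`, Silverman).
#' @param n_grid evaluation grid size.
#' @return a `score_densities` object with per-class grids/densities and
#'   the training score range used for clipping.
#' @export
fit_densities <- function(cv_scores, cv_labels, bandwidth_rule = "nrd0",
                          n_grid = 512) {
  lab <- as.character(cv_labels)
  stopifnot(length(cv_scores) == length(lab))
  for (cl in c("PSA", "PSC")) {
    s <- cv_scores[lab == cl]
    if (length(s) < 10) stop("need >= 10 scores per class (", cl, ")")
    if (sd(s) == 0) {
      stop("zero-variance scores in class ", cl,
           "; jitter the scores or use a richer classifier")
    }
  }
  rng <- range(cv_scores)
  fit1 <- function(cl) {
    s <- cv_scores[lab == cl]
    d <- density(s, bw = bandwidth_rule, n = n_grid,
                 from = rng[1] - 3 * stats::bw.nrd0(s),
                 to = rng[2] + 3 * stats::bw.nrd0(s))
    list(x = d$x, y = d$y)
  }
  structure(list(psa = fit1("PSA"), psc = fit1("PSC"), range = rng),
            class = "score_densities")
}

# integrate a fitted density over its grid (trapezoid)
density_integral <- function(d) {
  sum(diff(d$x) * (head(d$y, -1) + tail(d$y, -1)) / 2)
}

.eval_density <- function(d, s) {
  approx(d$x, d$y, xout = s, rule = 2)$y
}

#' Posterior PsA probability from a classifier score
#'
#' Bayes' rule over the two class-conditional score densities:
#' `P(PsA|s) = d(s|PsA) P(PsA) / (d(s|PsA) P(PsA) + d(s|PsC) P(PsC))`,
#' with `P(PsC) = 1 - P(PsA)`. Scores outside the training range are
#' evaluated at the clipped boundary (KDE tails underflow to zero and would
#' otherwise yield 0/0); if both densities vanish at a clipped score the
#' prior is returned with a warning.
#'
#' @param s numeric score(s).
#' @param densities a [fit_densities()] object.
#' @param prior_psa prior PsA prevalence in (0, 1).
#' @return posterior probabilities in `[0, 1]`.
#' @export
posterior_risk <- function(s, densities, prior_psa) {
  stopifnot(inherits(densities, "score_densities"),
            prior_psa > 0, prior_psa < 1)
  sc <- clip(s, densities$range[1], densities$range[2])
  da <- .eval_density(densities$psa, sc)
  dc <- .eval_density(densities$psc, sc)
  num <- da * prior_psa
  den <- num + dc * (1 - prior_psa)
  out <- ifelse(den > 0, num / den, prior_psa)
  if (any(den == 0)) {
    warning("both class densities are zero at ", sum(den == 0),
            " score(s); returning the prior there")
  }
  out
}

#' Calibration curve
#'
#' Bins predicted probabilities over `[0, 1]` and reports, per occupied
#' bin, the mean prediction and the empirical PsA fraction.
#'
#' @param posteriors predicted probabilities.
#' @param true_labels matching labels.
#' @param n_bins number of equal-width bins (default 10).
#' @param positive PsA-like label.
#' @return data.frame: `bin`, `mean_predicted`, `empirical_fraction`,
#'   `count` (empty bins kept with count 0 and missing summaries).
#' @export
calibration_curve <- function(posteriors, true_labels, n_bins = 10,
                              positive = "PSA") {
  stopifnot(all(posteriors >= 0 & posteriors <= 1))
  pos <- as.character(true_labels) == positive
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(findInterval(posteriors, edges, rightmost.closed = TRUE), n_bins)
  out <- data.frame(bin = seq_len(n_bins),
                    lower = edges[-length(edges)], upper = edges[-1],
                    mean_predicted = NA_real_, empirical_fraction = NA_real_,
                    count = 0L)
  for (b in unique(bin)) {
    w <- bin == b
    out$mean_predicted[b] <- mean(posteriors[w])
    out$empirical_fraction[b] <- mean(pos[w])
    out$count[b] <- sum(w)
  }
  out
}

#' Mean absolute calibration error over occupied bins
#'
#' @param curve output of [calibration_curve()].
#' @return weighted mean of |mean predicted - empirical fraction|.
#' @export
calibration_error <- function(curve) {
  occ <- curve$count > 0
  sum(abs(curve$mean_predicted[occ] - curve$empirical_fraction[occ]) *
        curve$count[occ]) / sum(curve$count[occ])
}

#' Posterior PsA risk for unknown-subtype patients
#'
#' Scores psoriasis patients of unknown subtype with a trained classifier
#' and converts the scores to posterior PsA probabilities under each prior
#' prevalence in `priors`.
#'
#' @param genotypes a [genotype_matrix()] (or plain matrix) holding the
#'   unknown-subtype samples; must contain every model marker.
#' @param model a `classifier_model`.
#' @param densities CV-score densities from [fit_densities()].
#' @param priors prior PsA prevalences (default 10/20/30/40%).
#' @param high_risk thresholds reported in the summary attribute.
#' @return a `risk_profile` data.frame: `sample_id`, `score`, one
#'   `posterior_<prior>` column per prior; counts of samples above each
#'   `high_risk` threshold (at each prior) in `attr(, "high_risk_counts")`.
#' @export
assess_unknowns <- function(genotypes, model, densities,
                            priors = c(0.10, 0.20, 0.30, 0.40),
                            high_risk = c(0.80, 0.98)) {
  x <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages else
    as.matrix(genotypes)
  if (nrow(x) == 0) {
    out <- data.frame(sample_id = character(), score = numeric())
    for (pr in priors) out[[sprintf("posterior_%g", pr)]] <- numeric()
    class(out) <- c("risk_profile", "data.frame")
    return(out)
  }
  miss <- setdiff(model$markers, colnames(x))
  if (length(miss)) {
    stop("genotypes lack model marker(s): ", paste(miss, collapse = ", "))
  }
  score <- predict_classifier(model, x)
  out <- data.frame(sample_id = rownames(x) %||% sprintf("s%05d", seq_len(nrow(x))),
                    score = score, stringsAsFactors = FALSE)
  for (pr in priors) {
    out[[sprintf("posterior_%g", pr)]] <- posterior_risk(score, densities, pr)
  }
  counts <- sapply(priors, function(pr) {
    sapply(high_risk, function(th) sum(out[[sprintf("posterior_%g", pr)]] > th))
  })
  dimnames(counts) <- list(paste0(">", high_risk), sprintf("prior_%g", priors))
  class(out) <- c("risk_profile", "data.frame")
  attr(out, "high_risk_counts") <- counts
  out
}
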