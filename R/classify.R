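#' Area under the receiver operator curve
#'
#' Mann-Whitney concordance probability: the chance a random positive
#' outscores a random negative, ties counted one half.
#'
#' @param scores numeric scores, higher = more positive-like.
#' @param labels class labels.
#' @param positive label treated as positive (default "PSA").
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels, positive = "PSA") {
  stopifnot(length(scores) == length(labels))
  pos <- as.character(labels) == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

#' Precision, recall and specificity at the top k percent
#'
#' Samples are ranked by score (descending; ties broken by stable sample-id
#' order) and the top `ceiling(k/100 * n)` are called PsA.
#'
#' @param scores numeric scores, higher = more PsA-like.
#' @param labels class labels.
#' @param k_percent vector of percentages in (0, 100].
#' @param ids sample ids for deterministic tie-breaking (defaults to input
#'   order).
#' @param positive the PsA-like label.
#' @return data.frame with one row per k: `k_percent`, `n_called`,
#'   `true_positives`, `precision`, `recall`, `specificity`.
#' @export
topk_metrics <- function(scores, labels, k_percent = c(5, 10, 20),
                         ids = NULL, positive = "PSA") {
  stopifnot(all(k_percent > 0), all(k_percent <= 100))
  n <- length(scores)
  ids <- ids %||% sprintf("s%06d", seq_len(n))
  pos <- as.character(labels) == positive
  o <- order_by_score_desc(scores, ids)
  if (anyDuplicated(scores)) {
    message("topk_metrics: score ties broken by stable sample-id order")
  }
  res <- lapply(k_percent, function(k) {
    n_called <- min(n, ceiling(k / 100 * n))
    called <- o[seq_len(n_called)]
    tp <- sum(pos[called])
    data.frame(k_percent = k, n_called = n_called, true_positives = tp,
               precision = tp / n_called, recall = tp / sum(pos),
               specificity = sum(!pos[-called]) / sum(!pos))
  })
  do.call(rbind, res)
}

#' Training/test split plan
#'
#' Holds out `test_frac` of the subtyped samples as a test set with a fixed
#' PsA fraction (default 30%, the assumed PsA prevalence among psoriasis
#' patients, i.e. a 3:7 PsA:PsC ratio), balances the remaining training
#' samples to an even subtype proportion by subsampling the majority class,
#' and assigns stratified cross-validation folds (per cohort and subtype).
#' Deterministic given `seed`.
#'
#' @param pheno a [phenotype_table()] (or data.frame with `sample_id`,
#'   `cohort`, `status`); only PSA/PSC rows are used.
#' @param test_frac fraction of subtyped samples held out.
#' @param test_psa_frac PsA fraction of the test set.
#' @param folds number of cross-validation folds.
#' @param seed integer seed.
#' @return a `split_plan`: list with `test_ids`, `train_ids`, `fold`
#'   (named integer vector over training ids), and the parameters.
#' @export
make_split <- function(pheno, test_frac = 0.10, test_psa_frac = 0.30,
                       folds = 10, seed = 1L) {
  df <- as.data.frame(pheno)
  df <- df[df$status %in% c("PSA", "PSC"), , drop = FALSE]
  n <- nrow(df)
  n_psa <- sum(df$status == "PSA")
  n_psc <- sum(df$status == "PSC")
  n_test <- round(test_frac * n)
  n_test_psa <- round(test_psa_frac * n_test)
  n_test_psc <- n_test - n_test_psa
  if (n_test_psa < 1 || n_test_psc < 1 || n_test_psa > n_psa ||
      n_test_psc > n_psc) {
    stop(sprintf(paste0("infeasible split: need >= %d PsA and >= %d PsC for the ",
                        "test set (have %d and %d)"),
                 max(1, n_test_psa), max(1, n_test_psc), n_psa, n_psc))
  }
  with_seed(seed, {
    psa_ids <- sample(df$sample_id[df$status == "PSA"])
    psc_ids <- sample(df$sample_id[df$status == "PSC"])
    test_ids <- c(psa_ids[seq_len(n_test_psa)], psc_ids[seq_len(n_test_psc)])
    psa_rem <- setdiff(psa_ids, test_ids)
    psc_rem <- setdiff(psc_ids, test_ids)
    n_bal <- min(length(psa_rem), length(psc_rem))
    if (n_bal < folds) {
      stop(sprintf("infeasible split: balanced training has %d per class, need >= %d",
                   n_bal, folds))
    }
    train_ids <- c(psa_rem[seq_len(n_bal)], psc_rem[seq_len(n_bal)])
    # stratified fold assignment preserving per-cohort composition
    tr <- df[match(train_ids, df$sample_id), c("sample_id", "cohort", "status")]
    fold <- integer(nrow(tr))
    names(fold) <- tr$sample_id
    for (grp in split(seq_len(nrow(tr)), paste(tr$cohort, tr$status))) {
      fold[grp] <- sample(rep_len(seq_len(folds), length(grp)))
    }
    structure(list(test_ids = sort(test_ids), train_ids = sort(train_ids),
                   fold = fold, folds = folds, test_frac = test_frac,
                   test_psa_frac = test_psa_frac, seed = as.integer(seed)),
              class = "split_plan")
  })
}

# stratified fold ids for a label vector
.strat_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    w <- which(y == cl)
    fold[w] <- sample(rep_len(seq_len(folds), length(w)))
  }
  fold
}

#' Repeated stratified cross-validation of a registered classifier
#'
#' Each trial reshuffles the fold assignment with a seed derived from
#' `seed`, trains on the remaining folds and scores the held-out fold; the
#' trial AUROC is the mean across fold AUROCs.
#'
#' @param model_name registry entry.
#' @param x feature matrix.
#' @param y labels (PSA/PSC).
#' @param folds folds per trial (default 10).
#' @param trials number of repeats (default 50).
#' @param seed master seed.
#' @param positive PsA-like label.
#' @return list with `mean_auroc`, `trial_auroc` (one value per trial) and
#'   `sd_auroc`.
#' @export
cross_validate <- function(model_name, x, y, folds = 10, trials = 50,
                           seed = 1L, positive = "PSA") {
  .check_model_name(model_name)
  x <- as.matrix(x)
  y <- as.character(y)
  trial_auroc <- vapply(seq_len(trials), function(t) {
    tseed <- derive_seed(seed, t)
    with_seed(tseed, {
      fold <- .strat_folds(y, folds)
      aucs <- vapply(seq_len(folds), function(f) {
        tr <- fold != f
        if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2) {
          return(NA_real_)
        }
        m <- train_classifier(model_name, x[tr, , drop = FALSE], y[tr],
                              positive = positive, seed = tseed)
        auroc(predict_classifier(m, x[!tr, , drop = FALSE]), y[!tr],
              positive = positive)
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    })
  }, numeric(1))
  list(mean_auroc = mean(trial_auroc), trial_auroc = trial_auroc,
       sd_auroc = sd(trial_auroc))
}

#' Elastic-net model on association-prefiltered markers
#'
#' Restricts the feature matrix to markers passing an association p-value
#' threshold, fits a regularized logistic path, and reports the nonzero-
#' coefficient marker count and cross-validated AUROC along the path.
#'
#' @param x feature matrix (all markers).
#' @param y labels.
#' @param p_values named numeric vector of per-marker association p-values.
#' @param p_max prefilter threshold (default 0.05).
#' @param alpha elastic-net mixing (default 0.5).
#' @param nlambda path length.
#' @param folds folds for the path AUROC.
#' @param seed seed for fold shuffling.
#' @param positive PsA-like label.
#' @return list with `fit` (glmnet object), `markers` (prefiltered ids) and
#'   `path` (data.frame: `lambda`, `n_nonzero`, `auroc_cv`).
#' @export
elastic_net_model <- function(x, y, p_values, p_max = 0.05, alpha = 0.5,
                              nlambda = 50, folds = 5, seed = 1L,
                              positive = "PSA") {
  stopifnot(p_max > 0, p_max <= 1)
  keep <- names(p_values)[is.finite(p_values) & p_values <= p_max]
  keep <- intersect(colnames(x), keep)
  if (!length(keep)) stop("no markers pass the association prefilter")
  xs <- as.matrix(x)[, keep, drop = FALSE]
  y01 <- as.integer(as.character(y) == positive)
  fit <- glmnet::glmnet(xs, y01, family = "binomial", alpha = alpha,
                        nlambda = nlambda)
  lambda <- fit$lambda
  oof <- matrix(NA_real_, nrow(xs), length(lambda))
  with_seed(seed, {
    fold <- .strat_folds(y01, folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      ffit <- glmnet::glmnet(xs[tr, , drop = FALSE], y01[tr],
                             family = "binomial", alpha = alpha,
                             lambda = lambda)
      oof[!tr, ] <- predict(ffit, xs[!tr, , drop = FALSE], type = "response")
    }
  })
  auroc_cv <- apply(oof, 2, function(s) auroc(s, y01, positive = 1))
  list(fit = fit, markers = keep,
       path = data.frame(lambda = lambda,
                         n_nonzero = fit$df,
                         auroc_cv = auroc_cv))
}
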