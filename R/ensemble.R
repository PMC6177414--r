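# Tenfold ensemble with per-fold conditional selection, rank combination,
# and leave-one-cohort-out evaluation.

#' Train a fold-ensemble of selection + classification models
#'
#' Holds out a common test set (3:7 PsA:PsC by default), partitions the
#' remaining subtyped samples into `folds` disjoint folds preserving the
#' per-cohort subtype composition, and — separately within each fold —
#' runs stepwise conditional selection and trains one classifier on that
#' fold's samples with its own marker list. No member ever sees the test
#' set during selection or training (audited by sample id).
#'
#' @param cohorts a `cohort_set`.
#' @param test_frac held-out fraction (default 0.10).
#' @param test_psa_frac PsA fraction of the test set (default 0.30).
#' @param folds ensemble size (default 10).
#' @param classifier registry entry for the member models.
#' @param select_params named list of overrides passed to
#'   [stepwise_select()] (e.g. `max_markers`, `block_size`).
#' @param seed master seed.
#' @return an `ensemble_model`: list of `members` (each with `markers`,
#'   `model`, `sample_ids`), `test_ids`, `combination = "mean_rank"`.
#' @export
ensemble_train <- function(cohorts, test_frac = 0.10, test_psa_frac = 0.30,
                           folds = 10, classifier = "ridge",
                           select_params = list(), seed = 1L) {
  pool <- pool_samples(cohorts)
  df <- data.frame(sample_id = pool$sample_id, cohort = pool$cohort,
                   status = pool$status, stringsAsFactors = FALSE)
  n_test <- round(test_frac * nrow(df))
  n_test_psa <- round(test_psa_frac * n_test)
  if (n_test_psa < 1 || n_test - n_test_psa < 1) stop("infeasible test split")
  with_seed(seed, {
    psa_ids <- sample(df$sample_id[df$status == "PSA"])
    psc_ids <- sample(df$sample_id[df$status == "PSC"])
    if (length(psa_ids) < n_test_psa || length(psc_ids) < n_test - n_test_psa) {
      stop("not enough subtyped samples for the requested test ratio")
    }
    test_ids <- c(psa_ids[seq_len(n_test_psa)],
                  psc_ids[seq_len(n_test - n_test_psa)])
    rest <- df[!df$sample_id %in% test_ids, ]
    fold <- integer(nrow(rest))
    names(fold) <- rest$sample_id
    for (grp in split(seq_len(nrow(rest)), paste(rest$cohort, rest$status))) {
      fold[grp] <- sample(rep_len(seq_len(folds), length(grp)))
    }
    members <- vector("list", folds)
    for (f in seq_len(folds)) {
      ids <- names(fold)[fold == f]
      st <- rest$status[match(ids, rest$sample_id)]
      if (sum(st == "PSA") < 2 || sum(st == "PSC") < 2) {
        stop("fold ", f, " has fewer than 2 samples in one class")
      }
      stopifnot(!any(ids %in% test_ids)) # test-set isolation audit
      args <- modifyList(list(cohorts = cohorts, samples = ids,
                              classifier = classifier,
                              seed = derive_seed(seed, f)),
                         select_params)
      path <- do.call(stepwise_select, args)
      fx <- pool_samples(cohorts, markers = path$selected, samples = ids)
      model <- train_classifier(classifier, fx$x, fx$status,
                                seed = derive_seed(seed, 1000L + f))
      members[[f]] <- list(fold = f, markers = path$selected, model = model,
                           sample_ids = sort(ids), path = path)
    }
    structure(list(members = members, test_ids = sort(test_ids),
                   fold = fold, combination = "mean_rank",
                   classifier = classifier, seed = as.integer(seed)),
              class = "ensemble_model")
  })
}

#' Combine per-member scores by mean rank
#'
#' Within each member, test samples are ranked by score (rank 1 = most
#' PsA-like; ties broken by stable sample id); the combined score is the
#' negative mean rank across members rescaled to `[0, 1]`.
#'
#' @param scores samples x members numeric matrix with sample ids as row
#'   names; every member must score every sample (no missing entries).
#' @return data.frame ordered by combined rank: `sample_id`, `mean_rank`,
#'   `combined_score`.
#' @export
rank_combine <- function(scores) {
  scores <- as.matrix(scores)
  if (anyNA(scores)) stop("every member must score every sample")
  n <- nrow(scores)
  ids <- rownames(scores) %||% sprintf("s%05d", seq_len(n))
  rk <- apply(scores, 2, function(s) {
    o <- order_by_score_desc(s, ids)
    r <- integer(n); r[o] <- seq_len(n); r
  })
  mean_rank <- rowMeans(rk)
  combined <- if (n > 1) (n - mean_rank) / (n - 1) else rep(1, n)
  out <- data.frame(sample_id = ids, mean_rank = mean_rank,
                    combined_score = combined, stringsAsFactors = FALSE)
  out[order(out$mean_rank, out$sample_id), , drop = FALSE]
}

#' Score the common test set with an ensemble
#'
#' @param em an `ensemble_model`.
#' @param cohorts the `cohort_set` it was trained on.
#' @return the [rank_combine()] table over the test samples, with the true
#'   labels attached as column `status`.
#' @export
predict_ensemble <- function(em, cohorts) {
  stopifnot(inherits(em, "ensemble_model"))
  test <- pool_samples(cohorts, samples = em$test_ids)
  scores <- vapply(em$members, function(mb) {
    predict_classifier(mb$model, test$x[, mb$markers, drop = FALSE])
  }, numeric(length(test$sample_id)))
  rownames(scores) <- test$sample_id
  out <- rank_combine(scores)
  out$status <- test$status[match(out$sample_id, test$sample_id)]
  out
}

#' Leave-one-cohort-out evaluation
#'
#' Each cohort containing both subtypes is left out in turn; stepwise
#' selection and classifier training run on the remaining cohorts, and the
#' model is scored on the left-out cohort's subtyped samples. Cohorts
#' lacking one subtype cannot serve as a test cohort and are skipped with a
#' notice.
#'
#' @param cohorts a `cohort_set` (>= 2 cohorts).
#' @param classifier registry entry.
#' @param select_params overrides for [stepwise_select()].
#' @param seed master seed.
#' @return data.frame: `cohort`, `auroc`, `n_test`, `skipped`.
#' @export
leave_one_cohort_out <- function(cohorts, classifier = "ridge",
                                 select_params = list(), seed = 1L) {
  if (length(cohorts) < 2) stop("need at least two cohorts")
  res <- list()
  for (nm in names(cohorts)) {
    st <- cohorts[[nm]]$phenotypes$status
    if (sum(st == "PSA") == 0 || sum(st == "PSC") == 0) {
      message("leave_one_cohort_out: skipping ", nm,
              " (lacks one subtype, cannot be a test cohort)")
      res[[nm]] <- data.frame(cohort = nm, auroc = NA_real_, n_test = 0L,
                              skipped = TRUE)
      next
    }
    train_cohorts <- structure(cohorts[names(cohorts) != nm],
                               class = "cohort_set")
    args <- modifyList(list(cohorts = train_cohorts, classifier = classifier,
                            seed = derive_seed(seed, match(nm, names(cohorts)))),
                       select_params)
    path <- do.call(stepwise_select, args)
    tr <- pool_samples(train_cohorts, markers = path$selected)
    model <- train_classifier(classifier, tr$x, tr$status, seed = seed)
    te <- pool_samples(cohorts, markers = path$selected, cohort_names = nm)
    res[[nm]] <- data.frame(cohort = nm,
                            auroc = auroc(predict_classifier(model, te$x),
                                          te$status),
                            n_test = length(te$sample_id), skipped = FALSE)
  }
  out <- do.call(rbind, res)
  if (all(out$skipped)) stop("no cohort with both subtypes to leave out")
  rownames(out) <- NULL
  out
}
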