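# Classifier registry: each entry wraps fit/predict behind a uniform
# interface. Scores are oriented so that larger = more PsA-like; entries
# emitting class probabilities return P(PsA). Default hyperparameters are
# fixed here and documented in the registry table.

# deterministic internal fold ids for cv.glmnet (avoids consuming RNG)
.det_foldid <- function(y, nfolds) {
  id <- integer(length(y))
  for (cl in unique(y)) {
    w <- which(y == cl)
    id[w] <- rep_len(seq_len(nfolds), length(w))
  }
  id
}

.fit_glmnet_cv <- function(x, y01, alpha, nfolds = 5) {
  pad <- ncol(x) < 2 # glmnet requires >= 2 columns
  if (pad) x <- cbind(x, .pad = 0)
  cv <- glmnet::cv.glmnet(x, y01, family = "binomial", alpha = alpha,
                          nfolds = nfolds, foldid = .det_foldid(y01, nfolds),
                          standardize = TRUE)
  list(cv = cv, s = cv$lambda.min, pad = pad)
}

.predict_glmnet_cv <- function(fit, x) {
  if (isTRUE(fit$pad)) x <- cbind(x, .pad = 0)
  as.numeric(predict(fit$cv, x, s = fit$s, type = "response"))
}

.fit_lda <- function(x, y01) {
  MASS::lda(x, grouping = factor(y01, levels = c(0, 1)))
}

# shrinkage discriminant analysis: LDA with the pooled within-class
# covariance shrunk toward a scaled identity, intensity set by the
# Ledoit-Wolf analytic formula (no tuning).
.fit_sda <- function(x, y01) {
  mu0 <- colMeans(x[y01 == 0, , drop = FALSE])
  mu1 <- colMeans(x[y01 == 1, , drop = FALSE])
  Z <- rbind(sweep(x[y01 == 0, , drop = FALSE], 2, mu0),
             sweep(x[y01 == 1, , drop = FALSE], 2, mu1))
  n <- nrow(Z); p <- ncol(Z)
  S <- crossprod(Z) / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - diag(mu, p))^2)
  zz2 <- rowSums(Z^2)
  zSz <- rowSums((Z %*% S) * Z)
  b2bar <- (sum(zz2^2) - 2 * sum(zSz) + n * sum(S^2)) / n^2
  b2 <- min(b2bar, d2)
  gamma <- if (d2 > 0) b2 / d2 else 1
  Sigma <- (1 - gamma) * S + gamma * diag(mu, p)
  w <- solve(Sigma, mu1 - mu0)
  c0 <- as.numeric(crossprod(w, (mu1 + mu0) / 2)) -
    log(sum(y01 == 1) / sum(y01 == 0))
  list(w = w, c0 = c0, gamma = gamma)
}

# gradient-boosted decision stumps (least-squares fit to the logistic
# gradient), the documented stand-in for a conditional inference forest
.fit_gbstump <- function(x, y01, n_rounds = 200, shrinkage = 0.1,
                         min_leaf = 10) {
  x <- unname(as.matrix(x)); y01 <- unname(y01)
  n <- nrow(x); p <- ncol(x)
  ord <- apply(x, 2, order)
  f0 <- qlogis(clip(mean(y01), 1e-6, 1 - 1e-6))
  f <- rep(f0, n)
  stumps <- matrix(NA_real_, n_rounds, 4,
                   dimnames = list(NULL, c("feature", "threshold", "left", "right")))
  for (m in seq_len(n_rounds)) {
    r <- y01 - plogis(f)
    best <- c(sse = Inf, j = NA, thr = NA, left = NA, right = NA)
    tot <- sum(r)
    for (j in seq_len(p)) {
      o <- ord[, j]
      xv <- x[o, j]
      cs <- cumsum(r[o])
      valid <- which(diff(xv) > 0)
      valid <- valid[valid >= min_leaf & valid <= n - min_leaf]
      if (!length(valid)) next
      nl <- valid
      sse_red <- cs[valid]^2 / nl + (tot - cs[valid])^2 / (n - nl)
      b <- which.max(sse_red)
      if (-sse_red[[b]] < best[["sse"]]) {
        k <- valid[b]
        best <- c(sse = -sse_red[[b]], j = j, thr = (xv[[k]] + xv[[k + 1]]) / 2,
                  left = cs[[k]] / k, right = (tot - cs[[k]]) / (n - k))
      }
    }
    if (!is.finite(best[["sse"]])) break
    stumps[m, ] <- best[c("j", "thr", "left", "right")]
    j <- best[["j"]]
    f <- f + shrinkage *
      ifelse(x[, j] <= best[["thr"]], best[["left"]], best[["right"]])
  }
  list(f0 = f0, stumps = stumps[!is.na(stumps[, 1]), , drop = FALSE],
       shrinkage = shrinkage)
}

.predict_gbstump <- function(fit, x) {
  f <- rep(fit$f0, nrow(x))
  st <- fit$stumps
  for (m in seq_len(nrow(st))) {
    f <- f + fit$shrinkage *
      ifelse(x[, st[m, "feature"]] <= st[m, "threshold"],
             st[m, "left"], st[m, "right"])
  }
  plogis(f)
}

.fit_nbayes <- function(x, y01) {
  eps <- 1e-6
  stat <- function(cls) {
    xs <- x[y01 == cls, , drop = FALSE]
    list(mean = colMeans(xs), var = apply(xs, 2, var) + eps)
  }
  list(s0 = stat(0), s1 = stat(1),
       logprior = log(mean(y01) / (1 - mean(y01))))
}

.predict_nbayes <- function(fit, x) {
  ll <- fit$logprior
  for (j in seq_len(ncol(x))) {
    ll <- ll +
      dnorm(x[, j], fit$s1$mean[j], sqrt(fit$s1$var[j]), log = TRUE) -
      dnorm(x[, j], fit$s0$mean[j], sqrt(fit$s0$var[j]), log = TRUE)
  }
  plogis(ll)
}

.REGISTRY <- list(
  ridge = list(
    label = "logistic ridge regression",
    defaults = "alpha = 0; lambda chosen by 5-fold internal CV (deterministic folds)"),
  enet = list(
    label = "elastic-net logistic regression",
    defaults = "alpha = 0.5; lambda chosen by 5-fold internal CV (deterministic folds)"),
  lda = list(
    label = "linear discriminant analysis",
    defaults = "MASS::lda, empirical priors, pooled covariance"),
  sda = list(
    label = "shrinkage discriminant analysis",
    defaults = "LDA with Ledoit-Wolf shrinkage of the pooled covariance toward a scaled identity"),
  rf = list(
    label = "random forest (in-package CART forest)",
    defaults = "ntree = 500, mtry = floor(sqrt(p)), min_node = 5, max_depth = 25, Gini splits"),
  gbstump = list(
    label = "gradient-boosted stumps (conditional-inference-forest stand-in)",
    defaults = "200 rounds, shrinkage 0.1, min leaf 10, logistic loss"),
  nbayes = list(
    label = "Gaussian naive Bayes",
    defaults = "per-class feature means/variances, variance floor 1e-6")
)

#' Available classifiers
#'
#' The registry holds the classifier families benchmarked by the pipeline;
#' every entry is trained through [train_classifier()] with the fixed
#' default hyperparameters listed here ("default parameters throughout").
#'
#' @return data.frame with columns `name`, `label`, `defaults`.
#' @export
classifier_registry <- function() {
  data.frame(name = names(.REGISTRY),
             label = vapply(.REGISTRY, `[[`, "", "label"),
             defaults = vapply(.REGISTRY, `[[`, "", "defaults"),
             row.names = NULL, stringsAsFactors = FALSE)
}

.check_model_name <- function(name) {
  if (!name %in% names(.REGISTRY)) {
    stop("unknown classifier '", name, "'; registry: ",
         paste(names(.REGISTRY), collapse = ", "))
  }
}

#' Train a registered classifier
#'
#' @param name registry entry (see [classifier_registry()]).
#' @param x numeric feature matrix (samples x markers).
#' @param y labels; `positive` is scored high.
#' @param positive the PsA-like class label (default "PSA").
#' @param seed seed for stochastic learners (forest).
#' @return a `classifier_model` with the fitted object and the marker names
#'   it expects.
#' @export
train_classifier <- function(name, x, y, positive = "PSA", seed = 1L) {
  .check_model_name(name)
  x <- as.matrix(x)
  y01 <- as.integer(as.character(y) == positive)
  if (length(unique(y01)) < 2) stop("training labels contain a single class")
  fit <- switch(name,
    ridge = .fit_glmnet_cv(x, y01, alpha = 0),
    enet = .fit_glmnet_cv(x, y01, alpha = 0.5),
    lda = .fit_lda(x, y01),
    sda = .fit_sda(x, y01),
    rf = .rf_fit(x, y01, ntree = 500L, mtry = max(1L, floor(sqrt(ncol(x)))),
                 min_node = 5L, max_depth = 25L, seed = as.integer(seed)),
    gbstump = .fit_gbstump(x, y01),
    nbayes = .fit_nbayes(x, y01)
  )
  structure(list(name = name, fit = fit, markers = colnames(x),
                 positive = positive),
            class = "classifier_model")
}

#' Score samples with a trained classifier
#'
#' @param model a `classifier_model` from [train_classifier()].
#' @param x feature matrix; must contain the model's markers.
#' @return numeric scores, higher = more PsA-like (probability scale where
#'   the learner provides one).
#' @export
predict_classifier <- function(model, x) {
  stopifnot(inherits(model, "classifier_model"))
  x <- as.matrix(x)
  if (!is.null(model$markers)) {
    miss <- setdiff(model$markers, colnames(x))
    if (length(miss)) {
      stop("feature matrix lacks model marker(s): ", paste(miss, collapse = ", "))
    }
    x <- x[, model$markers, drop = FALSE]
  }
  as.numeric(switch(model$name,
    ridge = .predict_glmnet_cv(model$fit, x),
    enet = .predict_glmnet_cv(model$fit, x),
    lda = predict(model$fit, x)$posterior[, "1"],
    sda = plogis(as.numeric(x %*% model$fit$w) - model$fit$c0),
    rf = .rf_predict(model$fit, x),
    gbstump = .predict_gbstump(model$fit, x),
    nbayes = .predict_nbayes(model$fit, x)
  ))
}
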