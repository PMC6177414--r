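test_that("auroc equals brute-force pair counting (oracle)", {
  # worked example: 8 of 9 concordant pairs
  s <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  y <- c("PSA", "PSA", "PSA", "PSC", "PSC", "PSC")
  expect_equal(auroc(s, y), 8 / 9)
  expect_equal(auroc(y == "PSA", y), 1) # scores = labels
  expect_equal(auroc(rep(1, 6), y), 0.5) # all ties
  expect_error(auroc(1:3, rep("PSA", 3)), "both classes")
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:200, 1)
    s <- sample(round(rnorm(n), 2)) # rounding forces ties
    y <- sample(c("PSA", "PSC"), n, replace = TRUE,
                prob = c(0.4, 0.6))
    if (length(unique(y)) < 2) next
    expect_equal(auroc(s, y), auroc_bruteforce(s, y))
  }
})

test_that("topk metrics follow the ranking arithmetic", {
  # perfect scores at k = prevalence
  y <- c(rep("PSA", 30), rep("PSC", 70))
  s <- c(rep(1, 30), rep(0, 70)) + seq(0.001, 0.1, length.out = 100)
  tk <- topk_metrics(s, y, k_percent = 30)
  expect_equal(tk$precision, 1)
  expect_equal(tk$recall, 1)
  expect_equal(tk$specificity, 1)
  # k = 100%: everyone called, precision = prevalence
  tk100 <- topk_metrics(s, y, k_percent = 100)
  expect_equal(tk100$recall, 1)
  expect_equal(tk100$precision, 0.3)
  expect_equal(tk100$specificity, 0)
  # random scores: precision ~ prevalence
  set.seed(32)
  n <- 1e4
  y <- sample(c(rep("PSA", 0.3 * n), rep("PSC", 0.7 * n)))
  tk10 <- topk_metrics(rnorm(n), y, k_percent = 10)
  expect_equal(tk10$precision, 0.3, tolerance = 0.1)
  # recall is monotone non-decreasing in k
  ks <- c(5, 10, 20, 50, 100)
  tks <- topk_metrics(rnorm(n), y, k_percent = ks)
  expect_true(all(diff(tks$recall) >= 0))
  # ties at the cutoff break by stable id order
  s <- c(1, 1, 1, 0)
  suppressMessages(
    t1 <- topk_metrics(s, c("PSA", "PSC", "PSA", "PSC"), k_percent = 50,
                       ids = c("a", "b", "c", "d")))
  expect_equal(t1$n_called, 2) # calls a and b
  expect_equal(t1$true_positives, 1)
})

test_that("make_split honours the stated ratios and is deterministic", {
  ph <- make_pheno(c(rep("PSA", 1000), rep("PSC", 1000)),
                   sample_id = sprintf("x%04d", 1:2000))
  sp <- make_split(ph, seed = 77)
  expect_equal(length(sp$test_ids), 200)
  st <- ph$status[match(sp$test_ids, ph$sample_id)]
  expect_equal(sum(st == "PSA"), 60)
  expect_equal(sum(st == "PSC"), 140)
  expect_length(intersect(sp$test_ids, sp$train_ids), 0)
  # balanced training set
  st_tr <- ph$status[match(sp$train_ids, ph$sample_id)]
  expect_equal(sum(st_tr == "PSA"), sum(st_tr == "PSC"))
  # folds partition the training ids
  expect_setequal(names(sp$fold), sp$train_ids)
  expect_equal(sort(unique(sp$fold)), 1:10)
  # determinism
  sp2 <- make_split(ph, seed = 77)
  expect_identical(sp, sp2)
  expect_false(identical(sp$test_ids, make_split(ph, seed = 78)$test_ids))
  # infeasible ratios
  ph_bad <- make_pheno(c(rep("PSA", 10), rep("PSC", 1000)))
  expect_error(make_split(ph_bad), "infeasible")
})

test_that("the registry lists the required families and all entries learn", {
  reg <- classifier_registry()
  expect_true(all(c("ridge", "enet", "lda", "sda", "rf", "gbstump") %in%
                    reg$name))
  expect_true(all(nzchar(reg$defaults)))
  expect_error(train_classifier("nope", matrix(0, 2, 2), c("PSA", "PSC")),
               "registry")
  set.seed(33)
  n <- 240
  x <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, sprintf("f%d", 1:6)))
  y <- ifelse(x[, 1] + 0.8 * x[, 2] + rnorm(n, 0, 0.7) > 0, "PSA", "PSC")
  for (nm in reg$name) {
    m <- train_classifier(nm, x, y, seed = 5)
    a <- auroc(predict_classifier(m, x), y)
    expect_gt(a, 0.75) # every family learns an easy linear signal
  }
})

test_that("forest predictions are invariant to monotone feature transforms", {
  set.seed(34)
  n <- 200
  x <- matrix(abs(rnorm(n * 4)) + 0.1, n, 4,
              dimnames = list(NULL, sprintf("f%d", 1:4)))
  y <- ifelse(x[, 1] > median(x[, 1]), "PSA", "PSC")
  m1 <- train_classifier("rf", x, y, seed = 11)
  x2 <- log(x) # strictly monotone transform
  colnames(x2) <- colnames(x)
  m2 <- train_classifier("rf", x2, y, seed = 11)
  expect_equal(auroc(predict_classifier(m1, x), y),
               auroc(predict_classifier(m2, x2), y), tolerance = 1e-9)
})

test_that("cross_validate is reproducible and null-calibrated", {
  set.seed(35)
  n <- 600
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, sprintf("f%d", 1:3)))
  y <- sample(c("PSA", "PSC"), n, replace = TRUE)
  cv1 <- cross_validate("lda", x, y, folds = 5, trials = 4, seed = 9)
  cv2 <- cross_validate("lda", x, y, folds = 5, trials = 4, seed = 9)
  expect_identical(cv1$trial_auroc, cv2$trial_auroc)
  expect_equal(cv1$mean_auroc, 0.5, tolerance = 0.07)
  # informative features clear the permutation null
  y2 <- ifelse(x[, 1] + rnorm(n, 0, 0.6) > 0, "PSA", "PSC")
  cv3 <- cross_validate("lda", x, y2, folds = 5, trials = 4, seed = 9)
  expect_gt(cv3$mean_auroc, 0.7)
  expect_error(cross_validate("nope", x, y), "registry")
})

test_that("elastic net path behaves at its limits and recovers planted markers", {
  set.seed(36)
  n <- 400
  p <- 60
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("m%02d", 1:p)))
  beta <- numeric(p)
  planted <- c(3, 11, 25, 40, 55)
  beta[planted] <- 0.9
  y <- ifelse(as.numeric(x %*% beta) + rnorm(n) > 0, "PSA", "PSC")
  pvals <- setNames(rep(0.01, p), colnames(x))
  en <- elastic_net_model(x, y, pvals, seed = 4)
  # lambda -> infinity: zero nonzero coefficients at the path head
  expect_equal(en$path$n_nonzero[1], 0)
  # planted markers enter before >= 90% of null markers
  entry <- apply(glmnet::coef.glmnet(en$fit)[-1, ] != 0, 1, function(r) {
    w <- which(r); if (length(w)) min(w) else Inf
  })
  null_entry <- entry[-planted]
  expect_gte(mean(max(entry[planted]) <= null_entry), 0.9)
  # near-unpenalized fit matches plain logistic AUROC
  xs <- x[, 1:5]
  y2 <- ifelse(xs[, 1] + rnorm(n, 0, 0.8) > 0, "PSA", "PSC")
  en2 <- elastic_net_model(xs, y2, setNames(rep(0.01, 5), colnames(xs)),
                           seed = 4, nlambda = 80)
  glm_fit <- glm((y2 == "PSA") ~ xs, family = binomial())
  a_glm <- auroc(fitted(glm_fit), y2)
  a_en <- auroc(predict(en2$fit, xs, s = min(en2$fit$lambda),
                        type = "response"), y2)
  expect_equal(a_en, a_glm, tolerance = 0.01)
  # empty prefilter errors
  expect_error(elastic_net_model(x, y, setNames(rep(1, p), colnames(x)),
                                 p_max = 0.001), "prefilter")
})
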