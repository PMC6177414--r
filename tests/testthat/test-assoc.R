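test_that("HWE exact test matches direct enumeration and the worked cases", {
  # perfect Hardy-Weinberg proportions
  expect_equal(hwe_exact_p(25, 50, 25), 1)
  # total heterozygote deficit is vanishingly unlikely
  expect_lt(hwe_exact_p(50, 0, 50), 1e-6)
  # enumeration oracle across random genotype tables
  set.seed(11)
  for (i in 1:25) {
    n <- sample(20:300, 1)
    p <- runif(1, 0.05, 0.5)
    g <- rbinom(n, 2, p)
    tab <- tabulate(g + 1, 3)
    expect_equal(hwe_exact_p(tab[1], tab[2], tab[3]),
                 hwe_enum_p(tab[1], tab[2], tab[3]), tolerance = 1e-9)
  }
})

test_that("marker_qc applies MAF, call-rate and HWE filters and is idempotent", {
  set.seed(2)
  n <- 400
  d <- cbind(
    ok = rbinom(n, 2, 0.3),
    rare = rbinom(n, 2, 0.005), # MAF ~0.005 < 0.01
    holes = ifelse(runif(n) < 0.10, NA, rbinom(n, 2, 0.3)), # call rate ~0.9
    badhwe = c(rep(0, n / 2), rep(2, n / 2)) # no heterozygotes
  )
  g <- make_gm(d, genotyped = TRUE)
  q <- suppressMessages(marker_qc(g))
  expect_identical(q$markers$marker_id, "ok")
  rep <- attr(q, "qc_report")
  expect_equal(rep$n_failed[rep$criterion == "maf"], 1)
  expect_equal(rep$n_failed[rep$criterion == "call_rate"], 1)
  expect_equal(rep$n_failed[rep$criterion == "hwe"], 1)
  # idempotence
  q2 <- suppressMessages(marker_qc(q))
  expect_identical(q$dosages, q2$dosages)
  # imputed-only markers skip HWE
  g_imp <- make_gm(matrix(as.numeric(c(rep(0, n / 2), rep(2, n / 2)))),
                   genotyped = FALSE, r2 = 0.9)
  expect_equal(ncol(suppressMessages(marker_qc(g_imp))$dosages), 1)
})

test_that("logistic Wald equals the 2x2 closed form on a binary predictor", {
  # worked example: cases 60/40, controls 40/60 carriers
  d <- matrix(c(rep(1, 60), rep(0, 40), rep(1, 40), rep(0, 60)), ncol = 1)
  g <- make_gm(d, genotyped = TRUE)
  ph <- make_pheno(c(rep("PSA", 100), rep("CONTROL", 100)))
  res <- logistic_wald(g, ph)
  expect_equal(res$beta, log(60 * 60 / (40 * 40)), tolerance = 1e-6)
  expect_equal(res$se, sqrt(1 / 60 + 1 / 40 + 1 / 40 + 1 / 60),
               tolerance = 1e-6)
  expect_equal(res$p_value, 2 * pnorm(-abs(res$beta / res$se)))
  # property: random 2x2 tables agree with the closed form to 1e-6
  set.seed(4)
  for (i in 1:20) {
    k <- sample(10:80, 4, replace = TRUE) # a,b,c,d cell counts
    d <- matrix(c(rep(1, k[1]), rep(0, k[2]), rep(1, k[3]), rep(0, k[4])),
                ncol = 1)
    g <- make_gm(d, genotyped = TRUE)
    ph <- make_pheno(c(rep("PSA", k[1] + k[2]), rep("CONTROL", k[3] + k[4])))
    res <- logistic_wald(g, ph)
    expect_equal(res$beta, log(k[1] * k[4] / (k[2] * k[3])), tolerance = 1e-6)
    expect_equal(res$se, sqrt(sum(1 / k)), tolerance = 1e-6)
  }
})

test_that("monomorphic markers are skipped and separation is flagged", {
  set.seed(5)
  n <- 80
  d <- cbind(mono = rep(2, n), sep = c(rep(0, n / 2), rep(2, n / 2)))
  g <- make_gm(d, genotyped = TRUE)
  ph <- make_pheno(c(rep("PSA", n / 2), rep("CONTROL", n / 2)))
  res <- logistic_wald(g, ph)
  expect_equal(res$reason[res$marker_id == "mono"], "monomorphic")
  sep <- res[res$marker_id == "sep", ]
  expect_false(sep$converged)
  expect_true(is.na(sep$p_value))
})

test_that("conditioning excludes the marker itself and flags perfect proxies", {
  set.seed(6)
  n <- 200
  x <- rbinom(n, 2, 0.4)
  d <- cbind(causal = x, proxy = x, indep = rbinom(n, 2, 0.4))
  g <- make_gm(d, genotyped = TRUE)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x))
  ph <- make_pheno(ifelse(y == 1, "PSA", "CONTROL"))
  res <- logistic_wald(g, ph, conditioning_markers = "causal")
  expect_false("causal" %in% res$marker_id)
  prox <- res[res$marker_id == "proxy", ]
  expect_true(!prox$converged || prox$p_value > 0.99)
  expect_true(res$converged[res$marker_id == "indep"])
})

test_that("type-I error is nominal under permuted labels", {
  set.seed(8)
  n <- 400
  m <- 1000
  d <- matrix(rbinom(n * m, 2, 0.3), n, m)
  g <- make_gm(d, genotyped = TRUE)
  ph <- make_pheno(sample(rep(c("PSA", "CONTROL"), n / 2)))
  res <- logistic_wald(g, ph)
  frac <- mean(res$p_value <= 0.05, na.rm = TRUE)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("genomic inflation behaves as the chi-square median ratio", {
  expect_equal(genomic_inflation(rep(0.5, 7)), 1, tolerance = 1e-12)
  set.seed(9)
  expect_equal(genomic_inflation(runif(1e5)), 1, tolerance = 0.02)
  chi <- 1.5 * rchisq(2e5, 1)
  p <- pchisq(chi, 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(p), 1.5, tolerance = 0.03)
  expect_error(genomic_inflation(NA_real_), "p-values")
})

test_that("the subpopulation covariate absorbs stratification (lambda falls)", {
  cs <- simulate_cohorts(sim_config(
    n_cohorts = 1, n_control = 800, n_psa = 400, n_psc = 400,
    n_markers = 300, n_shared_loci = 0, n_psa_loci = 0, n_psc_loci = 0,
    mhc_effect = 0, fst_like_shift = 0.08, struct_effect = 0.8,
    frac_genotyped = 1, seed = 17))
  g <- cs$cohort1$genotypes
  ph <- cs$cohort1$phenotypes
  raw <- logistic_wald(g, ph, case_label = "PSA")
  adj <- logistic_wald(g, ph, case_label = "PSA", covariate_names = "pc1")
  l_raw <- genomic_inflation(raw$p_value)
  l_adj <- genomic_inflation(adj$p_value)
  expect_gt(l_raw, 1.05)
  expect_lt(l_adj, l_raw)
  expect_lt(abs(l_adj - 1), abs(l_raw - 1))
})
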