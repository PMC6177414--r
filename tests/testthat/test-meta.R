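# helper: assoc_result-shaped rows from explicit estimates
mk_assoc <- function(ids, beta, se, n_cases = 100, n_controls = 100) {
  structure(data.frame(
    marker_id = ids, beta = beta, se = se, wald_z = beta / se,
    p_value = 2 * pnorm(-abs(beta / se)), case_af = 0.3, control_af = 0.25,
    n_cases = n_cases, n_controls = n_controls, converged = TRUE,
    reason = NA_character_, stringsAsFactors = FALSE),
    class = c("assoc_result", "data.frame"))
}

test_that("inverse-variance pooling matches the hand-computed example", {
  r1 <- mk_assoc("m1", 0.2, 0.1) # V = 0.01
  r2 <- mk_assoc("m1", 0.5, 0.2) # V = 0.04
  meta <- fixed_effects_meta(list(a = r1, b = r2))
  expect_equal(meta$beta_meta, 0.26, tolerance = 1e-12)
  expect_equal(meta$se_meta, sqrt(1 / 125), tolerance = 1e-12)
  expect_equal(meta$z, 0.26 / sqrt(1 / 125), tolerance = 1e-12)
  expect_equal(meta$p_value, 2 * pnorm(-0.26 / sqrt(1 / 125)),
               tolerance = 1e-9)
  expect_equal(meta$direction, "++")
})

test_that("single-cohort meta is the identity and pooling shrinks the se", {
  r <- mk_assoc(c("m1", "m2"), c(0.3, -0.1), c(0.12, 0.2))
  meta <- fixed_effects_meta(list(only = r))
  expect_equal(meta$beta_meta, r$beta)
  expect_equal(meta$se_meta, r$se)
  expect_equal(meta$p_value, r$p_value)
  expect_equal(meta$direction, c("+", "-"))
  # two equal-variance opposite effects cancel
  sym <- fixed_effects_meta(list(a = mk_assoc("m1", 0.4, 0.1),
                                 b = mk_assoc("m1", -0.4, 0.1)))
  expect_equal(sym$beta_meta, 0)
  expect_equal(sym$p_value, 1)
  # se_meta never exceeds the smallest contributing se
  set.seed(1)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    res <- lapply(seq_len(k), function(j) mk_assoc("m", rnorm(1), runif(1, 0.05, 0.3)))
    names(res) <- paste0("c", seq_len(k))
    m <- fixed_effects_meta(res)
    expect_lte(m$se_meta, min(vapply(res, function(r) r$se, numeric(1))))
  }
})

test_that("pooling is invariant to cohort order and marks unusable cohorts '?'", {
  r1 <- mk_assoc(c("m1", "m2"), c(0.2, 0.1), c(0.1, 0.1))
  r2 <- mk_assoc("m1", 0.4, 0.15) # m2 absent from cohort b
  m_ab <- fixed_effects_meta(list(a = r1, b = r2))
  m_ba <- fixed_effects_meta(list(b = r2, a = r1))
  expect_equal(m_ab$beta_meta[m_ab$marker_id == "m1"],
               m_ba$beta_meta[m_ba$marker_id == "m1"])
  row_m2 <- m_ab[m_ab$marker_id == "m2", ]
  expect_equal(row_m2$direction, "+?")
  expect_equal(row_m2$n_cohorts_used, 1)
  # non-converged estimates are unusable
  r3 <- mk_assoc("m1", 0.4, 0.15)
  r3$converged <- FALSE
  m <- fixed_effects_meta(list(a = r1, b = r3))
  expect_equal(m$direction[m$marker_id == "m1"], "+?")
})

test_that("genomic control inflates but never deflates", {
  set.seed(2)
  deflated <- mk_assoc(sprintf("m%d", 1:200), rnorm(200, 0, 0.01),
                       rep(0.3, 200)) # lambda << 1
  m <- fixed_effects_meta(list(a = deflated), gc_correct = TRUE)
  expect_equal(unname(attr(m, "lambda_applied")["a"]), 1) # floored at 1
  expect_equal(m$se_meta, deflated$se)
  infl <- mk_assoc(sprintf("m%d", 1:200), rnorm(200, 0, 0.6), rep(0.3, 200))
  m2 <- fixed_effects_meta(list(a = infl), gc_correct = TRUE)
  lam <- unname(attr(m2, "lambda_applied")["a"])
  expect_gt(lam, 1)
  expect_equal(m2$se_meta, infl$se * sqrt(lam))
})

test_that("indirect statistic matches the worked examples and edge rules", {
  psa <- fixed_effects_meta(list(a = mk_assoc("m1", 0.3, 0.1)))
  psc <- fixed_effects_meta(list(a = mk_assoc("m1", 0.3, 0.1)))
  ind <- indirect_meta(psa, psc)
  expect_equal(ind$chi2, 0)
  expect_equal(ind$p_value, 1)
  # chi2 = (0.3-0.1)^2 / 0.02 = 2, p ~ 0.1573
  psa <- fixed_effects_meta(list(a = mk_assoc("m1", 0.3, 0.1)))
  psc <- fixed_effects_meta(list(a = mk_assoc("m1", 0.1, 0.1)))
  ind0 <- indirect_meta(psa, psc, rho = 0)
  expect_equal(ind0$chi2, 2, tolerance = 1e-12)
  expect_equal(ind0$p_value, pchisq(2, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(ind0$p_value, 4), 0.1573)
  ind5 <- indirect_meta(psa, psc, rho = 0.5)
  expect_equal(ind5$chi2, 4, tolerance = 1e-12)
  expect_error(indirect_meta(psa, psc, rho = 1.2), "rho")
  expect_error(indirect_meta(psa, psc, rho = 1), "denominator")
})

test_that("rho = 0 is conservative: chi2 non-decreasing over a rho grid", {
  set.seed(3)
  for (i in 1:10) {
    psa <- fixed_effects_meta(list(a = mk_assoc("m1", rnorm(1), runif(1, 0.05, 0.3))))
    psc <- fixed_effects_meta(list(a = mk_assoc("m1", rnorm(1), runif(1, 0.05, 0.3))))
    chi <- vapply(seq(0, 0.9, by = 0.15),
                  function(r) indirect_meta(psa, psc, rho = r)$chi2, numeric(1))
    expect_true(all(diff(chi) >= -1e-12))
  }
})

test_that("markers usable in only one arm get a missing indirect p", {
  psa <- fixed_effects_meta(list(a = mk_assoc(c("m1", "m2"), c(0.2, 0.3), c(0.1, 0.1))))
  psc <- fixed_effects_meta(list(a = mk_assoc("m1", 0.1, 0.1)))
  ind <- indirect_meta(psa, psc)
  expect_true(is.na(ind$p_value[ind$marker_id == "m2"]))
  expect_false(is.na(ind$p_value[ind$marker_id == "m1"]))
})

test_that("direct case-case meta excludes ineligible cohorts", {
  ok <- mk_assoc("m1", 0.3, 0.1)
  psa_only <- mk_assoc("m1", 0.3, 0.1, n_controls = 0) # no PsC samples
  expect_message(m <- direct_case_case_meta(list(good = ok, psaonly = psa_only)),
                 "psaonly")
  expect_equal(m$n_cohorts_used, 1)
  expect_equal(m$beta_meta, ok$beta)
  expect_error(direct_case_case_meta(list(a = psa_only)), "no cohort")
  # single eligible cohort: identity
  m1 <- suppressMessages(direct_case_case_meta(list(g = ok, b = NULL)))
  expect_equal(m1$beta_meta, ok$beta)
})

test_that("direct and indirect meta rank a planted subtype locus first", {
  cs <- simulate_cohorts(sim_config(
    n_cohorts = 2, n_control = 400, n_psa = 400, n_psc = 400,
    n_markers = 80, n_shared_loci = 5, n_psa_loci = 1, n_psc_loci = 0,
    effect_size_subtype = 0.9, mhc_effect = 0, seed = 23))
  locus <- sim_truth(cs)$psa_specific
  ind <- indirect_scan(cs)
  expect_equal(ind$marker_id[which.min(ind$p_value)], locus)
  cc <- assoc_by_cohort <- lapply(cs, function(co) {
    logistic_wald(co$genotypes, co$phenotypes, case_label = "PSA",
                  control_label = "PSC", covariate_names = "pc1")
  })
  dm <- direct_case_case_meta(cc)
  expect_equal(dm$marker_id[which.min(dm$p_value)], locus)
})

test_that("METAL files round-trip and harmonize flipped alleles", {
  r <- mk_assoc(c("m1", "m2", "m3"), c(0.2, -0.1, 0.05), c(0.1, 0.12, 0.2))
  meta <- fixed_effects_meta(list(a = r))
  markers <- data.frame(marker_id = c("m1", "m2", "m3"),
                        allele_risk = c("A", "C", "T"),
                        allele_nonrisk = c("G", "T", "A"))
  f <- tempfile(fileext = ".metal")
  write_metal(meta, markers, f)
  back <- read_metal(f, markers)
  expect_equal(back$beta_meta, meta$beta_meta, tolerance = 1e-12)
  expect_equal(back$p_value, meta$p_value, tolerance = 1e-12)
  # swap alleles on disk: effect must flip on harmonized read
  txt <- readLines(f)
  fields <- strsplit(txt[2], "\t")[[1]]
  fields[c(2, 3)] <- fields[c(3, 2)]
  txt[2] <- paste(fields, collapse = "\t")
  writeLines(txt, f)
  flipped <- read_metal(f, markers)
  expect_equal(flipped$beta_meta[flipped$marker_id == "m1"],
               -meta$beta_meta[meta$marker_id == "m1"])
  # unmatchable alleles are dropped with a warning
  fields <- strsplit(txt[3], "\t")[[1]]
  fields[2] <- "T"
  txt[3] <- paste(fields, collapse = "\t")
  writeLines(txt, f)
  expect_warning(dropped <- read_metal(f, markers), "alleles")
  expect_false("m2" %in% dropped$marker_id)
})
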