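test_that("Plackett root reduces to independence at psi = 1 and hits targets", {
  expect_equal(plackett_p11(0.3, 0.2, 1), 0.06)
  for (case in list(c(0.057, 0.057, 2^2.768), c(0.3, 0.4, 5),
                    c(0.2, 0.7, 0.25))) {
    p11 <- plackett_p11(case[1], case[2], case[3])
    p10 <- case[1] - p11; p01 <- case[2] - p11; p00 <- 1 - p11 - p10 - p01
    expect_equal(p11 * p00 / (p10 * p01), case[3], tolerance = 1e-9)
    expect_gte(p11, max(0, case[1] + case[2] - 1))
    expect_lte(p11, min(case[1], case[2]))
  }
  expect_error(plackett_p11(0.3, 0.2, -1), "psi")
})

test_that("realized joint frequency converges to the solved p11", {
  spec <- cohort_spec(n_samples = 1e6,
                      alteration_marginals = c(a = 0.057, b = 0.057),
                      pair_targets = data.frame(gene_a = "a", gene_b = "b",
                                                odds_ratio = 2^2.768),
                      seed = 61)
  alt <- generate_paired_alterations(spec)
  p11_hat <- mean(alt$altered["A", ] & alt$altered["B", ])
  # 3-decimal agreement: the Monte-Carlo sd at 1e6 draws is ~1.2e-4
  expect_lt(abs(p11_hat - plackett_p11(0.057, 0.057, 2^2.768)), 5e-4)
})

test_that("identical spec and seed give bit-identical cohorts", {
  spec <- cohort_spec(n_samples = 60,
                      alteration_marginals = c(g1 = 0.1, g2 = 0.2), seed = 62)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$expr$values, c2$expr$values)
  expect_identical(c1$alt$altered, c2$alt$altered)
  expect_identical(c1$clin, c2$clin)
})

test_that("per-gene alteration frequencies respect the spec marginals", {
  n <- 4000
  spec <- cohort_spec(n_samples = n,
                      alteration_marginals = c(a = 0.2, b = 0.1, c = 0.05),
                      pair_targets = data.frame(gene_a = "a", gene_b = "b",
                                                odds_ratio = 4),
                      seed = 63)
  alt <- generate_paired_alterations(spec)
  for (g in c("A", "B", "C")) {
    target <- spec$alteration_marginals[[tolower(g)]]
    f <- as.numeric(alteration_frequency(alt, g))
    expect_lt(abs(f - target), 3 * sqrt(target * (1 - target) / n))
  }
})

test_that("incompatible marginal/odds-ratio combinations are rejected", {
  spec <- cohort_spec(n_samples = 10,
                      alteration_marginals = c(a = 0.5, b = 0.5),
                      pair_targets = data.frame(gene_a = "a", gene_b = "c",
                                                odds_ratio = 2),
                      seed = 64)
  expect_error(generate_paired_alterations(spec), "without marginal")
  expect_error(cohort_spec(alteration_marginals = c(a = 1.2)), "marginals")
  expect_error(cohort_spec(pair_targets = data.frame(gene_a = "a", gene_b = "b",
                                                     odds_ratio = -2)),
               "odds ratio")
})

test_that("exponential survival reproduces the ln2/h medians and HR split", {
  spec <- cohort_spec(n_samples = 2000, baseline_hazard = log(2) / 60,
                      hazard_ratio = 2, censor_horizon = 1e9, seed = 65)
  samples <- sprintf("S%03d", 1:2000)
  altered <- samples[1:1000]
  clin <- generate_survival(spec, altered)
  km_alt <- km_estimate(clin$os_months[clin$sample %in% altered],
                        clin$os_event[clin$sample %in% altered])
  km_un <- km_estimate(clin$os_months[!clin$sample %in% altered],
                       clin$os_event[!clin$sample %in% altered])
  expect_lt(abs(km_alt$median - 30) / 30, 0.15)
  expect_lt(abs(km_un$median - 60) / 60, 0.15)
})

test_that("phenotype proportions must sum to one and cover all classes", {
  expect_error(cohort_spec(phenotype_proportions = c(N = 0.5, BS = 0.6, L = 0,
                                                     LI = 0, LP = 0)),
               "sum to 1")
  expect_error(cohort_spec(phenotype_proportions = c(N = 0.5, BS = 0.5)),
               "phenotype_proportions")
})

test_that("cell-line profiles are exact centroids at zero noise", {
  spec <- cohort_spec(seed = 66)
  profs <- generate_cellline_profiles(spec, "BS", noise_sd = 0, k = 2)
  expect_length(profs, 2)
  centroid <- 2^spec$genes$mean_BS
  expect_equal(unname(profs[[1]]$copies), centroid)
  expect_equal(attr(profs[[1]], "true_phenotype"), "BS")
  expect_length(generate_cellline_profiles(spec, "BS", 0.5, 0), 0)
  expect_error(generate_cellline_profiles(spec, "XX", 0.5, 1), "unknown phenotype")
})

test_that("null phenotype structure keeps the F-test size near alpha", {
  # 1000 flat genes: rejection rate at alpha = 0.05 should stay in its
  # binomial band (the genes are independent given the phenotype draw)
  spec <- cohort_spec(n_samples = 404,
                      genes = default_gene_panel(n_bsn_high = 0, n_lp_high = 0,
                                                 n_flat = 1000),
                      seed = 67)
  coh <- generate_cohort(spec)
  res <- tk_panel_f_tests(coh$expr, coh$clin, toupper(spec$genes$gene))
  rate <- mean(res$p < 0.05)
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("a group1-like shifted gene is recovered as group1 across seeds", {
  hits <- 0
  for (s in 1:20) {
    spec <- cohort_spec(n_samples = 404,
                        genes = default_gene_panel(n_bsn_high = 1, n_lp_high = 0,
                                                   n_flat = 0, delta = 1),
                        seed = 100 + s)
    coh <- generate_cohort(spec)
    res <- tk_panel_f_tests(coh$expr, coh$clin, "G1TK1")
    asg <- assign_tk_groups(res, 1e-4, 1e-4, 0.044)
    if (asg$group[1] == "group1") hits <- hits + 1
  }
  expect_gte(hits / 20, 0.95)
})
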