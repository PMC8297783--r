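test_that("F and R^2 satisfy the exact one-way ANOVA identity", {
  coh <- make_phenotype_cohort(
    n_per_class = 10,
    means = matrix(c(5, 5, 5.5, 5.5, 6), 1, 5,
                   dimnames = list("G", c("N", "BS", "L", "LI", "LP"))),
    seed = 41)
  res <- three_group_f_test(coh$expr, coh$clin, "G")
  n <- 50
  expect_equal(res$F, (res$r2 / 2) / ((1 - res$r2) / (n - 3)))
  expect_equal(res$df2, n - 3)
})

test_that("a constant gene gives F = 0, R^2 = 0 and no direction", {
  vals <- matrix(3, 1, 20, dimnames = list("FLAT", sprintf("s%02d", 1:20)))
  clin <- make_clin(sprintf("s%02d", 1:20), rep(c("N", "BS", "L", "LI", "LP"), 4))
  res <- three_group_f_test(expression_matrix(vals, "raw"), clin, "FLAT")
  expect_equal(res$F, 0)
  expect_equal(res$r2, 0)
  expect_equal(res$direction, "none")
  expect_equal(res$p, 1)
})

test_that("the F test reduces to the squared t statistic with 2 supergroups", {
  set.seed(43)
  n <- 30
  samples <- sprintf("s%02d", 1:n)
  phen <- rep(c("BS", "LP"), each = n / 2)
  y <- rnorm(n, mean = ifelse(phen == "BS", 1, 0))
  vals <- matrix(y, 1, n, dimnames = list("G", samples))
  clin <- make_clin(samples, phen)
  two_scheme <- c(LP = "LP", LI = "LIL", L = "LIL", BS = "BSN", N = "BSN")
  res <- three_group_f_test(expression_matrix(vals, "zscore"), clin, "G",
                            scheme = two_scheme)
  tt <- t.test(y[phen == "BS"], y[phen == "LP"], var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2)
})

test_that("a BS/N-shifted gene is called high_in_BSN", {
  means <- matrix(5, 1, 5, dimnames = list("G1", c("N", "BS", "L", "LI", "LP")))
  means[, c("N", "BS")] <- 6
  coh <- make_phenotype_cohort(30, means, seed = 44)
  res <- three_group_f_test(coh$expr, coh$clin, "G1")
  expect_equal(res$direction, "high_in_BSN")
})

test_that("a synthetic 4/3/3 panel is assigned to groups 1/2/3", {
  spec <- cohort_spec(n_samples = 404, seed = 45)
  coh <- generate_cohort(spec)
  genes <- toupper(spec$genes$gene)
  res <- tk_panel_f_tests(coh$expr, coh$clin, genes)
  asg <- assign_tk_groups(res, p_max = 1e-4, q_max = 1e-4, r2_min = 0.044)
  counts <- attr(asg, "counts")
  expect_equal(unname(counts["group1"]), 4)
  expect_equal(unname(counts["group2"]), 3)
  expect_equal(unname(counts["group3"]), 3)
  expect_setequal(asg$gene[asg$group == "group1"], paste0("G1TK", 1:4))
  expect_setequal(asg$gene[asg$group == "group2"], paste0("G2TK", 1:3))
})

test_that("unattainable thresholds send every gene to group 3", {
  spec <- cohort_spec(n_samples = 100, seed = 46)
  coh <- generate_cohort(spec)
  res <- tk_panel_f_tests(coh$expr, coh$clin, toupper(spec$genes$gene))
  asg <- assign_tk_groups(res, p_max = 0, q_max = 0)
  expect_true(all(asg$group == "group3"))
})

test_that("assignment is stable under sample and gene reordering", {
  spec <- cohort_spec(n_samples = 150, seed = 47)
  coh <- generate_cohort(spec)
  genes <- toupper(spec$genes$gene)
  a1 <- assign_tk_groups(tk_panel_f_tests(coh$expr, coh$clin, genes),
                         1e-3, 1e-3)
  perm <- sample(ncol(coh$expr$values))
  expr2 <- expression_matrix(coh$expr$values[rev(seq_along(genes)), perm], "raw")
  a2 <- assign_tk_groups(tk_panel_f_tests(expr2, coh$clin, rev(genes)),
                         1e-3, 1e-3)
  m <- match(a1$gene, a2$gene)
  expect_equal(as.character(a1$group), as.character(a2$group[m]))
})

test_that("minimal-subset reduction preserves the declared group ratio", {
  # 31 + 21 strongly separated genes, reduced to 31 at the nominal 3:2 ratio
  spec <- cohort_spec(n_samples = 404,
                      genes = default_gene_panel(n_bsn_high = 31, n_lp_high = 21,
                                                 n_flat = 0, delta = 1.5),
                      seed = 48)
  coh <- generate_cohort(spec)
  genes <- toupper(spec$genes$gene)
  sub <- reduce_to_minimal_subset(coh$expr, coh$clin, genes, target_size = 31,
                                  p_max = 1e-4, q_max = 1e-4, r2_min = 0.044,
                                  ratio = c(3, 2))
  expect_length(sub, 31)
  asg <- attr(sub, "assignment")
  expect_equal(sum(asg$group == "group1"), 19)
  expect_equal(sum(asg$group == "group2"), 12)
  # identity when the target is the parent size
  all_back <- reduce_to_minimal_subset(coh$expr, coh$clin, genes,
                                       target_size = 52,
                                       p_max = 1e-4, q_max = 1e-4)
  expect_equal(as.character(all_back), genes)
})

test_that("reduction refuses a parent set that fails the thresholds", {
  spec <- cohort_spec(n_samples = 100, seed = 49)  # includes flat genes
  coh <- generate_cohort(spec)
  expect_error(
    reduce_to_minimal_subset(coh$expr, coh$clin, toupper(spec$genes$gene),
                             target_size = 5, p_max = 1e-4, q_max = 1e-4),
    "fails thresholds")
})
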