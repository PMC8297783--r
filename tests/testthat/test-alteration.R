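test_that("z-scores use the sample standard deviation per gene", {
  vals <- matrix(c(1, 2, 3), 1, 3, dimnames = list("A", paste0("s", 1:3)))
  z <- compute_z_scores(expression_matrix(vals, "raw"))
  expect_equal(unname(z$values["A", ]), c(-1, 0, 1))
  expect_equal(z$value_kind, "zscore")
})

test_that("zero-variance genes get all-zero z with a warning", {
  vals <- matrix(c(5, 5, 5, 5, 1, 2, 3, 4), 2, 4, byrow = TRUE,
                 dimnames = list(c("FLAT", "VAR"), paste0("s", 1:4)))
  expect_warning(z <- compute_z_scores(expression_matrix(vals, "raw")),
                 "zero-variance")
  expect_equal(unname(z$values["FLAT", ]), rep(0, 4))
})

test_that("an injected outlier at mean + 3 sd is the only sample flagged", {
  set.seed(7)
  base <- rnorm(19, mean = 10, sd = 2)
  # one outlier well above the bulk; oracle mean/sd by direct summation
  x <- c(base, mean(base) + 6 * sd(base))
  mu <- sum(x) / 20
  sdev <- sqrt(sum((x - mu)^2) / 19)
  oracle_z <- (x - mu) / sdev
  vals <- matrix(x, 1, 20, dimnames = list("G", sprintf("s%02d", 1:20)))
  z <- compute_z_scores(expression_matrix(vals, "raw"))
  expect_equal(unname(z$values["G", ]), oracle_z)
  expect_identical(unname(which(z$values["G", ] > 2)), which(oracle_z > 2))
  expect_length(which(oracle_z > 2), 1)
})

test_that("fewer than 3 reference samples is a hard error", {
  vals <- matrix(1:4, 2, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_error(compute_z_scores(expression_matrix(vals, "raw")), "3 reference")
})

test_that("alteration calls follow the z/amplification/mutation disjunction", {
  z <- expression_matrix(
    matrix(c(2.5, 1.0, 1.0, -3.0), 1, 4,
           dimnames = list("G", paste0("s", 1:4))), "zscore")
  cna <- copy_number_matrix(
    matrix(c(0L, 2L, 1L, -2L), 1, 4,
           dimnames = list("G", paste0("s", 1:4))))
  mut <- matrix(c(FALSE, FALSE, TRUE, FALSE), 1, 4,
                dimnames = list("G", paste0("s", 1:4)))

  alt <- call_alterations(z, cna, mut,
                          alteration_config(include_amplification = TRUE,
                                            include_mutation = FALSE))
  expect_equal(unname(alt$altered["G", ]), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(alt$flags["G", "s1"], "OVEREXPR")
  expect_equal(alt$flags["G", "s2"], "AMP")
  expect_equal(alt$flags["G", "s4"], "HOMDEL")

  alt2 <- call_alterations(z, cna, mut,
                           alteration_config(include_amplification = TRUE,
                                             include_mutation = TRUE))
  expect_true(alt2$altered["G", "s3"])

  alt3 <- call_alterations(z, cna, mut,
                           alteration_config(direction = "two_sided"))
  expect_match(alt3$flags["G", "s4"], "UNDEREXPR")
  expect_false(alt3$altered["G", "s4"])  # underexpression never feeds altered
})

test_that("over_only altered set is contained in the two_sided flagged set", {
  set.seed(11)
  zv <- matrix(rnorm(200, sd = 1.5), 10, 20,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
  z <- expression_matrix(zv, "zscore")
  a1 <- call_alterations(z, config = alteration_config(direction = "over_only"))
  a2 <- call_alterations(z, config = alteration_config(direction = "two_sided"))
  flagged2 <- a2$flags != ""
  expect_true(all(flagged2[a1$altered]))
})

test_that("lowering the z threshold never shrinks an altered case set", {
  set.seed(12)
  zv <- matrix(rnorm(300), 5, 60,
               dimnames = list(paste0("g", 1:5), sprintf("s%02d", 1:60)))
  z <- expression_matrix(zv, "zscore")
  for (thr in c(2, 1.5, 1)) {
    hi <- altered_case_set(call_alterations(z, config = alteration_config(z_threshold = thr + 0.5)),
                           paste0("g", 1:5))
    lo <- altered_case_set(call_alterations(z, config = alteration_config(z_threshold = thr)),
                           paste0("g", 1:5))
    expect_true(all(hi %in% lo))
  }
})

test_that("altered case sets partition the cohort and handle edge cases", {
  altered <- matrix(FALSE, 1, 5, dimnames = list("AXL", paste0("s", 1:5)))
  altered["AXL", "s2"] <- TRUE
  alt <- make_alt(altered)
  expect_equal(altered_case_set(alt, "AXL"), "s2")
  expect_error(altered_case_set(alt, character(0)), "empty gene set")
})

test_that("union of independent per-gene alterations matches closed form", {
  spec <- cohort_spec(n_samples = 50,
                      alteration_marginals = setNames(rep(0.1, 5), paste0("g", 1:5)),
                      seed = 3)
  alt <- generate_paired_alterations(spec)
  frac <- length(altered_case_set(alt, paste0("G", 1:5))) / 50
  p_union <- 1 - 0.9^5  # 0.40951
  expect_lt(abs(frac - p_union), 3 * sqrt(p_union * (1 - p_union) / 50))
})

test_that("per-gene frequency is the altered count over the denominator", {
  altered <- matrix(FALSE, 2, 8, dimnames = list(c("A", "B"), paste0("s", 1:8)))
  altered["A", c("s1", "s5")] <- TRUE
  alt <- make_alt(altered)
  f <- alteration_frequency(alt, "A")
  expect_equal(as.numeric(f), 0.25)
  expect_equal(attr(f, "denominator"), 8)
  expect_equal(as.numeric(alteration_frequency(alt, "B")), 0)
  expect_error(alteration_frequency(alt, "NOPE"), "unknown gene")
})

test_that("total altered count equals the sum of per-gene counts", {
  set.seed(13)
  zv <- matrix(rnorm(400), 8, 50,
               dimnames = list(paste0("g", 1:8), sprintf("s%02d", 1:50)))
  alt <- call_alterations(expression_matrix(zv, "zscore"))
  per_gene <- vapply(paste0("g", 1:8), function(g)
    attr(alteration_frequency(alt, g), "n_altered"), numeric(1))
  expect_equal(sum(per_gene), sum(alt$altered))
})
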