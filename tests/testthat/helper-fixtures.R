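# shared fixtures and independent oracles

# exhaustive fixed-margin Fisher oracle, built from binomial coefficients
# (independent of the dhyper-based implementation path)
enum_fisher <- function(neither, a_only, b_only, both, sidedness) {
  m1 <- both + a_only
  m2 <- b_only + neither
  k <- both + b_only
  support <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, support) + lchoose(m2, k - support) - lchoose(m1 + m2, k)
  probs <- exp(logp)
  if (sidedness == "one_sided_greater") {
    sum(probs[support >= both])
  } else {
    p_obs <- probs[support == both]
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
}

# hand-computed two-group log-rank chi-square (hypergeometric variance),
# independent of the survdiff-backed implementation path
hand_logrank_chisq <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1]
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event]))) {
    at_risk <- time >= t
    nj <- sum(at_risk); n1j <- sum(at_risk & g1)
    dj <- sum(event & time == t); d1j <- sum(event & time == t & g1)
    o_minus_e <- o_minus_e + d1j - dj * n1j / nj
    if (nj > 1)
      v <- v + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
  }
  if (v == 0) 0 else o_minus_e^2 / v
}

# small alteration matrix built directly from a logical matrix
make_alt <- function(altered) {
  flags <- matrix("", nrow(altered), ncol(altered), dimnames = dimnames(altered))
  flags[altered] <- "OVEREXPR"
  structure(list(flags = flags, altered = altered,
                 config = alteration_config()),
            class = "alteration_matrix")
}

# expression fixture: genes x samples with dimnames
make_expr <- function(values, value_kind = "raw") {
  expression_matrix(values, value_kind)
}

# balanced clinical table over the five phenotypes
make_clin <- function(samples, phenotypes,
                      os_months = rep(12, length(samples)),
                      os_event = rep(TRUE, length(samples))) {
  clinical_table(samples, phenotypes, os_months, os_event)
}

# phenotype-labelled cohort for grouping/classifier tests: per-phenotype
# gene means given as a genes x 5 matrix (columns N, BS, L, LI, LP)
make_phenotype_cohort <- function(n_per_class, means, sd = 1, seed = 42) {
  set.seed(seed)
  phen <- rep(c("N", "BS", "L", "LI", "LP"), each = n_per_class)
  n <- length(phen)
  samples <- sprintf("P%03d", seq_len(n))
  vals <- matrix(NA_real_, nrow(means), n,
                 dimnames = list(rownames(means), samples))
  for (i in seq_len(nrow(means))) {
    vals[i, ] <- stats::rnorm(n, mean = means[i, phen], sd = sd)
  }
  list(expr = expression_matrix(2^vals, "raw"),
       clin = make_clin(samples, phen),
       phenotypes = stats::setNames(phen, samples))
}
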