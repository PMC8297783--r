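PHENOTYPES <- c("N", "BS", "L", "LI", "LP")

# deterministic per-component substream: adding a stage never perturbs the
# draws of earlier stages because each stage reseeds from (seed, stage id)
substream_seed <- function(seed, component) {
  offsets <- c(phenotypes = 11L, expression = 23L, alterations = 37L,
               survival = 53L, celllines = 71L)
  if (!component %in% names(offsets)) stop("unknown component: ", component)
  (as.integer(seed) %% 1000000L) * 1009L + offsets[[component]]
}

#' Specification of a synthetic MIBC-like cohort
#'
#' Defaults emulate the published MIBC cohort structure: 404 samples (the
#' co-occurrence tables' denominator), subtype prevalences LP 35%, BS 35%,
#' LI 19%, L 6%, N 5%, phenotype-dependent gene means on the log2 scale,
#' per-gene alteration frequencies, pairwise alteration dependence with a
#' target odds ratio psi, and exponential survival whose hazard differs
#' between altered and unaltered cases.
#'
#' @param n_samples cohort size (default 404).
#' @param phenotype_proportions named proportions over N/BS/L/LI/LP
#'   (must sum to 1).
#' @param genes data.frame with columns gene, mean_N, mean_BS, mean_L,
#'   mean_LI, mean_LP, sd (means on log2 scale); default
#'   [default_gene_panel()].
#' @param alteration_marginals named gene -> frequency in (0, 1).
#' @param pair_targets data.frame gene_a, gene_b, odds_ratio (psi > 0).
#' @param baseline_hazard exponential hazard per month for unaltered cases
#'   (default ln2/60: 60-month median).
#' @param hazard_ratio altered:unaltered hazard ratio (default 2).
#' @param censor_horizon uniform censoring horizon in months (default 120).
#' @param seed integer seed driving all draws.
#' @return a validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 404,
                        phenotype_proportions = c(N = 0.05, BS = 0.35, L = 0.06,
                                                  LI = 0.19, LP = 0.35),
                        genes = default_gene_panel(),
                        alteration_marginals = NULL,
                        pair_targets = NULL,
                        baseline_hazard = log(2) / 60,
                        hazard_ratio = 2,
                        censor_horizon = 120,
                        seed = 1L) {
  if (abs(sum(phenotype_proportions) - 1) > 1e-9)
    stop("phenotype proportions must sum to 1")
  if (!all(PHENOTYPES %in% names(phenotype_proportions)))
    stop("phenotype_proportions must name all of ", paste(PHENOTYPES, collapse = ", "))
  if (!is.null(alteration_marginals) &&
      any(alteration_marginals <= 0 | alteration_marginals >= 1))
    stop("alteration marginals must lie in (0, 1)")
  if (!is.null(pair_targets) && any(pair_targets$odds_ratio <= 0))
    stop("pair target odds ratios must be > 0")
  if (baseline_hazard <= 0) stop("baseline hazard must be > 0")
  if (censor_horizon <= 0) stop("censoring horizon must be > 0")
  structure(list(n_samples = n_samples,
                 phenotype_proportions = phenotype_proportions[PHENOTYPES],
                 genes = genes,
                 alteration_marginals = alteration_marginals,
                 pair_targets = pair_targets,
                 baseline_hazard = baseline_hazard,
                 hazard_ratio = hazard_ratio,
                 censor_horizon = censor_horizon,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default phenotype-structured gene panel
#'
#' A compact TK-like panel: `n_bsn_high` genes overexpressed (+delta on the
#' log2 scale) in the BS and N phenotypes (group-1-like), `n_lp_high` genes
#' with the reciprocal LP-high pattern (group-2-like) and `n_flat`
#' phenotype-independent genes (group-3-like), all with within-phenotype
#' sd 1 on the log2 scale.
#'
#' @param n_bsn_high,n_lp_high,n_flat panel composition (defaults 4/3/3).
#' @param delta phenotype effect size in log2 units (default 1).
#' @param base baseline log2 expression level (default 5).
#' @return data.frame usable as `genes` in [cohort_spec()].
#' @export
default_gene_panel <- function(n_bsn_high = 4, n_lp_high = 3, n_flat = 3,
                               delta = 1, base = 5) {
  mk <- function(prefix, n) if (n > 0) paste0(prefix, seq_len(n)) else character(0)
  genes <- c(mk("G1TK", n_bsn_high), mk("G2TK", n_lp_high), mk("G3TK", n_flat))
  kind <- rep(c("bsn_high", "lp_high", "flat"),
              c(n_bsn_high, n_lp_high, n_flat))
  df <- data.frame(gene = genes,
                   mean_N = base, mean_BS = base, mean_L = base,
                   mean_LI = base, mean_LP = base, sd = 1,
                   truth = kind, stringsAsFactors = FALSE)
  df$mean_N[kind == "bsn_high"] <- base + delta
  df$mean_BS[kind == "bsn_high"] <- base + delta
  df$mean_LP[kind == "lp_high"] <- base + delta
  df$mean_L[kind == "lp_high"] <- base + delta / 2
  df$mean_LI[kind == "lp_high"] <- base + delta / 2
  df
}

#' Gene panel with well-separated per-phenotype centroids
#'
#' Marker-gene design for classifier validation: each of the five molecular
#' phenotypes gets `markers_per_class` genes elevated by `delta` (log2 scale)
#' only in that phenotype, so every pair of phenotype centroids is separated
#' by `delta * sqrt(2 * markers_per_class)` in log2 space.
#'
#' @param markers_per_class marker genes per phenotype (default 3).
#' @param delta marker elevation in log2 units (default 2).
#' @param base baseline log2 expression (default 5).
#' @return data.frame usable as `genes` in [cohort_spec()].
#' @export
phenotype_marker_panel <- function(markers_per_class = 3, delta = 2, base = 5) {
  genes <- unlist(lapply(PHENOTYPES, function(ph)
    paste0("MK", ph, seq_len(markers_per_class))))
  df <- data.frame(gene = genes,
                   mean_N = base, mean_BS = base, mean_L = base,
                   mean_LI = base, mean_LP = base, sd = 1,
                   truth = rep(PHENOTYPES, each = markers_per_class),
                   stringsAsFactors = FALSE)
  for (ph in PHENOTYPES) {
    df[[paste0("mean_", ph)]][df$truth == ph] <- base + delta
  }
  df
}

draw_phenotypes <- function(spec) {
  set.seed(substream_seed(spec$seed, "phenotypes"))
  sample(PHENOTYPES, spec$n_samples, replace = TRUE,
         prob = spec$phenotype_proportions)
}

#' Generate phenotype-structured expression
#'
#' Per-sample phenotype drawn from the spec proportions, then per-gene
#' values Normal(mean\[phenotype\], sd) on the log2 scale, exponentiated to
#' a raw scale. Bit-reproducible from the spec seed.
#'
#' @param spec a [cohort_spec()].
#' @return list: `expr` (raw `expression_matrix`) and `phenotypes`
#'   (named character vector per sample).
#' @export
generate_expression <- function(spec) {
  phen <- draw_phenotypes(spec)
  samples <- sprintf("S%03d", seq_len(spec$n_samples))
  names(phen) <- samples
  set.seed(substream_seed(spec$seed, "expression"))
  g <- spec$genes
  logm <- matrix(NA_real_, nrow(g), spec$n_samples,
                 dimnames = list(toupper(g$gene), samples))
  mean_cols <- paste0("mean_", phen)
  for (i in seq_len(nrow(g))) {
    mu <- as.numeric(g[i, mean_cols])
    logm[i, ] <- stats::rnorm(spec$n_samples, mean = mu, sd = g$sd[i])
  }
  list(expr = expression_matrix(2^logm, "raw"), phenotypes = phen)
}

#' Joint success probability of a dependent Bernoulli pair (Plackett root)
#'
#' Solves psi = p11 p00 / (p10 p01) for p11 subject to the two marginals:
#' the unique admissible root of the quadratic
#' (psi - 1) p11^2 - \[1 + (pa + pb)(psi - 1)\] p11 + psi pa pb = 0.
#'
#' @param pa,pb marginal alteration frequencies in (0, 1).
#' @param psi target odds ratio (> 0).
#' @return p11 in \[max(0, pa + pb - 1), min(pa, pb)\].
#' @export
plackett_p11 <- function(pa, pb, psi) {
  if (psi <= 0) stop("psi must be > 0")
  if (psi == 1) return(pa * pb)
  s <- 1 + (pa + pb) * (psi - 1)
  disc <- s^2 - 4 * psi * (psi - 1) * pa * pb
  if (disc < 0) stop("marginals incompatible with psi (negative discriminant)")
  p11 <- (s - sqrt(disc)) / (2 * (psi - 1))
  lo <- max(0, pa + pb - 1); hi <- min(pa, pb)
  if (p11 < lo - 1e-12 || p11 > hi + 1e-12)
    stop(sprintf("no admissible root for psi=%.4g at marginals (%.4g, %.4g); feasible p11 in [%.4g, %.4g]",
                 psi, pa, pb, lo, hi))
  min(max(p11, lo), hi)
}

#' Generate per-sample alteration calls with target pairwise odds ratios
#'
#' Each pair target draws (A, B) jointly from the Plackett cell
#' probabilities, so marginals and odds ratio hold by construction; genes
#' not involved in any pair are independent Bernoulli draws at their
#' marginal frequency.
#'
#' @param spec a [cohort_spec()] with `alteration_marginals` (and optionally
#'   `pair_targets`).
#' @return an `alteration_matrix` whose flags are OVEREXPR for every
#'   altered cell.
#' @export
generate_paired_alterations <- function(spec) {
  marg <- spec$alteration_marginals
  if (is.null(marg)) stop("spec has no alteration_marginals")
  names(marg) <- toupper(names(marg))
  samples <- sprintf("S%03d", seq_len(spec$n_samples))
  genes <- names(marg)
  altered <- matrix(FALSE, length(genes), spec$n_samples,
                    dimnames = list(genes, samples))
  set.seed(substream_seed(spec$seed, "alterations"))
  paired <- character(0)
  pt <- spec$pair_targets
  if (!is.null(pt)) {
    for (i in seq_len(nrow(pt))) {
      a <- toupper(pt$gene_a[i]); b <- toupper(pt$gene_b[i])
      if (!a %in% genes || !b %in% genes)
        stop("pair target gene without marginal: ", a, "/", b)
      pa <- marg[[a]]; pb <- marg[[b]]
      p11 <- plackett_p11(pa, pb, pt$odds_ratio[i])
      p10 <- pa - p11; p01 <- pb - p11; p00 <- 1 - p11 - p10 - p01
      cell <- sample.int(4, spec$n_samples, replace = TRUE,
                         prob = c(p00, p10, p01, p11))
      altered[a, ] <- cell %in% c(2, 4)
      altered[b, ] <- cell %in% c(3, 4)
      paired <- c(paired, a, b)
    }
  }
  for (g in setdiff(genes, paired)) {
    altered[g, ] <- stats::runif(spec$n_samples) < marg[[g]]
  }
  flags <- matrix("", nrow(altered), ncol(altered), dimnames = dimnames(altered))
  flags[altered] <- "OVEREXPR"
  structure(list(flags = flags, altered = altered,
                 config = alteration_config()),
            class = "alteration_matrix")
}

#' Generate exponential survival with an altered-vs-unaltered hazard ratio
#'
#' Event times are exponential with hazard h0 (unaltered) or h0 * HR
#' (altered); censoring times are uniform on \[0, horizon\]; the observed
#' time is the smaller of the two.
#'
#' @param spec a [cohort_spec()].
#' @param altered character vector of altered sample IDs.
#' @param phenotypes optional named phenotype labels per sample (defaults to
#'   a fresh draw from the spec proportions).
#' @return a `clinical_table` covering all spec samples (OS endpoint; DFS
#'   mirrors OS with independent censoring).
#' @export
generate_survival <- function(spec, altered, phenotypes = NULL) {
  samples <- sprintf("S%03d", seq_len(spec$n_samples))
  if (is.null(phenotypes)) {
    phen <- draw_phenotypes(spec)
  } else phen <- phenotypes[samples]
  set.seed(substream_seed(spec$seed, "survival"))
  haz <- ifelse(samples %in% altered,
                spec$baseline_hazard * spec$hazard_ratio,
                spec$baseline_hazard)
  t_event <- stats::rexp(spec$n_samples, rate = haz)
  t_cens <- stats::runif(spec$n_samples, 0, spec$censor_horizon)
  os <- pmin(t_event, t_cens)
  os_ev <- t_event <= t_cens
  t_cens2 <- stats::runif(spec$n_samples, 0, spec$censor_horizon)
  dfs <- pmin(t_event, t_cens2)
  dfs_ev <- t_event <= t_cens2
  clinical_table(samples, phen, os, os_ev, dfs, dfs_ev)
}

#' Generate synthetic cell-line profiles from a phenotype centroid
#'
#' Each profile is the phenotype's gene-panel centroid (log2 scale) plus
#' Normal noise, exponentiated to absolute copy numbers; the generating
#' phenotype is attached as ground truth.
#'
#' @param spec a [cohort_spec()].
#' @param phenotype one of N/BS/L/LI/LP.
#' @param noise_sd log2-scale noise standard deviation.
#' @param k number of profiles.
#' @return list of [cellline_profile()] objects with attribute
#'   `true_phenotype`.
#' @export
generate_cellline_profiles <- function(spec, phenotype, noise_sd, k) {
  if (!phenotype %in% PHENOTYPES) stop("unknown phenotype: ", phenotype)
  if (k == 0) return(list())
  set.seed(substream_seed(spec$seed, "celllines"))
  g <- spec$genes
  centroid <- as.numeric(g[[paste0("mean_", phenotype)]])
  lapply(seq_len(k), function(i) {
    vals <- 2^(centroid + stats::rnorm(nrow(g), 0, noise_sd))
    names(vals) <- toupper(g$gene)
    pr <- cellline_profile(sprintf("%s_line_%02d", phenotype, i), vals)
    attr(pr, "true_phenotype") <- phenotype
    pr
  })
}

#' Generate a full synthetic cohort
#'
#' Composes expression, alteration, and survival generation under the
#' spec's per-component substreams, keeping the realized latent states as
#' ground truth.
#'
#' @param spec a [cohort_spec()].
#' @param altered_from optional gene set: the altered case set used for the
#'   survival hazard split (default: genes of the first pair target, else
#'   all marginal genes).
#' @return list: expr, phenotypes, alt (or NULL), clin, spec.
#' @export
generate_cohort <- function(spec, altered_from = NULL) {
  ex <- generate_expression(spec)
  alt <- if (!is.null(spec$alteration_marginals))
    generate_paired_alterations(spec) else NULL
  altered <- character(0)
  if (!is.null(alt)) {
    genes <- if (!is.null(altered_from)) toupper(altered_from)
    else rownames(alt$altered)
    altered <- altered_case_set(alt, genes)
  }
  clin <- generate_survival(spec, altered, phenotypes = ex$phenotypes)
  list(expr = ex$expr, phenotypes = ex$phenotypes, alt = alt, clin = clin,
       spec = spec)
}
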