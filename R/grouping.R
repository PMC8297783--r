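#' The 3-supergroup scheme over molecular phenotypes
#'
#' Fixed mapping LP vs (LI + L) vs (BS + N); samples with unknown phenotype
#' are excluded from the F test.
#'
#' @return named character vector phenotype -> supergroup.
#' @export
supergroup_scheme <- function() {
  c(LP = "LP", LI = "LIL", L = "LIL", BS = "BSN", N = "BSN")
}

transform_expression <- function(expr) {
  # raw RSEM-like values are heavy-tailed: model on log2(x + 1);
  # z-scores and copy numbers are used as-is
  if (expr$value_kind == "raw") log2(expr$values + 1) else expr$values
}

supergroup_factor <- function(clin, samples, scheme = supergroup_scheme()) {
  ph <- as.character(clin$phenotype[match(samples, clin$sample)])
  factor(unname(scheme[ph]), levels = unique(unname(scheme)))
}

#' One-gene 3-supergroup F test
#'
#' One-way fixed-effects ANOVA of a gene's (log-transformed) expression
#' across the LP / (LI+L) / (BS+N) supergroups. R^2 is the between-group
#' fraction of total sum of squares, and direction compares the BS+N mean to
#' the LP mean. F and R^2 satisfy F = (R^2/2) / ((1 - R^2)/(n - 3)) exactly.
#'
#' @param expr an `expression_matrix`.
#' @param clin a `clinical_table` with phenotype labels.
#' @param gene gene symbol.
#' @param scheme supergroup mapping (default [supergroup_scheme()]).
#' @return one-row data.frame: gene, F, df1, df2, p, r2, direction
#'   ("high_in_BSN", "high_in_LP" or "none").
#' @export
three_group_f_test <- function(expr, clin, gene, scheme = supergroup_scheme()) {
  gene <- toupper(gene)
  vals <- transform_expression(expr)
  if (!gene %in% rownames(vals)) stop("unknown gene: ", gene)
  samples <- intersect(colnames(vals), clin$sample)
  g <- supergroup_factor(clin, samples, scheme)
  y <- vals[gene, samples]
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep])
  counts <- table(g)
  if (length(counts) < 2 || any(counts < 2))
    stop("each supergroup needs >= 2 samples; got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  n <- length(y)
  k <- length(counts)
  gm <- tapply(y, g, mean)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    return(data.frame(gene = gene, F = 0, df1 = k - 1L, df2 = n - k, p = 1,
                      r2 = 0, direction = "none", stringsAsFactors = FALSE))
  }
  ss_between <- sum(tapply(y, g, length) * (gm - mean(y))^2)
  r2 <- ss_between / ss_tot
  fit <- stats::lm(y ~ g)
  an <- stats::anova(fit)
  Fstat <- an[["F value"]][1]
  p <- an[["Pr(>F)"]][1]
  direction <- if (!all(c("BSN", "LP") %in% names(gm))) "none"
  else if (gm[["BSN"]] > gm[["LP"]]) "high_in_BSN"
  else if (gm[["BSN"]] < gm[["LP"]]) "high_in_LP"
  else "none"
  data.frame(gene = gene, F = Fstat, df1 = k - 1L, df2 = n - k, p = p, r2 = r2,
             direction = direction, stringsAsFactors = FALSE)
}

#' F tests for a gene panel, with BH q-values
#'
#' Vectorized one-way ANOVA over all panel genes at once (the sums of
#' squares are shared-transform matrix operations); genes with missing
#' values fall back to the per-gene path. Results match
#' [three_group_f_test()] gene by gene.
#'
#' @param expr,clin,scheme as in [three_group_f_test()].
#' @param genes character vector of gene symbols.
#' @return data.frame with one row per gene (columns of
#'   [three_group_f_test()] plus `q`), in input gene order.
#' @export
tk_panel_f_tests <- function(expr, clin, genes, scheme = supergroup_scheme()) {
  genes <- toupper(genes)
  vals <- transform_expression(expr)
  missing_genes <- setdiff(genes, rownames(vals))
  if (length(missing_genes) > 0)
    stop("unknown gene(s): ", paste(missing_genes, collapse = ", "))
  samples <- intersect(colnames(vals), clin$sample)
  g <- supergroup_factor(clin, samples, scheme)
  keep <- !is.na(g)
  g <- droplevels(g[keep])
  Y <- vals[genes, samples[keep], drop = FALSE]
  counts <- table(g)
  if (length(counts) < 2 || any(counts < 2))
    stop("each supergroup needs >= 2 samples; got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  has_na <- rowSums(is.na(Y)) > 0
  res <- vector("list", length(genes))
  if (any(!has_na)) {
    Yc <- Y[!has_na, , drop = FALSE]
    n <- ncol(Yc); k <- length(counts)
    grand <- rowMeans(Yc)
    gmeans <- vapply(names(counts), function(lev)
      rowMeans(Yc[, g == lev, drop = FALSE]), numeric(nrow(Yc)))
    if (nrow(Yc) == 1) gmeans <- matrix(gmeans, 1, dimnames = list(rownames(Yc), names(counts)))
    ssb <- as.vector((gmeans - grand)^2 %*% as.numeric(counts))
    sst <- rowSums((Yc - grand)^2)
    r2 <- ifelse(sst == 0, 0, ssb / sst)
    Fstat <- ifelse(sst == 0, 0,
                    (ssb / (k - 1)) / pmax(sst - ssb, 0) * (n - k))
    p <- ifelse(sst == 0, 1, stats::pf(Fstat, k - 1, n - k, lower.tail = FALSE))
    dir <- rep("none", nrow(Yc))
    if (all(c("BSN", "LP") %in% colnames(gmeans))) {
      dir[gmeans[, "BSN"] > gmeans[, "LP"]] <- "high_in_BSN"
      dir[gmeans[, "BSN"] < gmeans[, "LP"]] <- "high_in_LP"
    }
    dir[sst == 0] <- "none"
    fast <- data.frame(gene = rownames(Yc), F = Fstat, df1 = k - 1L,
                       df2 = n - k, p = p, r2 = r2, direction = dir,
                       stringsAsFactors = FALSE)
    res[!has_na] <- split(fast, seq_len(nrow(fast)))
  }
  for (i in which(has_na)) {
    res[[i]] <- three_group_f_test(expr, clin, genes[i], scheme)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$q <- bh_fdr(out$p)
  out
}

#' Assign TK genes to expression groups 1 / 2 / 3
#'
#' Group 1: significant and high in the worse-survival BS+N supergroup;
#' group 2: significant with the reciprocal (LP-high) pattern; group 3: not
#' significant (expression varies independently of phenotype).
#'
#' @param results data.frame from [tk_panel_f_tests()].
#' @param p_max,q_max significance thresholds on p and q.
#' @param r2_min optional minimum variance-explained threshold (default 0).
#' @return data.frame gene, group (factor group1/group2/group3) plus the test
#'   columns; attribute `counts` holds the per-group sizes.
#' @export
assign_tk_groups <- function(results, p_max, q_max, r2_min = 0) {
  if (p_max <= 0 && q_max <= 0) {
    sig <- rep(FALSE, nrow(results))
  } else {
    sig <- results$p < p_max & results$q < q_max & results$r2 >= r2_min
  }
  grp <- rep("group3", nrow(results))
  grp[sig & results$direction == "high_in_BSN"] <- "group1"
  grp[sig & results$direction == "high_in_LP"] <- "group2"
  out <- results
  out$group <- factor(grp, levels = c("group1", "group2", "group3"))
  attr(out, "counts") <- table(out$group)
  out
}

#' Reduce a significant gene panel to a minimal subset
#'
#' Greedy backward elimination: the parent panel must pass the thresholds
#' gene-by-gene; genes are then dropped, weakest per-gene F first, while the
#' group1:group2 ratio is preserved within rounding (largest-remainder
#' allocation of the target size across the two groups). Because the F test
#' is per-gene, dropping the weakest survivor is exactly the removal that
#' least degrades the minimum per-gene F among survivors. Deterministic
#' given gene order (ties broken by input order).
#'
#' @param expr,clin,scheme as in [three_group_f_test()].
#' @param genes ordered parent gene set.
#' @param target_size desired subset size (<= length(genes)).
#' @param p_max,q_max,r2_min thresholds every retained gene must pass.
#' @param ratio length-2 numeric giving the group1:group2 allocation ratio;
#'   default `NULL` uses the parent panel's own group counts.
#' @return character vector of retained genes (parent order), with the group
#'   assignment data.frame attached as attribute `assignment`.
#' @export
reduce_to_minimal_subset <- function(expr, clin, genes, target_size,
                                     p_max, q_max, r2_min = 0,
                                     scheme = supergroup_scheme(),
                                     ratio = NULL) {
  genes <- toupper(genes)
  res <- tk_panel_f_tests(expr, clin, genes, scheme)
  asg <- assign_tk_groups(res, p_max, q_max, r2_min)
  if (any(asg$group == "group3"))
    stop("parent set fails thresholds: ",
         paste(asg$gene[asg$group == "group3"], collapse = ", "))
  if (target_size > length(genes)) stop("target_size exceeds parent size")
  if (target_size == length(genes)) {
    out <- genes
  } else {
    n1 <- sum(asg$group == "group1"); n2 <- sum(asg$group == "group2")
    if (is.null(ratio)) ratio <- c(n1, n2)
    # largest-remainder allocation of target_size across the two groups
    quota <- target_size * ratio / sum(ratio)
    base <- floor(quota)
    rem <- target_size - sum(base)
    if (rem > 0) {
      extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    k1 <- min(base[1], n1); k2 <- min(base[2], n2)
    if (k1 + k2 < target_size)  # one group exhausted; top up from the other
      if (k1 < base[1]) k2 <- target_size - k1 else k1 <- target_size - k2
    keep1 <- asg$gene[asg$group == "group1"][
      order(-asg$F[asg$group == "group1"])][seq_len(k1)]
    keep2 <- asg$gene[asg$group == "group2"][
      order(-asg$F[asg$group == "group2"])][seq_len(k2)]
    out <- genes[genes %in% c(keep1, keep2)]
  }
  attr(out, "assignment") <- asg[asg$gene %in% out, ]
  out
}
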