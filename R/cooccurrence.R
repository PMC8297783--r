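#' Build a 2x2 co-alteration contingency table
#'
#' Each cohort sample is assigned to exactly one of four cells by whether it
#' is altered in gene set A and/or gene set B, giving the
#' (neither, a_only, b_only, both) counts that drive the screen.
#'
#' @param alt an `alteration_matrix`.
#' @param a,b gene symbols (single gene or gene set); must be disjoint.
#' @param label_a,label_b names used in reports (defaults: joined symbols).
#' @return a `contingency_table`.
#' @export
build_contingency <- function(alt, a, b,
                              label_a = paste(a, collapse = "+"),
                              label_b = paste(b, collapse = "+")) {
  a <- toupper(a); b <- toupper(b)
  if (length(intersect(a, b)) > 0)
    stop("gene sets overlap (sample category would be ill-defined): ",
         paste(intersect(a, b), collapse = ", "))
  in_a <- samples_of_alt(alt) %in% altered_case_set(alt, a)
  in_b <- samples_of_alt(alt) %in% altered_case_set(alt, b)
  contingency_table(neither = sum(!in_a & !in_b),
                    a_only = sum(in_a & !in_b),
                    b_only = sum(!in_a & in_b),
                    both = sum(in_a & in_b),
                    label_a = label_a, label_b = label_b)
}

samples_of_alt <- function(alt) colnames(alt$altered)

#' Construct a contingency table from counts
#'
#' @param neither,a_only,b_only,both non-negative cell counts.
#' @param label_a,label_b labels for the two genes/gene sets.
#' @return a `contingency_table` list; `total` is the analysis denominator.
#' @export
contingency_table <- function(neither, a_only, b_only, both,
                              label_a = "A", label_b = "B") {
  counts <- c(neither = neither, a_only = a_only, b_only = b_only, both = both)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  structure(list(neither = neither, a_only = a_only, b_only = b_only,
                 both = both, total = sum(counts),
                 label_a = label_a, label_b = label_b),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("%s x %s: neither=%d %s-only=%d %s-only=%d both=%d (n=%d)\n",
              x$label_a, x$label_b, x$neither, x$label_a, x$a_only,
              x$label_b, x$b_only, x$both, x$total))
  invisible(x)
}

#' Log2 odds ratio of a 2x2 table
#'
#' log2((both * neither) / (a_only * b_only)), with no continuity
#' correction: `+Inf` when a zero off-diagonal makes the ratio infinite but
#' the numerator is positive, `NA` when the numerator is zero too.
#'
#' @param t a `contingency_table`.
#' @return numeric scalar (possibly `Inf`/`-Inf`/`NA`).
#' @export
log2_odds_ratio <- function(t) {
  num <- t$both * t$neither
  den <- t$a_only * t$b_only
  if (den == 0) {
    if (num > 0) return(Inf)
    return(NA_real_)
  }
  if (num == 0) return(-Inf)
  log2(num / den)
}

#' Display form of a log2 odds ratio
#'
#' Values above 3 print as `">3"` (publication-style cap); finite values
#' print to 3 decimals; `NA` prints as `"NA"`.
#'
#' @param x numeric log2 odds ratio.
#' @return character scalar.
#' @export
format_log2_or <- function(x) {
  if (is.na(x)) return("NA")
  if (x > 3) return(">3")
  sprintf("%.3f", x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric p-value conditioned on the table margins.
#' `one_sided_greater` sums the probabilities of tables with `both` at least
#' as large as observed (co-occurrence direction); `two_sided` sums the
#' probabilities of all tables no more probable than the observed one.
#'
#' @param t a `contingency_table`.
#' @param sidedness `"one_sided_greater"` (default) or `"two_sided"`.
#' @return p-value in [0, 1].
#' @export
fisher_exact <- function(t, sidedness = c("one_sided_greater", "two_sided")) {
  sidedness <- match.arg(sidedness)
  m1 <- t$both + t$a_only     # samples altered in A
  m2 <- t$b_only + t$neither  # samples not altered in A
  k <- t$both + t$b_only      # samples altered in B
  support <- max(0, k - m2):min(k, m1)
  probs <- stats::dhyper(support, m1, m2, k)
  obs <- t$both
  p <- if (sidedness == "one_sided_greater") {
    sum(probs[support >= obs])
  } else {
    # relative tolerance absorbs floating-point ties across the support
    p_obs <- stats::dhyper(obs, m1, m2, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  min(1, max(0, p))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted p-values over one screening family, capped at 1.
#'
#' @param pvals numeric vector of p-values in [0, 1] (NAs preserved).
#' @return numeric vector of q-values, same length/order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Exhaustive pairwise co-occurrence screen
#'
#' Enumerates all `choose(k, 2)` unordered pairs of a gene set
#' (`mode = "all_pairs"`) or the RTK-ligand pairs of a pair map
#' (`mode = "mapped_pairs"`), builds each 2x2 table, and reports the log2
#' odds ratio, Fisher p and BH q per pair. Significance requires both
#' p < 0.05 and q < 0.05. The FDR family is the set of pairs screened in
#' this one invocation. Pairs involving genes absent from the matrix are
#' flagged `skipped`, not dropped.
#'
#' @param alt an `alteration_matrix`.
#' @param genes character vector of >= 2 genes (`all_pairs`) or a named list
#'   mapping an RTK symbol to its cognate ligand symbols (`mapped_pairs`).
#' @param mode `"all_pairs"` or `"mapped_pairs"`.
#' @param sidedness passed to [fisher_exact()].
#' @param p_max,q_max significance thresholds (default 0.05 and 0.05).
#' @return data.frame of class `pair_screen` sorted by p then labels, with
#'   columns label_a, label_b, neither, a_only, b_only, both, log2_or,
#'   log2_or_display, p, q, significant, skipped.
#' @export
screen_pairs <- function(alt, genes, mode = c("all_pairs", "mapped_pairs"),
                         sidedness = "one_sided_greater",
                         p_max = 0.05, q_max = 0.05) {
  mode <- match.arg(mode)
  if (mode == "all_pairs") {
    genes <- toupper(unlist(genes))
    if (length(genes) < 2) stop("all_pairs mode needs at least 2 genes")
    idx <- utils::combn(length(genes), 2)
    pairs <- data.frame(a = genes[idx[1, ]], b = genes[idx[2, ]])
  } else {
    if (length(genes) == 0) stop("mapped_pairs mode needs a non-empty map")
    pairs <- do.call(rbind, lapply(names(genes), function(r)
      data.frame(a = toupper(r), b = toupper(unlist(genes[[r]])))))
  }
  present <- rownames(alt$altered)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$a[i]; b <- pairs$b[i]
    if (!(a %in% present) || !(b %in% present)) {
      return(data.frame(label_a = a, label_b = b, neither = NA, a_only = NA,
                        b_only = NA, both = NA, log2_or = NA_real_,
                        log2_or_display = "NA", p = NA_real_, skipped = TRUE))
    }
    tab <- build_contingency(alt, a, b)
    lor <- log2_odds_ratio(tab)
    data.frame(label_a = a, label_b = b, neither = tab$neither,
               a_only = tab$a_only, b_only = tab$b_only, both = tab$both,
               log2_or = lor, log2_or_display = format_log2_or(lor),
               p = fisher_exact(tab, sidedness), skipped = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  res$q[!res$skipped] <- bh_fdr(res$p[!res$skipped])
  res$significant <- !res$skipped & res$p < p_max & res$q < q_max
  res <- res[order(res$p, res$label_a, res$label_b), ]
  rownames(res) <- NULL
  res <- res[, c("label_a", "label_b", "neither", "a_only", "b_only", "both",
                 "log2_or", "log2_or_display", "p", "q", "significant", "skipped")]
  class(res) <- c("pair_screen", "data.frame")
  res
}
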