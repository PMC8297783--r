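#' Construct a cell-line expression profile
#'
#' Absolute mRNA copy numbers over a classification gene panel. Undetectable
#' transcripts ("ND" in source tables) are represented as copy number 0.
#'
#' @param name cell line name.
#' @param copies named numeric vector gene -> copy number (>= 0).
#' @return a `cellline_profile`.
#' @export
cellline_profile <- function(name, copies) {
  if (is.null(names(copies))) stop("`copies` must be named by gene symbol")
  names(copies) <- toupper(names(copies))
  if (any(copies < 0, na.rm = TRUE)) stop("copy numbers must be >= 0")
  structure(list(name = name, copies = copies), class = "cellline_profile")
}

#' Correlate a cell-line profile against every cohort sample
#'
#' One coefficient per cohort sample, computed over the panel genes shared
#' between profile and cohort. Default Spearman rank correlation between the
#' line's copy numbers and the samples' z-scores, which is invariant to the
#' unknown monotone relation between the two scales; Pearson on
#' log2(copies + 1) is the alternative.
#'
#' @param profile a [cellline_profile()].
#' @param cohort an `expression_matrix` of z-scores.
#' @param panel character vector of panel gene symbols.
#' @param method `"spearman"` (default) or `"pearson_log"`.
#' @return named numeric vector of per-sample coefficients; attribute
#'   `n_shared_genes` reports the panel overlap.
#' @export
correlate_to_cohort <- function(profile, cohort, panel,
                                method = c("spearman", "pearson_log")) {
  method <- match.arg(method)
  panel <- toupper(panel)
  shared <- Reduce(intersect, list(panel, names(profile$copies),
                                   genes_of(cohort)))
  if (length(shared) < 5)
    stop("fewer than 5 shared panel genes between profile '",
         profile$name, "' and cohort (", length(shared), ")")
  x <- profile$copies[shared]
  m <- cohort$values[shared, , drop = FALSE]
  if (method == "pearson_log") {
    x <- log2(x + 1)
    r <- apply(m, 2, function(col) suppressWarnings(
      stats::cor(x, col, method = "pearson", use = "pairwise.complete.obs")))
  } else {
    r <- apply(m, 2, function(col) suppressWarnings(
      stats::cor(x, col, method = "spearman", use = "pairwise.complete.obs")))
  }
  structure(r, n_shared_genes = length(shared))
}

#' Classify one cell line from its per-sample correlation coefficients
#'
#' Coefficients are averaged within each molecular phenotype (phenotypes
#' with fewer than 3 cohort samples are excluded with a warning); the best
#' phenotype is the one with the maximal mean coefficient, and for every
#' other phenotype a Welch two-sample t-test compares the coefficient
#' distributions. Verdicts: `assigned` when every comparison passes at
#' p < 0.05, `assigned_with_exceptions` (naming the failures) when some do,
#' `best_only` when none do.
#'
#' @param coefficients named per-sample correlation coefficients
#'   (names = cohort sample IDs).
#' @param clin a `clinical_table` supplying phenotype labels.
#' @param alpha t-test significance level per comparison (default 0.05,
#'   uncorrected, mirroring per-comparison reporting).
#' @return a `phenotype_call`: best phenotype, per-phenotype mean
#'   coefficients, passed_vs map, exceptions, verdict.
#' @export
classify_cell_line <- function(coefficients, clin, alpha = 0.05) {
  ph <- as.character(clin$phenotype[match(names(coefficients), clin$sample)])
  keep <- !is.na(ph) & ph != "unknown" & !is.na(coefficients)
  ph <- ph[keep]; r <- coefficients[keep]
  sizes <- table(ph)
  small <- names(sizes)[sizes < 3]
  if (length(small) > 0) {
    warning("phenotype(s) with < 3 samples excluded: ",
            paste(small, collapse = ", "))
    sel <- !(ph %in% small)
    ph <- ph[sel]; r <- r[sel]
  }
  if (length(unique(ph)) == 0) stop("all phenotypes excluded")
  means <- tapply(r, ph, mean)
  best <- names(means)[which.max(means)]
  others <- setdiff(names(means), best)
  passed <- vapply(others, function(p2) {
    stats::t.test(r[ph == best], r[ph == p2])$p.value < alpha
  }, logical(1))
  verdict <- if (length(others) == 0 || all(passed)) "assigned"
  else if (!any(passed)) "best_only"
  else "assigned_with_exceptions"
  structure(list(best = best, mean_coefficients = means,
                 passed_vs = passed, exceptions = others[!passed],
                 verdict = verdict),
            class = "phenotype_call")
}

#' @export
print.phenotype_call <- function(x, ...) {
  extra <- switch(x$verdict,
                  assigned = "passed t-test vs all other phenotypes",
                  assigned_with_exceptions = paste("yes except",
                                                   paste(x$exceptions, collapse = ", ")),
                  best_only = "t-test not passed")
  cat(sprintf("closest phenotype: %s (mean r = %.3f; %s)\n",
              x$best, max(x$mean_coefficients), extra))
  invisible(x)
}

#' Classify a panel of cell lines
#'
#' One phenotype call per line; per-line errors are collected in the
#' `error` column rather than aborting the batch.
#'
#' @param profiles list of [cellline_profile()] objects (unique names).
#' @param cohort,clin,panel,method as in [correlate_to_cohort()].
#' @return data.frame: cell_line, closest_phenotype, correlation_value,
#'   passed_t_test (display string), verdict, error.
#' @export
classify_panel <- function(profiles, cohort, clin, panel,
                           method = "spearman") {
  if (length(profiles) == 0)
    return(data.frame(cell_line = character(0), closest_phenotype = character(0),
                      correlation_value = numeric(0), passed_t_test = character(0),
                      verdict = character(0), error = character(0)))
  nms <- vapply(profiles, function(p) p$name, character(1))
  if (anyDuplicated(nms))
    stop("duplicate cell line name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  rows <- lapply(profiles, function(pr) {
    out <- tryCatch({
      r <- correlate_to_cohort(pr, cohort, panel, method)
      call <- classify_cell_line(r, clin)
      disp <- switch(call$verdict,
                     assigned = "Yes",
                     best_only = "No",
                     assigned_with_exceptions =
                       paste("Yes except", paste(call$exceptions, collapse = ", ")))
      data.frame(cell_line = pr$name, closest_phenotype = call$best,
                 correlation_value = unname(max(call$mean_coefficients)),
                 passed_t_test = disp, verdict = call$verdict,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(cell_line = pr$name, closest_phenotype = NA_character_,
                 correlation_value = NA_real_, passed_t_test = NA_character_,
                 verdict = NA_character_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    out
  })
  do.call(rbind, rows)
}
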