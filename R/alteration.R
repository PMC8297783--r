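#' Alteration-calling configuration
#'
#' @param z_threshold positive z-score cutoff for overexpression (default 2;
#'   4 is the stricter alternative used for high-confidence calls).
#' @param direction `"over_only"` flags only overexpression; `"two_sided"`
#'   additionally records UNDEREXPR flags (which never feed `altered`).
#' @param include_amplification count GISTIC +2 calls as alterations.
#' @param include_mutation count mutation flags as alterations.
#' @param reference_population `"all_samples"` or `"supplied_subset"`
#'   (z-scores computed against a supplied subset of samples).
#' @return an `alteration_config` list.
#' @export
alteration_config <- function(z_threshold = 2,
                              direction = c("over_only", "two_sided"),
                              include_amplification = TRUE,
                              include_mutation = FALSE,
                              reference_population = c("all_samples", "supplied_subset")) {
  if (!is.numeric(z_threshold) || length(z_threshold) != 1 || z_threshold <= 0)
    stop("z_threshold must be a positive number")
  structure(list(z_threshold = z_threshold,
                 direction = match.arg(direction),
                 include_amplification = isTRUE(include_amplification),
                 include_mutation = isTRUE(include_mutation),
                 reference_population = match.arg(reference_population)),
            class = "alteration_config")
}

#' Per-gene expression z-scores
#'
#' z(g, s) = (x(g, s) - mean_g) / sd_g with mean and the sample (n-1)
#' standard deviation computed over the reference population. Genes with zero
#' variance get z = 0 everywhere (with a warning) so matrix shapes stay
#' stable.
#'
#' @param expr an `expression_matrix` with `value_kind = "raw"`.
#' @param config an [alteration_config()].
#' @param reference_samples sample IDs defining the reference population when
#'   `config$reference_population == "supplied_subset"`.
#' @return an `expression_matrix` with `value_kind = "zscore"`.
#' @export
compute_z_scores <- function(expr, config = alteration_config(),
                             reference_samples = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$value_kind != "raw")
    stop("compute_z_scores expects raw expression values")
  vals <- expr$values
  ref <- if (config$reference_population == "supplied_subset") {
    if (is.null(reference_samples))
      stop("reference_samples required for supplied_subset reference")
    vals[, intersect(colnames(vals), reference_samples), drop = FALSE]
  } else vals
  if (ncol(ref) < 3)
    stop("fewer than 3 reference samples")
  mu <- rowMeans(ref, na.rm = TRUE)
  sdv <- apply(ref, 1, stats::sd, na.rm = TRUE)
  zero <- !is.na(sdv) & sdv == 0
  if (any(zero))
    warning("zero-variance gene(s) set to z = 0: ",
            paste(utils::head(rownames(vals)[zero], 5), collapse = ", "),
            if (sum(zero) > 5) ", ..." else "")
  z <- (vals - mu) / sdv
  z[zero, ] <- 0
  expression_matrix(z, "zscore")
}

#' Call per-gene, per-sample potentially oncogenic alterations
#'
#' A cell is `altered` when its z-score exceeds `+z_threshold`
#' (overexpression), or its copy-number call is +2 (amplification, when
#' enabled), or its mutation flag is set (when enabled). Under `two_sided`
#' direction, `|z| > threshold` additionally records UNDEREXPR flags, but
#' only overexpression feeds `altered`; homozygous deletions are recorded as
#' HOMDEL flags only.
#'
#' @param z an `expression_matrix` of z-scores.
#' @param cna optional `copy_number_matrix`; genes absent from it simply
#'   cannot receive AMP/HOMDEL flags (logged once per gene).
#' @param mut optional gene x sample logical matrix of mutation flags.
#' @param config an [alteration_config()].
#' @return an `alteration_matrix` with `flags` (character matrix, "|"-joined
#'   flag sets, "" = none) and `altered` (logical matrix).
#' @export
call_alterations <- function(z, cna = NULL, mut = NULL,
                             config = alteration_config()) {
  stopifnot(inherits(z, "expression_matrix"))
  if (z$value_kind != "zscore") stop("call_alterations expects z-scores")
  zv <- z$values
  genes <- rownames(zv); samp <- colnames(zv)
  over <- !is.na(zv) & zv > config$z_threshold
  under <- if (config$direction == "two_sided")
    !is.na(zv) & zv < -config$z_threshold else matrix(FALSE, nrow(zv), ncol(zv))
  amp <- homdel <- matrix(FALSE, nrow(zv), ncol(zv), dimnames = dimnames(zv))
  if (!is.null(cna)) {
    stopifnot(inherits(cna, "copy_number_matrix"))
    shared_g <- intersect(genes, rownames(cna$calls))
    missing_g <- setdiff(genes, rownames(cna$calls))
    if (length(missing_g) > 0)
      message(length(missing_g), " gene(s) without copy-number data (no AMP possible): ",
              paste(utils::head(missing_g, 5), collapse = ", "),
              if (length(missing_g) > 5) ", ..." else "")
    shared_s <- intersect(samp, colnames(cna$calls))
    cc <- cna$calls[shared_g, shared_s, drop = FALSE]
    amp[shared_g, shared_s] <- !is.na(cc) & cc == 2L
    homdel[shared_g, shared_s] <- !is.na(cc) & cc == -2L
  }
  mutm <- matrix(FALSE, nrow(zv), ncol(zv), dimnames = dimnames(zv))
  if (!is.null(mut)) {
    shared_g <- intersect(genes, rownames(mut))
    shared_s <- intersect(samp, colnames(mut))
    mutm[shared_g, shared_s] <- isTRUE_matrix(mut[shared_g, shared_s, drop = FALSE])
  }
  altered <- over |
    (config$include_amplification & amp) |
    (config$include_mutation & mutm)
  flags <- matrix("", nrow(zv), ncol(zv), dimnames = dimnames(zv))
  add_flag <- function(flags, mask, lab) {
    flags[mask] <- ifelse(flags[mask] == "", lab, paste(flags[mask], lab, sep = "|"))
    flags
  }
  flags <- add_flag(flags, over, "OVEREXPR")
  flags <- add_flag(flags, under, "UNDEREXPR")
  flags <- add_flag(flags, amp, "AMP")
  flags <- add_flag(flags, homdel, "HOMDEL")
  flags <- add_flag(flags, mutm, "MUT")
  structure(list(flags = flags, altered = altered, config = config),
            class = "alteration_matrix")
}

isTRUE_matrix <- function(m) {
  m[is.na(m)] <- FALSE
  m
}

#' @export
print.alteration_matrix <- function(x, ...) {
  cat(sprintf("alteration_matrix: %d genes x %d samples, %d altered cell(s)\n",
              nrow(x$altered), ncol(x$altered), sum(x$altered)))
  invisible(x)
}

#' Altered case set for a gene set
#'
#' Samples carrying at least one altered call among the given genes; the
#' complement is the unaltered case set, and the two partition the cohort.
#'
#' @param alt an `alteration_matrix`.
#' @param genes non-empty character vector of gene symbols (missing genes
#'   dropped with a warning).
#' @return character vector of altered sample IDs.
#' @export
altered_case_set <- function(alt, genes) {
  stopifnot(inherits(alt, "alteration_matrix"))
  genes <- toupper(genes)
  if (length(genes) == 0) stop("empty gene set")
  present <- intersect(genes, rownames(alt$altered))
  if (length(present) < length(genes))
    warning("gene(s) absent from alteration matrix dropped: ",
            paste(setdiff(genes, present), collapse = ", "))
  if (length(present) == 0) stop("no genes of the set present in the matrix")
  hit <- colSums(alt$altered[present, , drop = FALSE]) > 0
  colnames(alt$altered)[hit]
}

#' Per-gene altered fraction
#'
#' @param alt an `alteration_matrix`.
#' @param gene single gene symbol.
#' @return fraction altered, with attributes `n_altered` and `denominator`.
#' @export
alteration_frequency <- function(alt, gene) {
  stopifnot(inherits(alt, "alteration_matrix"))
  gene <- toupper(gene)
  if (!gene %in% rownames(alt$altered)) stop("unknown gene: ", gene)
  k <- sum(alt$altered[gene, ])
  n <- ncol(alt$altered)
  structure(k / n, n_altered = k, denominator = n)
}
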