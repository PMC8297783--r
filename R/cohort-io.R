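PHENOTYPE_LEVELS <- c("N", "BS", "L", "LI", "LP", "unknown")

# case-insensitive aliases for the five molecular phenotype classes
PHENOTYPE_ALIASES <- c(
  "n" = "N", "neuronal" = "N",
  "bs" = "BS", "basal squamous" = "BS", "basal_squamous" = "BS",
  "basal-squamous" = "BS",
  "l" = "L", "luminal" = "L",
  "li" = "LI", "luminal infiltrating" = "LI", "luminal_infiltrating" = "LI",
  "luminal-infiltrating" = "LI", "luminal infiltrated" = "LI",
  "lp" = "LP", "luminal papillary" = "LP", "luminal_papillary" = "LP",
  "luminal-papillary" = "LP"
)

#' Construct an expression matrix object
#'
#' Central container for gene x sample continuous expression values. Rows are
#' HUGO gene symbols (upper-cased, unique), columns are sample IDs (unique).
#' `value_kind` declares the scale of the values so downstream stages can pick
#' the right transform (raw RSEM-like values are log2(x+1)-transformed before
#' linear modelling; z-scores are used as-is).
#'
#' @param values numeric matrix, genes in rows, samples in columns. Dimnames
#'   are taken as gene symbols and sample IDs.
#' @param value_kind one of `"raw"`, `"zscore"`, `"abs_copy_number"`.
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, value_kind = c("raw", "zscore", "abs_copy_number")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  genes <- toupper(rownames(values))
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop("`values` must have gene rownames and sample colnames")
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0)
    stop("duplicate gene symbol(s): ", paste(unique(dup), collapse = ", "))
  dup <- samples[duplicated(samples)]
  if (length(dup) > 0)
    stop("duplicate sample ID(s): ", paste(unique(dup), collapse = ", "))
  rownames(values) <- genes
  structure(list(values = values, value_kind = value_kind),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d genes x %d samples, %d missing value(s)\n",
              x$value_kind, nrow(x$values), ncol(x$values), n_missing(x)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Count of missing cells in an expression matrix
#' @param x an `expression_matrix`.
#' @return integer count of `NA` cells.
#' @export
n_missing <- function(x) sum(is.na(x$values))

genes_of <- function(x) rownames(x$values)
samples_of <- function(x) colnames(x$values)

#' Read a gene x sample expression TSV
#'
#' Expects one header row of sample IDs and a first column of gene symbols.
#' UTF-8, "." decimal separator; empty cells or "NA" are missing.
#'
#' @param path TSV file path.
#' @param value_kind declared scale of the values (see [expression_matrix()]).
#' @return an `expression_matrix`; row/column order preserved from file.
#' @export
read_expression_tsv <- function(path, value_kind = c("raw", "zscore", "abs_copy_number")) {
  value_kind <- match.arg(value_kind)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), colClasses = "character")
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("empty or malformed expression file: ", path)
  genes <- toupper(df[[1]])
  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0)
    stop("duplicate gene symbol(s) in ", path, ": ", paste(dup, collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(genes, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell at gene '%s', sample '%s' in %s",
                 genes[bad[1, 1]], colnames(vals)[bad[1, 2]], path))
  expression_matrix(num, value_kind)
}

#' Write an expression matrix to TSV
#'
#' Round-trips with [read_expression_tsv()] for text-representable numbers at
#' the given decimal precision.
#'
#' @param x an `expression_matrix` (or copy-number matrix).
#' @param path output path.
#' @param digits decimal digits to print (default 6).
#' @export
write_expression_tsv <- function(x, path, digits = 6) {
  vals <- if (inherits(x, "expression_matrix")) x$values else x
  fmt <- format(round(vals, digits), trim = TRUE, scientific = FALSE)
  fmt[is.na(vals)] <- "NA"
  df <- cbind(gene = rownames(vals), as.data.frame(fmt, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample clinical table
#'
#' Columns: `sample`, `phenotype`, `os_months`, `os_event`, and optionally
#' `dfs_months`, `dfs_event`. Phenotype strings are mapped case-insensitively
#' to the five molecular classes (N, BS, L, LI, LP); unmapped labels become
#' `"unknown"` with a warning. The non-OS endpoint is exposed as DFS
#' throughout (the literature uses DFS and PFS interchangeably for it).
#'
#' @param path TSV file path.
#' @return a `clinical_table` (data.frame subclass) keyed by sample.
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("sample", "phenotype", "os_months", "os_event")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (!"dfs_months" %in% names(df)) df$dfs_months <- NA_real_
  if (!"dfs_event" %in% names(df)) df$dfs_event <- NA
  clinical_table(df$sample, df$phenotype, df$os_months, df$os_event,
                 df$dfs_months, df$dfs_event)
}

parse_event_flag <- function(x, what) {
  if (is.logical(x)) return(x)
  s <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(s))
  out[s %in% c("1", "true")] <- TRUE
  out[s %in% c("0", "false")] <- FALSE
  bad <- !is.na(s) & s != "" & is.na(out)
  if (any(bad))
    stop(what, " flag not in {0,1,true,false}: '", s[which(bad)[1]], "'")
  out
}

#' Construct a clinical table
#'
#' @param sample sample IDs (unique).
#' @param phenotype phenotype labels, mapped to {N, BS, L, LI, LP, unknown}.
#' @param os_months,os_event overall survival months (>= 0) and event flag.
#' @param dfs_months,dfs_event disease-free survival months and event flag.
#' @return a data.frame of class `clinical_table`.
#' @export
clinical_table <- function(sample, phenotype, os_months, os_event,
                           dfs_months = NA_real_, dfs_event = NA) {
  sample <- as.character(sample)
  if (anyDuplicated(sample))
    stop("duplicate sample ID(s): ",
         paste(unique(sample[duplicated(sample)]), collapse = ", "))
  key <- tolower(trimws(as.character(phenotype)))
  mapped <- unname(PHENOTYPE_ALIASES[key])
  unmapped <- !is.na(key) & key != "" & is.na(mapped)
  if (any(unmapped)) {
    warning("unmapped phenotype label(s) set to 'unknown': ",
            paste(unique(phenotype[unmapped]), collapse = ", "))
  }
  mapped[is.na(mapped)] <- "unknown"
  os_months <- as.numeric(os_months)
  dfs_months <- as.numeric(dfs_months)
  if (any(os_months < 0, na.rm = TRUE) || any(dfs_months < 0, na.rm = TRUE))
    stop("negative survival months")
  os_event <- parse_event_flag(os_event, "os_event")
  dfs_event <- parse_event_flag(dfs_event, "dfs_event")
  if (any(!is.na(os_months) & is.na(os_event)))
    stop("os_event undefined for sample(s) with os_months")
  if (any(!is.na(dfs_months) & is.na(dfs_event)))
    stop("dfs_event undefined for sample(s) with dfs_months")
  df <- data.frame(sample = sample,
                   phenotype = factor(mapped, levels = PHENOTYPE_LEVELS),
                   os_months = os_months, os_event = os_event,
                   dfs_months = rep_len(dfs_months, length(sample)),
                   dfs_event = rep_len(dfs_event, length(sample)),
                   stringsAsFactors = FALSE)
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a discrete copy-number call matrix
#'
#' Same layout as the expression TSV; cells must be integers in -2..2
#' (GISTIC-style calls: -2 homozygous deletion ... +2 amplification).
#'
#' @param path TSV file path.
#' @return a `copy_number_matrix` (integer matrix wrapper).
#' @export
read_cna_tsv <- function(path) {
  em <- read_expression_tsv(path, value_kind = "raw")
  copy_number_matrix(em$values)
}

#' Construct a copy-number call matrix
#' @param calls integer matrix with values in {-2,-1,0,1,2}; gene rownames,
#'   sample colnames.
#' @return object of class `copy_number_matrix`.
#' @export
copy_number_matrix <- function(calls) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  ok <- is.na(calls) | calls %in% (-2:2)
  if (!all(ok))
    stop("copy-number calls must be integers in -2..2; first offender: ",
         calls[which(!ok)[1]])
  storage.mode(calls) <- "integer"
  rownames(calls) <- toupper(rownames(calls))
  structure(list(calls = calls), class = "copy_number_matrix")
}

#' Read a gene-set catalog
#'
#' YAML file with two optional top-level keys: `sets` (name -> list of
#' symbols) and `pair_maps` (name -> map of RTK symbol -> list of cognate
#' ligand symbols).
#'
#' @param path YAML file path.
#' @return a `gene_set_catalog` with elements `sets` and `pair_maps`.
#' @export
read_gene_sets <- function(path) {
  y <- yaml::read_yaml(path)
  sets <- lapply(y$sets, function(s) toupper(unlist(s)))
  for (nm in names(sets)) {
    dup <- unique(sets[[nm]][duplicated(sets[[nm]])])
    if (length(dup) > 0)
      stop("duplicate symbol(s) in set '", nm, "': ", paste(dup, collapse = ", "))
  }
  maps <- lapply(y$pair_maps, function(m) lapply(m, function(v) toupper(unlist(v))))
  if (!is.null(maps)) {
    maps <- lapply(maps, function(m) { names(m) <- toupper(names(m)); m })
  }
  structure(list(sets = sets, pair_maps = maps), class = "gene_set_catalog")
}

#' Report catalog symbols absent from a matrix
#' @param catalog a `gene_set_catalog`.
#' @param x an `expression_matrix` or `copy_number_matrix`.
#' @return named list of character vectors of absent symbols per set.
#' @export
absent_symbols <- function(catalog, x) {
  genes <- if (inherits(x, "copy_number_matrix")) rownames(x$calls) else genes_of(x)
  lapply(catalog$sets, function(s) setdiff(s, genes))
}

#' Intersect expression, copy-number and clinical samples
#'
#' Joins operate on the intersection of sample IDs; the intersection size is
#' reported via message so denominators are never silent.
#'
#' @param expr an `expression_matrix`.
#' @param clin a `clinical_table` or NULL.
#' @param cna a `copy_number_matrix` or NULL.
#' @return character vector of shared sample IDs.
#' @export
shared_samples <- function(expr, clin = NULL, cna = NULL) {
  ids <- samples_of(expr)
  if (!is.null(clin)) ids <- intersect(ids, clin$sample)
  if (!is.null(cna)) ids <- intersect(ids, colnames(cna$calls))
  message(sprintf("sample intersection: n = %d", length(ids)))
  ids
}
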