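#' Published RTK/ligand and TK/EMT co-occurrence tables
#'
#' The printed 2x2 counts (neither / A-only / B-only / both), log2 odds
#' ratios (numeric or the ">3" display cap) and Fisher p-values of the three
#' published co-occurrence screens over the n = 408 MIBC cohort: the
#' RTK-cognate-ligand screen, the EMT-transcriptional-activator screen, and
#' the group 1 / group 2 TK vs EMT TA screens. These counts are inputs: the
#' screen statistics can be recomputed from them without the cohort
#' download.
#'
#' @param which `"rtk_ligand"`, `"emt_ta"`, `"group1_emt"`, `"group2_emt"` or
#'   `"all"` (default).
#' @return data.frame: table_id, label_a, label_b, neither, a_only, b_only,
#'   both, printed_log2_or, printed_p.
#' @export
published_cooccurrence_tables <- function(which = c("all", "rtk_ligand", "emt_ta",
                                                    "group1_emt", "group2_emt")) {
  which <- match.arg(which)
  path <- system.file("extdata", "published_cooccurrence_tables.tsv",
                      package = "coaltk")
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(table_id = "character",
                                         label_a = "character",
                                         label_b = "character",
                                         printed_log2_or = "character",
                                         printed_p = "character"))
  if (which != "all") df <- df[df$table_id == which, ]
  rownames(df) <- NULL
  df
}

#' Bundled TK gene-set catalog
#'
#' The published group 1 (31 genes) and group 2 (21) TK panels, the 19
#' cabozantinib-target RTKs, the 9 EMT transcriptional activators, and the
#' RTK-to-cognate-ligand pair map. The 37-gene group 3 set is completed with
#' representative TK symbols beyond its 10 published members and is labelled
#' synthetic in the shipped file: rely on its size, not its membership.
#'
#' @return a `gene_set_catalog` (see [read_gene_sets()]).
#' @export
tk_gene_sets <- function() {
  read_gene_sets(system.file("extdata", "tk_gene_sets_synthetic.yaml",
                             package = "coaltk"))
}

#' Recompute screen statistics from pre-tabulated 2x2 counts
#'
#' Contingency-override path: consumes a data.frame of printed counts
#' (as returned by [published_cooccurrence_tables()]) instead of an
#' alteration matrix, and computes log2 OR, Fisher p and BH q per row. The
#' FDR family is the set of rows supplied.
#'
#' @param counts data.frame with columns label_a, label_b, neither, a_only,
#'   b_only, both.
#' @param sidedness passed to [fisher_exact()].
#' @return a `pair_screen` data.frame (see [screen_pairs()]).
#' @export
screen_from_counts <- function(counts, sidedness = "one_sided_greater") {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    tab <- contingency_table(counts$neither[i], counts$a_only[i],
                             counts$b_only[i], counts$both[i],
                             counts$label_a[i], counts$label_b[i])
    lor <- log2_odds_ratio(tab)
    data.frame(label_a = tab$label_a, label_b = tab$label_b,
               neither = tab$neither, a_only = tab$a_only,
               b_only = tab$b_only, both = tab$both, log2_or = lor,
               log2_or_display = format_log2_or(lor),
               p = fisher_exact(tab, sidedness), skipped = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_fdr(res$p)
  res$significant <- res$p < 0.05 & res$q < 0.05
  res <- res[, c("label_a", "label_b", "neither", "a_only", "b_only", "both",
                 "log2_or", "log2_or_display", "p", "q", "significant", "skipped")]
  class(res) <- c("pair_screen", "data.frame")
  res
}

#' Text oncoprint of an alteration matrix
#'
#' One row per gene: symbol, altered percentage, and a per-sample glyph
#' string ("O" overexpression, "A" amplification, "M" mutation, "U"
#' underexpression, "D" homozygous deletion, "*" multiple flags, "."
#' unaltered). Genes are sorted by altered frequency (descending); samples
#' are mutually sorted by their alteration pattern over the sorted genes,
#' lexicographic sample ID within pattern.
#'
#' @param alt an `alteration_matrix`.
#' @param genes gene set to display (absent genes dropped).
#' @return character vector of lines (empty for an empty gene set).
#' @export
render_text_oncoprint <- function(alt, genes) {
  genes <- intersect(toupper(genes), rownames(alt$altered))
  if (length(genes) == 0) return(character(0))
  sub <- alt$altered[genes, , drop = FALSE]
  freq <- rowMeans(sub)
  genes <- genes[order(-freq, genes)]
  sub <- sub[genes, , drop = FALSE]
  pattern <- apply(sub, 2, function(col) paste(as.integer(col), collapse = ""))
  ord <- order(pattern, colnames(sub), decreasing = c(TRUE, FALSE), method = "radix")
  glyph_of <- function(f) {
    if (f == "") return(".")
    parts <- strsplit(f, "|", fixed = TRUE)[[1]]
    if (length(parts) > 1) return("*")
    switch(parts, OVEREXPR = "O", AMP = "A", MUT = "M",
           UNDEREXPR = "U", HOMDEL = "D", "?")
  }
  vapply(genes, function(g) {
    glyphs <- vapply(alt$flags[g, ord], glyph_of, character(1))
    sprintf("%-10s %3.0f%% %s", g, 100 * mean(sub[g, ]), paste(glyphs, collapse = ""))
  }, character(1))
}

#' Run the full co-alteration pipeline on a cohort
#'
#' Composes the stages end to end: z-scoring, alteration calling, TK group
#' assignment by the 3-supergroup F test, pairwise co-occurrence screens
#' per TK group, altered-vs-unaltered survival contrasts per group, a text
#' oncoprint, and a run manifest with the denominators of every stage.
#' Deterministic: identical inputs give identical outputs.
#'
#' @param expr raw `expression_matrix`.
#' @param clin `clinical_table`.
#' @param cna optional `copy_number_matrix`.
#' @param mut optional mutation flag matrix.
#' @param config [alteration_config()].
#' @param panel_genes genes to group and screen (default: all genes).
#' @param p_max,q_max grouping significance thresholds (defaults 1e-4 on p
#'   and q, the published panel thresholds).
#' @param r2_min minimum variance explained for grouping (default 0.044).
#' @param sidedness Fisher sidedness for the screens.
#' @param out_dir optional directory: TSV/JSON outputs are written there.
#' @return list bundle: zscores, alt, grouping, screens (per group),
#'   survival (per group x endpoint), oncoprint, manifest.
#' @export
run_pipeline <- function(expr, clin, cna = NULL, mut = NULL,
                         config = alteration_config(),
                         panel_genes = NULL,
                         p_max = 1e-4, q_max = 1e-4, r2_min = 0.044,
                         sidedness = "one_sided_greater",
                         out_dir = NULL) {
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(panel_genes)) panel_genes <- genes_of(expr)
  panel_genes <- toupper(panel_genes)

  z <- stage("zscore", compute_z_scores(expr, config))
  alt <- stage("call", call_alterations(z, cna, mut, config))
  grouping <- stage("group", {
    res <- tk_panel_f_tests(expr, clin, panel_genes)
    assign_tk_groups(res, p_max, q_max, r2_min)
  })
  screens <- stage("screen", {
    out <- list()
    for (g in c("group1", "group2", "group3")) {
      gs <- grouping$gene[grouping$group == g]
      if (length(gs) >= 2)
        out[[g]] <- screen_pairs(alt, gs, "all_pairs", sidedness)
    }
    out
  })
  surv <- stage("survival", {
    out <- list()
    for (g in c("group1", "group2", "group3")) {
      gs <- grouping$gene[grouping$group == g]
      if (length(gs) == 0) next
      cs <- altered_case_set(alt, gs)
      for (ep in c("OS", "DFS")) {
        key <- paste(g, ep, sep = "_")
        out[[key]] <- tryCatch(
          suppressMessages(compare_altered_vs_unaltered(clin, cs, ep)),
          error = function(e) NULL)
      }
    }
    out
  })
  oncoprint <- stage("oncoprint", render_text_oncoprint(alt, panel_genes))
  manifest <- list(
    n_expression_samples = ncol(expr$values),
    n_clinical_samples = nrow(clin),
    n_shared = length(intersect(samples_of(expr), clin$sample)),
    n_panel_genes = length(panel_genes),
    group_counts = as.list(table(grouping$group)),
    z_threshold = config$z_threshold,
    sidedness = sidedness,
    thresholds = list(p_max = p_max, q_max = q_max, r2_min = r2_min))
  bundle <- list(zscores = z, alt = alt, grouping = grouping,
                 screens = screens, survival = surv,
                 oncoprint = oncoprint, manifest = manifest)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(bundle$grouping,
                     file.path(out_dir, "tk_groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (g in names(bundle$screens)) {
    utils::write.table(bundle$screens[[g]],
                       file.path(out_dir, paste0("screen_", g, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  surv_json <- lapply(bundle$survival, function(s) {
    if (is.null(s)) return(NULL)
    list(endpoint = s$endpoint, chisq = s$chisq, p = s$p,
         n_used = s$n_used,
         groups = lapply(s$groups, function(g)
           list(n = g$n, events = g$events,
                median = if (is.na(g$median)) NULL else g$median)))
  })
  jsonlite::write_json(surv_json, file.path(out_dir, "survival_contrasts.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(bundle$oncoprint, file.path(out_dir, "oncoprint.txt"))
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
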