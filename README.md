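# coaltk

Co-alteration screening of tyrosine kinase (TK) genes in muscle-invasive
bladder cancer (MIBC) expression cohorts.

## The problem

Bulk RNA-Seq cohorts of MIBC fall into five molecular phenotypes — neuronal
(N), basal squamous (BS), luminal (L), luminal infiltrating (LI) and luminal
papillary (LP) — with markedly different survival. A recurring question is
whether *potentially oncogenic alterations* of TK genes (mRNA overexpression
and/or gene amplification) co-occur more often than chance, whether
co-altered cases fare worse, and whether receptor TKs are co-altered with
their cognate ligands (the signature of autocrine signaling, e.g. GAS6→AXL,
CSF1→CSF1R, MST1→MST1R). `coaltk` packages that analysis end to end for
anyone with a gene × sample expression matrix, GISTIC-style copy-number
calls and a clinical table:

1. **Alteration calling** — per-gene z-scores
   `z(g,s) = (x(g,s) − μ_g)/σ_g` (sample sd over a reference population);
   a cell is altered when `z > τ` (default τ = 2; 4 for strict calls), the
   copy-number call is +2, or an optional mutation flag is set.
2. **Co-occurrence screening** — for each gene (or gene-set) pair, the
   cohort partitions into a 2×2 table (neither / A-only / B-only / both);
   the screen reports `log2 OR = log2(n11·n00 / (n10·n01))`, the one-sided
   Fisher exact p (hypergeometric, co-occurrence direction), and
   Benjamini–Hochberg q within the screened family; significance requires
   p < 0.05 *and* q < 0.05.
3. **Survival contrasts** — Kaplan–Meier product-limit curves and the
   unweighted two-group log-rank test for altered vs unaltered case sets,
   for OS and DFS.
4. **Phenotype grouping** — one-way F test of each gene's (log) expression
   over the three supergroups LP vs (LI+L) vs (BS+N); significant
   BS/N-high genes form group 1, significant LP-high genes group 2, the
   rest group 3; plus a greedy reduction of a panel to a minimal subset
   preserving the group ratio.
5. **Cell-line phenotyping** — a correlation-template classifier: each
   cell-line profile (absolute mRNA copy number over a TK panel) is
   rank-correlated with every cohort sample; coefficients are averaged per
   phenotype, and the best phenotype must beat the others by Welch t-test
   at p < 0.05 to be *assigned*.
6. **Synthetic cohorts** — a generator producing phenotype-structured
   expression, pairwise-dependent alterations with an exact target odds
   ratio ψ (Plackett construction), exponential survival with a target
   hazard ratio, and noisy cell-line profiles, so every stage is testable
   without any data download.

## Worked example

Screen a published RTK/ligand table, then simulate a cohort with the same
dependence and recover it:

```r
library(coaltk)

tab <- contingency_table(358, 16, 23, 7, label_a = "AXL", label_b = "GAS6")
log2_odds_ratio(tab)          # 2.768 (log2 of 6.81)
fisher_exact(tab, "one_sided_greater")  # 0.000651

spec <- cohort_spec(n_samples = 404,
                    alteration_marginals = c(axl = 0.057, gas6 = 0.074),
                    pair_targets = data.frame(gene_a = "axl", gene_b = "gas6",
                                              odds_ratio = 2^2.768),
                    seed = 17)
alt <- generate_paired_alterations(spec)
screen_pairs(alt, c("AXL", "GAS6"), "all_pairs")
#>   label_a label_b neither a_only b_only both  log2_or log2_or_display
#> 1     AXL    GAS6     356     17     25    6 2.329377           2.329
#>             p           q significant skipped
#> 1 0.004951509 0.004951509        TRUE   FALSE

altered <- altered_case_set(alt, c("AXL", "GAS6"))
clin <- generate_survival(spec, altered)
compare_altered_vs_unaltered(clin, altered, "OS")
#> log-rank: chisq=11.9314 (1 df), p=0.000552
#>   altered: n=48, events=35, median=27.68903
#>   unaltered: n=356, events=164, median=57.14169
```

The single simulated cohort estimates the planted log2 odds ratio of 2.768
as 2.33 (one 404-sample draw carries a sampling sd near 0.9 at these
alteration frequencies), flags the pair as significant, and the doubled
hazard of the altered cases halves their median survival.

The bundled catalog `tk_gene_sets()` carries the TK panel memberships
(group 1: 31 genes, group 2: 21, group 3: 37, cabozantinib-target RTKs: 19,
EMT transcriptional activators: 9) and the RTK→ligand map;
`published_cooccurrence_tables()` carries the printed 2×2 counts of the
three published screens so their statistics can be recomputed without the
cohort download. `run_pipeline()` composes all stages and writes TSV/JSON
reports plus a text oncoprint.

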