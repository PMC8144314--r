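#' Published multiple-sclerosis gene-screen results (example data)
#'
#' Gene-level results for the 28 multiple-sclerosis risk genes that a
#' published gene-based screen of a large MS GWAS (9,772 cases, 17,376
#' controls; 464,357 autosomal SNPs; 10,956 genes shared between the two
#' methods) reported as significant under both gene tests. Per gene:
#' genomic position, SNP count, span (kb) and gene p-value from the
#' set-screen (Fisher/Brown) test, and SNP count and empirical p-value from
#' the simulation-based test. Several set-screen p-values are printed as
#' literally 0 (numeric underflow in the source output); the smallest
#' simulation-test p-values sit at the 1e-6 floor of a 1e6-draw final
#' stage. These records are example *inputs* for the decision layer -- they
#' let the Bonferroni intersection rule be exercised on real published
#' numbers without access to the underlying GWAS.
#'
#' @return Tibble with columns `gene_id`, `position`, `nsnp_setscreen`,
#'   `kb`, `p_setscreen`, `nsnp_sim`, `p_sim`.
#' @export
ms_gene_screen <- function() {
  path <- system.file("extdata", "ms_gene_screen.tsv", package = "genewise")
  readr::read_tsv(path, col_types = "cciddid", progress = FALSE)
}

#' Published MS case-control expression-screen results (example data)
#'
#' Probe-level differential-expression records for the same 28 MS risk
#' genes in two public case-control expression series: peripheral blood
#' mononuclear cells (`pbmc`, 12 MS cases vs 15 controls) and peripheral
#' blood T cells (`pbtc`, 10 vs 10). Per gene and series: the selected
#' (smallest-p) probe, its Benjamini-Hochberg adjusted p-value, raw
#' p-value, and log2 fold change (case minus control). Used as example
#' inputs for the significance-count and fold-change conversion layers.
#'
#' @return Tibble with columns `gene_id`, `series`, `probe_id`, `adj_p`,
#'   `p`, `log_fc`.
#' @export
ms_expression_screen <- function() {
  path <- system.file("extdata", "ms_expression_screen.tsv", package = "genewise")
  readr::read_tsv(path, col_types = "cccddd", progress = FALSE)
}
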