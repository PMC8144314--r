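#' Assign SNPs to genes under a boundary rule
#'
#' Five boundary rules are supported. The kb rules (`0kbloc`, `10kbloc`,
#' `20kbloc`, `50kbloc`) include a SNP iff its position lies in
#' `[start - flank, end + flank]` (1-based closed, ties at the boundary
#' included). The LD-bin rule (`0kbldbin`) includes the SNPs inside the gene
#' body plus any same-chromosome SNP outside it whose squared dosage
#' correlation with at least one in-gene SNP is strictly greater than
#' `r2_threshold`; it requires a reference panel. A SNP may belong to
#' several (overlapping) genes. Genes with no assigned SNP are dropped and
#' counted.
#'
#' @param genes Tibble of gene models (`gene_id`, `chrom`, `start`, `end`),
#'   1-based closed.
#' @param snps Tibble of SNP association records (`snp_id`, `chrom`, `pos`,
#'   `p`), e.g. from [read_summary_stats()] or [trend_test()].
#' @param rule One of `"0kbloc"`, `"10kbloc"`, `"20kbloc"`, `"50kbloc"`,
#'   `"0kbldbin"`.
#' @param panel Reference `genotype_panel`; required for `0kbldbin`.
#' @param r2_threshold LD-bin inclusion threshold on r^2 (strict `>`),
#'   default 0.8.
#' @return Tibble with one row per (gene, SNP) assignment: `gene_id`,
#'   `snp_id`, `chrom`, `pos`, `p`, `rule`, ordered by gene then position.
#'   Attributes: `dropped_genes` (ids with zero SNPs), `n_unmapped_snps`
#'   (SNPs assigned to no gene).
#' @export
map_snps <- function(genes, snps, rule = c("0kbloc", "10kbloc", "20kbloc",
                                           "50kbloc", "0kbldbin"),
                     panel = NULL, r2_threshold = 0.8) {
  rule <- tryCatch(match.arg(rule), error = function(e) {
    stop_param(paste0("unknown boundary rule: ", rule[1]))
  })
  if (rule == "0kbldbin" && is.null(panel)) {
    stop_param("rule '0kbldbin' requires a reference panel for LD")
  }
  flank <- switch(rule,
    "0kbloc" = 0L, "10kbloc" = 10000L, "20kbloc" = 20000L,
    "50kbloc" = 50000L, "0kbldbin" = 0L
  )
  check_prob_open_closed(snps$p, "snps$p")

  assign_one <- function(gene_id, chrom, start, end) {
    on_chrom <- snps[snps$chrom == chrom, , drop = FALSE]
    inside <- on_chrom$pos >= start - flank & on_chrom$pos <= end + flank
    picked <- on_chrom[inside, , drop = FALSE]
    if (rule == "0kbldbin" && nrow(picked) > 0) {
      outside <- on_chrom[!inside, , drop = FALSE]
      in_panel_out <- outside$snp_id[outside$snp_id %in% colnames(panel$dosage)]
      in_panel_in <- picked$snp_id[picked$snp_id %in% colnames(panel$dosage)]
      if (length(in_panel_out) && length(in_panel_in)) {
        r <- suppressWarnings(stats::cor(
          panel$dosage[, in_panel_out, drop = FALSE],
          panel$dosage[, in_panel_in, drop = FALSE]
        ))
        r[is.na(r)] <- 0
        hit <- in_panel_out[apply(r^2, 1, max) > r2_threshold]
        picked <- dplyr::bind_rows(picked, outside[outside$snp_id %in% hit, , drop = FALSE])
      }
    }
    if (!nrow(picked)) return(NULL)
    picked <- picked[order(picked$pos, picked$snp_id), , drop = FALSE]
    tibble(
      gene_id = gene_id, snp_id = picked$snp_id, chrom = picked$chrom,
      pos = picked$pos, p = picked$p, rule = rule
    )
  }

  pieces <- purrr::pmap(
    list(genes$gene_id, genes$chrom, genes$start, genes$end), assign_one
  )
  kept <- !purrr::map_lgl(pieces, is.null)
  out <- dplyr::bind_rows(pieces[kept])
  if (!nrow(out)) {
    out <- tibble(gene_id = character(), snp_id = character(), chrom = character(),
                  pos = integer(), p = numeric(), rule = character())
  }
  attr(out, "dropped_genes") <- genes$gene_id[!kept]
  attr(out, "n_unmapped_snps") <- sum(!snps$snp_id %in% out$snp_id)
  out
}

#' Gene ids appearing in both of two per-gene result tables
#'
#' @param results_a,results_b Data frames with a `gene_id` column (or bare
#'   character vectors of gene ids).
#' @return Character vector of shared gene ids.
#' @export
shared_genes <- function(results_a, results_b) {
  ids <- function(x) if (is.data.frame(x)) x$gene_id else as.character(x)
  intersect(ids(results_a), ids(results_b))
}
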