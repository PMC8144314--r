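# Small builders shared by the tests; everything is generated in code.

# panel whose genes coincide with LD blocks, plus matching gene models
block_panel <- function(n_genes, snps_per_gene, rho, n_samples, seed,
                        maf_range = c(0.1, 0.5)) {
  spec <- ld_block_spec(snps_per_gene, n_genes,
    within_block_rho = rho,
    maf_range = maf_range
  )
  panel <- simulate_genotypes(spec, n_samples, seed)
  genes <- panel$snps |>
    dplyr::group_by(block) |>
    dplyr::summarise(
      gene_id = sprintf("GENE%04d", block[1]),
      chrom = chrom[1], start = min(pos), end = max(pos),
      .groups = "drop"
    ) |>
    dplyr::select(gene_id, chrom, start, end)
  list(panel = panel, genes = genes)
}

# the shipped 28-gene screen as two per-gene result tables, with the
# printed-zero p-values floored the same way the summary-stat reader does
example_gene_results <- function() {
  tab <- ms_gene_screen()
  floor0 <- function(p) ifelse(p == 0, .Machine$double.xmin, p)
  list(
    setscreen = tibble::tibble(
      gene_id = tab$gene_id, n_snps = tab$nsnp_setscreen,
      kb = tab$kb, gene_p = floor0(tab$p_setscreen)
    ),
    sim = tibble::tibble(
      gene_id = tab$gene_id, n_snps = tab$nsnp_sim,
      gene_p = tab$p_sim
    )
  )
}
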