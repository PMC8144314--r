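#' Read SNP-level GWAS summary statistics
#'
#' Expects a tab-delimited file whose header contains the columns SNP, CHR,
#' BP and P (case-insensitive, any order; extra columns ignored). Rows with
#' an unparseable or out-of-range p-value (p < 0 or p > 1) or a
#' non-positive position are rejected with a row-numbered warning. A p-value
#' printed as exactly 0 is accepted but flagged as an underflow: the stored
#' `p` used in computation is the smallest positive double while `p_display`
#' preserves the printed 0.
#'
#' @param path Path to the TSV file.
#' @return Tibble of SNP association records: `snp_id`, `chrom`, `pos`,
#'   `p`, `p_display`, `underflow`. Attribute `n_rejected` counts dropped
#'   rows.
#' @export
read_summary_stats <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  nm <- toupper(names(raw))
  need <- c("SNP", "CHR", "BP", "P")
  missing_cols <- setdiff(need, nm)
  if (length(missing_cols)) {
    stop_format(paste0("summary statistics missing column(s): ",
                       paste(missing_cols, collapse = ", ")))
  }
  idx <- match(need, nm)
  out <- tibble(
    snp_id = raw[[idx[1]]],
    chrom = raw[[idx[2]]],
    pos = suppressWarnings(as.integer(raw[[idx[3]]])),
    p_display = suppressWarnings(as.numeric(raw[[idx[4]]]))
  )
  bad <- is.na(out$snp_id) | is.na(out$pos) | out$pos < 1 |
    is.na(out$p_display) | out$p_display < 0 | out$p_display > 1
  if (any(bad)) {
    warn(sprintf(
      "rejected %d malformed summary-statistic row(s): %s",
      sum(bad), paste(which(bad), collapse = ", ")
    ))
    out <- out[!bad, , drop = FALSE]
  }
  if (anyDuplicated(out$snp_id)) {
    stop_format(paste0("duplicate SNP id(s): ",
                       paste(unique(out$snp_id[duplicated(out$snp_id)]), collapse = ", ")))
  }
  out$underflow <- out$p_display == 0
  out$p <- ifelse(out$underflow, .Machine$double.xmin, out$p_display)
  out <- out[, c("snp_id", "chrom", "pos", "p", "p_display", "underflow")]
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Write summary statistics as a 4-column TSV (SNP, CHR, BP, P)
#'
#' @param stats Tibble with `snp_id`, `chrom`, `pos` and `p` (or
#'   `p_display`) columns, e.g. from [trend_test()] or [read_summary_stats()].
#' @param path Output path.
#' @export
write_summary_stats <- function(stats, path) {
  p_out <- if ("p_display" %in% names(stats)) stats$p_display else stats$p
  readr::write_tsv(
    tibble(SNP = stats$snp_id, CHR = stats$chrom, BP = stats$pos, P = p_out),
    path, progress = FALSE
  )
  invisible(path)
}

#' Read gene models
#'
#' Two dialects are supported: `bed0` (headerless BED3+1: chrom, start, end,
#' gene id; 0-based half-open) and `tsv1` (headered TSV with columns GENE,
#' CHROM, START, END in any order, case-insensitive; 1-based closed).
#' Internally all coordinates are 1-based closed, so `bed0` starts are
#' shifted by +1 on read.
#'
#' @param path Path to the file.
#' @param dialect `"bed0"` or `"tsv1"`.
#' @return Tibble of gene models: `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_models <- function(path, dialect = c("bed0", "tsv1")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed0") {
    raw <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "gene_id"),
                           col_types = "ciic", progress = FALSE)
    out <- tibble(
      gene_id = raw$gene_id, chrom = raw$chrom,
      start = raw$start + 1L, end = raw$end
    )
  } else {
    raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    nm <- toupper(names(raw))
    need <- c("GENE", "CHROM", "START", "END")
    if (!all(need %in% nm)) {
      stop_format(paste0("gene model file missing column(s): ",
                         paste(setdiff(need, nm), collapse = ", ")))
    }
    out <- tibble(
      gene_id = as.character(raw[[match("GENE", nm)]]),
      chrom = as.character(raw[[match("CHROM", nm)]]),
      start = as.integer(raw[[match("START", nm)]]),
      end = as.integer(raw[[match("END", nm)]])
    )
  }
  bad <- out$start > out$end
  if (any(bad)) {
    stop_format(sprintf(
      "gene interval(s) empty after coordinate conversion: %s",
      paste(out$gene_id[bad], collapse = ", ")
    ))
  }
  if (anyDuplicated(out$gene_id)) stop_format("duplicate gene id(s) in gene models")
  out
}

#' Write gene models as BED3+1 (0-based half-open)
#'
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end` (1-based
#'   closed internal convention).
#' @param path Output path.
#' @export
write_gene_models_bed <- function(genes, path) {
  readr::write_tsv(
    tibble(chrom = genes$chrom, start = genes$start - 1L,
           end = genes$end, gene_id = genes$gene_id),
    path, col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Read a reference genotype panel
#'
#' `vcf` reads a VCF v4.x file via \pkg{vcfR}; only biallelic records are
#' kept (multi-allelic rows are skipped with a warning) and dosages are the
#' per-sample counts of the alternate allele in the GT field. `dosage_tsv`
#' reads the plain matrix format written by [write_dosage_tsv()]: one row
#' per SNP with columns SNP, CHR, BP then one column per sample holding
#' 0/1/2. Missing genotypes are mean-imputed per SNP (for LD computation
#' only); the number of imputed calls is reported in attribute `n_imputed`.
#'
#' @param path Input path.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @return A `genotype_panel` (see [simulate_genotypes()]).
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT %||% "")
    if (any(multi)) {
      warn(sprintf("skipped %d multi-allelic VCF record(s)", sum(multi)))
    }
    keep <- !multi
    if (!any(keep)) stop_format("no biallelic records in VCF")
    gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
    count_alt <- function(x) {
      ifelse(is.na(x) | x %in% c(".", "./.", ".|."), NA_real_,
             vapply(strsplit(x, "[/|]"), function(a) sum(a == "1"), numeric(1)))
    }
    dos <- apply(gt, 2, count_alt)
    if (is.null(dim(dos))) dos <- matrix(dos, nrow = sum(keep), dimnames = list(NULL, colnames(gt)))
    ids <- fix$ID[keep]
    ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM[keep], ":", fix$POS[keep])[is.na(ids) | ids == "."]
    rownames(dos) <- ids
    snps <- tibble(snp_id = ids, chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]))
    mat <- t(dos)
  } else {
    raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    nm <- toupper(names(raw))
    need <- c("SNP", "CHR", "BP")
    if (!all(need %in% nm)) {
      stop_format("dosage TSV must have SNP, CHR, BP then sample columns")
    }
    sample_cols <- setdiff(seq_along(raw), match(need, nm))
    if (!length(sample_cols)) stop_format("dosage TSV has no sample columns")
    snps <- tibble(
      snp_id = as.character(raw[[match("SNP", nm)]]),
      chrom = as.character(raw[[match("CHR", nm)]]),
      pos = as.integer(raw[[match("BP", nm)]])
    )
    mat <- t(as.matrix(raw[, sample_cols]))
    colnames(mat) <- snps$snp_id
  }
  if (!nrow(mat) || !ncol(mat)) stop_format("empty genotype panel")
  n_imputed <- sum(is.na(mat))
  if (n_imputed > 0) {
    for (j in which(colSums(is.na(mat)) > 0)) {
      mj <- mean(mat[, j], na.rm = TRUE)
      mat[is.na(mat[, j]), j] <- if (is.nan(mj)) 0 else mj
    }
  }
  structure(
    list(dosage = mat, snps = snps, n_imputed = n_imputed),
    class = "genotype_panel"
  )
}

#' Write a genotype panel as a dosage TSV
#'
#' One row per SNP: SNP, CHR, BP, then one 0/1/2 column per sample.
#'
#' @param panel A `genotype_panel`.
#' @param path Output path.
#' @export
write_dosage_tsv <- function(panel, path) {
  d <- t(panel$dosage)
  out <- dplyr::bind_cols(
    tibble(SNP = panel$snps$snp_id, CHR = panel$snps$chrom, BP = panel$snps$pos),
    as_tibble(d, .name_repair = "minimal")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a genotype panel as an unphased VCF
#'
#' Dosages 0/1/2 become GT 0/0, 0/1, 1/1 with placeholder REF/ALT alleles.
#'
#' @param panel A `genotype_panel`.
#' @param path Output path.
#' @export
write_genotypes_vcf <- function(panel, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=genewise",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            rownames(panel$dosage)), collapse = "\t")
  )
  rows <- vapply(seq_len(ncol(panel$dosage)), function(j) {
    dos <- round(panel$dosage[, j])
    paste(c(panel$snps$chrom[j], panel$snps$pos[j], panel$snps$snp_id[j],
            "A", "G", ".", "PASS", ".", "GT", gt_code[dos + 1]), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a probe-level expression matrix with group labels and probe map
#'
#' @param matrix_path TSV: first column probe ids, remaining columns one per
#'   sample (log2 intensities), header row of sample ids.
#' @param groups_path TSV with columns `sample_id` and `group` (labels must
#'   be `case`/`control`).
#' @param map_path TSV with columns `probe_id` and `gene_id`.
#' @return An `expression_set` (see [simulate_expression()]); matrix columns
#'   without a group label are dropped with a warning, all-constant probes
#'   are flagged in attribute `constant_probes`.
#' @export
read_expression <- function(matrix_path, groups_path, map_path) {
  raw <- readr::read_tsv(matrix_path, col_types = readr::cols(), progress = FALSE)
  mat <- as.matrix(raw[, -1])
  rownames(mat) <- as.character(raw[[1]])
  groups <- readr::read_tsv(groups_path, col_types = "cc", progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(groups))) {
    stop_format("groups file must have columns sample_id and group")
  }
  if (!all(groups$group %in% c("case", "control"))) {
    stop_format("group labels must be 'case' or 'control'")
  }
  if (!all(groups$sample_id %in% colnames(mat))) {
    stop_format("groups file lists samples absent from the matrix")
  }
  unlabeled <- setdiff(colnames(mat), groups$sample_id)
  if (length(unlabeled)) {
    warn(sprintf("dropping %d unlabeled sample column(s): %s",
                 length(unlabeled), paste(unlabeled, collapse = ", ")))
    mat <- mat[, groups$sample_id, drop = FALSE]
  } else {
    mat <- mat[, groups$sample_id, drop = FALSE]
  }
  if (sum(groups$group == "case") < 2 || sum(groups$group == "control") < 2) {
    stop_format("need at least 2 samples per group")
  }
  map <- readr::read_tsv(map_path, col_types = "cc", progress = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(map))) {
    stop_format("probe map must have columns probe_id and gene_id")
  }
  constant <- rownames(mat)[apply(mat, 1, function(x) diff(range(x)) == 0)]
  out <- structure(
    list(matrix = mat, probe_map = map, groups = groups),
    class = "expression_set"
  )
  attr(out, "constant_probes") <- constant
  out
}

#' Write an expression set to TSV files
#'
#' @param eset An `expression_set`.
#' @param matrix_path,groups_path,map_path Output paths.
#' @export
write_expression <- function(eset, matrix_path, groups_path, map_path) {
  out <- dplyr::bind_cols(
    tibble(probe_id = rownames(eset$matrix)),
    as_tibble(eset$matrix, .name_repair = "minimal")
  )
  readr::write_tsv(out, matrix_path, progress = FALSE)
  readr::write_tsv(eset$groups, groups_path, progress = FALSE)
  readr::write_tsv(eset$probe_map, map_path, progress = FALSE)
  invisible(matrix_path)
}
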