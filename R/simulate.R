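#' Specify an LD-block genotype model
#'
#' Describes a panel of independent linkage-disequilibrium (LD) blocks.
#' Within a block the latent liability of adjacent SNPs follows an AR(1)
#' process with parameter `within_block_rho`, so SNPs `k` steps apart have
#' latent correlation `rho^k` (monotonically decaying LD); blocks are
#' mutually independent. Genotypes are produced by thresholding two latent
#' haplotypes per individual at the Hardy-Weinberg quantile of each SNP's
#' allele frequency, which attenuates the latent correlation towards the
#' dosage scale in the usual way.
#'
#' @param n_snps_per_block SNPs per block (positive integer).
#' @param n_blocks Number of independent blocks.
#' @param within_block_rho AR(1) decay parameter in `[0, 1)`.
#' @param maf_range Length-2 numeric in `(0, 0.5]`; per-SNP minor-allele
#'   frequencies are drawn uniformly from this interval.
#' @param bp_spacing Base pairs between adjacent SNPs within a block.
#' @param block_gap_bp Base pairs separating consecutive blocks.
#' @return A list of class `ld_block_spec`.
#' @export
ld_block_spec <- function(n_snps_per_block,
                          n_blocks = 1L,
                          within_block_rho = 0,
                          maf_range = c(0.05, 0.5),
                          bp_spacing = 5000L,
                          block_gap_bp = 1e6) {
  n_snps_per_block <- check_count(n_snps_per_block, "n_snps_per_block")
  n_blocks <- check_count(n_blocks, "n_blocks")
  if (!is.numeric(within_block_rho) || length(within_block_rho) != 1 ||
      is.na(within_block_rho) || within_block_rho < 0 || within_block_rho >= 1) {
    stop_param("`within_block_rho` must lie in [0, 1)")
  }
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop_param("`maf_range` must be an increasing pair in (0, 0.5]")
  }
  bp_spacing <- check_count(bp_spacing, "bp_spacing")
  structure(
    list(
      n_snps_per_block = n_snps_per_block,
      n_blocks = n_blocks,
      within_block_rho = within_block_rho,
      maf_range = as.numeric(maf_range),
      bp_spacing = bp_spacing,
      block_gap_bp = as.numeric(block_gap_bp)
    ),
    class = "ld_block_spec"
  )
}

#' Simulate an LD-structured genotype panel
#'
#' Draws two latent AR(1) Gaussian haplotypes per individual and thresholds
#' each at `qnorm(maf)` per SNP; the dosage is the minor-allele count (0/1/2),
#' which is in Hardy-Weinberg equilibrium at the drawn allele frequency.
#' The same `(spec, n_samples, seed)` triple always returns a bit-identical
#' panel.
#'
#' @param spec An [ld_block_spec()].
#' @param n_samples Number of individuals (>= 2).
#' @param seed Integer seed.
#' @return A `genotype_panel`: list with `dosage` (samples x SNPs integer
#'   matrix) and `snps` (tibble: `snp_id`, `chrom`, `pos`, `block`, `maf`).
#' @export
simulate_genotypes <- function(spec, n_samples, seed) {
  if (!inherits(spec, "ld_block_spec")) stop_param("`spec` must be an ld_block_spec")
  n_samples <- check_count(n_samples, "n_samples", min = 2)

  m <- spec$n_snps_per_block
  B <- spec$n_blocks
  rho <- spec$within_block_rho
  n_snp <- m * B

  withr::with_seed(as.integer(seed), {
    maf <- runif(n_snp, spec$maf_range[1], spec$maf_range[2])
    thr <- qnorm(maf)
    H <- 2L * n_samples
    dosage <- matrix(0L, n_samples, n_snp)
    for (b in seq_len(B)) {
      z <- matrix(0, H, m)
      z[, 1] <- rnorm(H)
      if (m > 1) {
        sig <- sqrt(1 - rho^2)
        for (k in 2:m) z[, k] <- rho * z[, k - 1] + sig * rnorm(H)
      }
      cols <- (b - 1L) * m + seq_len(m)
      alle <- z < rep(thr[cols], each = H)
      dosage[, cols] <- alle[seq(1, H, by = 2), , drop = FALSE] +
        alle[seq(2, H, by = 2), , drop = FALSE]
    }
    block <- rep(seq_len(B), each = m)
    within <- rep(seq_len(m), times = B)
    pos <- (block - 1) * (m * spec$bp_spacing + spec$block_gap_bp) +
      (within - 1) * spec$bp_spacing + 1
    snp_id <- sprintf("snp%06d", seq_len(n_snp))
    dimnames(dosage) <- list(sprintf("S%05d", seq_len(n_samples)), snp_id)
    structure(
      list(
        dosage = dosage,
        snps = tibble(
          snp_id = snp_id, chrom = "1", pos = as.integer(pos),
          block = block, maf = maf
        )
      ),
      class = "genotype_panel"
    )
  })
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "<genotype_panel> %d samples x %d SNPs (%d block(s))\n",
    nrow(x$dosage), ncol(x$dosage), max(x$snps$block)
  ))
  invisible(x)
}

#' Specify a case-control phenotype model
#'
#' Disease liability follows a logistic model: the log-odds of disease for
#' individual `i` is `qlogis(baseline_prevalence) + sum_j beta_j g_ij` over
#' the causal SNPs. With no causal SNPs every SNP is null.
#'
#' @param n_cases,n_controls Case/control quotas to sample from the cohort.
#' @param causal_snps Named numeric vector of per-allele log odds ratios;
#'   names are SNP ids (or panel column indices as character). Empty for a
#'   fully null model.
#' @param baseline_prevalence Disease probability at dosage 0, in `(0, 1)`.
#' @return A list of class `pheno_model`.
#' @export
pheno_model <- function(n_cases, n_controls,
                        causal_snps = numeric(),
                        baseline_prevalence = 0.3) {
  n_cases <- check_count(n_cases, "n_cases")
  n_controls <- check_count(n_controls, "n_controls")
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1) {
    stop_param("`baseline_prevalence` must lie strictly in (0, 1)")
  }
  if (length(causal_snps) && is.null(names(causal_snps))) {
    stop_param("`causal_snps` must be named by SNP id or column index")
  }
  structure(
    list(
      n_cases = n_cases, n_controls = n_controls,
      causal_snps = causal_snps,
      baseline_prevalence = baseline_prevalence
    ),
    class = "pheno_model"
  )
}

#' Sample case-control phenotypes retrospectively from a cohort
#'
#' Each cohort member's disease status is drawn from the logistic model;
#' repeated thinning rounds assign drawn cases (controls) to the case
#' (control) pool until both quotas are exactly met, mirroring a
#' retrospective case-control design. Individuals drawn for an already-full
#' pool are returned to the pool of unassigned members and redrawn.
#'
#' @param panel A `genotype_panel` (or bare dosage matrix, samples x SNPs).
#' @param model A [pheno_model()].
#' @param seed Integer seed.
#' @return Tibble with `sample_id`, `sample_index` (row in the panel) and
#'   `status` (1 = case, 0 = control); cases first.
#' @export
simulate_phenotypes <- function(panel, model, seed) {
  G <- if (inherits(panel, "genotype_panel")) panel$dosage else panel
  if (!inherits(model, "pheno_model")) stop_param("`model` must be a pheno_model")
  n <- nrow(G)
  if (model$n_cases + model$n_controls > n) {
    abort(sprintf(
      "cohort of %d cannot supply %d cases + %d controls",
      n, model$n_cases, model$n_controls
    ), class = "genewise_simulation_error")
  }
  eta <- rep(qlogis(model$baseline_prevalence), n)
  if (length(model$causal_snps)) {
    ids <- names(model$causal_snps)
    idx <- if (all(grepl("^[0-9]+$", ids))) as.integer(ids) else match(ids, colnames(G))
    if (anyNA(idx) || any(idx < 1) || any(idx > ncol(G))) {
      stop_param("causal SNP ids/indices not found in the panel")
    }
    eta <- eta + drop(G[, idx, drop = FALSE] %*% model$causal_snps)
  }
  pi <- plogis(eta)

  withr::with_seed(as.integer(seed), {
    unassigned <- seq_len(n)
    cases <- controls <- integer()
    for (round in seq_len(10000L)) {
      if (length(cases) >= model$n_cases && length(controls) >= model$n_controls) break
      if (!length(unassigned)) break
      y <- rbinom(length(unassigned), 1L, pi[unassigned])
      new_cases <- unassigned[y == 1L]
      new_controls <- unassigned[y == 0L]
      take_ca <- head(new_cases, model$n_cases - length(cases))
      take_co <- head(new_controls, model$n_controls - length(controls))
      cases <- c(cases, take_ca)
      controls <- c(controls, take_co)
      unassigned <- setdiff(unassigned, c(take_ca, take_co))
    }
    if (length(cases) < model$n_cases || length(controls) < model$n_controls) {
      abort("case/control quota unreachable under this phenotype model",
        class = "genewise_simulation_error"
      )
    }
    sel <- c(cases, controls)
    tibble(
      sample_id = if (!is.null(rownames(G))) rownames(G)[sel] else as.character(sel),
      sample_index = sel,
      status = rep(c(1L, 0L), c(length(cases), length(controls)))
    )
  })
}

#' Cochran-Armitage trend test per SNP
#'
#' The standard 1-df trend chi-square for a 2 x 3 case-control by dosage
#' table with scores (0, 1, 2), computed in its `N * r^2` form (`r` the
#' Pearson correlation between phenotype and dosage). Monomorphic SNPs get
#' statistic 0, p = 1 and `monomorphic = TRUE`.
#'
#' @param panel A `genotype_panel` or dosage matrix.
#' @param phenotypes Either a 0/1 vector aligned to panel rows, or the
#'   tibble returned by [simulate_phenotypes()] (rows are subset to its
#'   `sample_index`).
#' @return Tibble of SNP association records: `snp_id`, `chrom`, `pos`,
#'   `stat`, `p`, `monomorphic`.
#' @export
trend_test <- function(panel, phenotypes) {
  G <- if (inherits(panel, "genotype_panel")) panel$dosage else panel
  info <- if (inherits(panel, "genotype_panel")) {
    panel$snps
  } else {
    tibble(
      snp_id = colnames(G) %||% sprintf("snp%06d", seq_len(ncol(G))),
      chrom = NA_character_, pos = NA_integer_
    )
  }
  if (is.data.frame(phenotypes)) {
    G <- G[phenotypes$sample_index, , drop = FALSE]
    y <- phenotypes$status
  } else {
    y <- phenotypes
  }
  if (!all(y %in% c(0, 1))) stop_param("phenotypes must be binary 0/1")
  if (length(y) != nrow(G)) stop_param("phenotype length must match panel rows")
  if (all(y == 1) || all(y == 0)) {
    stop_param("need at least one case and one control")
  }

  n <- length(y)
  yc <- y - mean(y)
  syy <- sum(yc^2)
  if (anyNA(G)) {
    res <- vapply(seq_len(ncol(G)), function(j) {
      ok <- !is.na(G[, j])
      g <- G[ok, j]
      yj <- y[ok]
      sgg <- sum((g - mean(g))^2)
      if (sgg == 0) return(c(0, 1, 1))
      num <- sum((yj - mean(yj)) * (g - mean(g)))
      stat <- length(yj) * num^2 / (sum((yj - mean(yj))^2) * sgg)
      c(stat, pchisq(stat, 1, lower.tail = FALSE), 0)
    }, numeric(3))
    stat <- res[1, ]
    p <- res[2, ]
    mono <- res[3, ] == 1
  } else {
    gm <- colMeans(G)
    num <- drop(crossprod(G, yc)) # sum((g - gm) * yc) since sum(yc) = 0
    sgg <- colSums(G^2) - n * gm^2
    mono <- sgg <= .Machine$double.eps * n
    stat <- ifelse(mono, 0, n * num^2 / (syy * pmax(sgg, .Machine$double.eps)))
    p <- ifelse(mono, 1, pchisq(stat, 1, lower.tail = FALSE))
  }
  tibble(
    snp_id = info$snp_id, chrom = info$chrom, pos = info$pos,
    stat = stat, p = pmin(p, 1), monomorphic = mono
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specify a two-group probe-level expression model
#'
#' Expression is simulated on the log2 scale: each gene has a baseline mean,
#' each of its probes a fixed offset, and each measurement independent
#' Gaussian noise. Genes listed in `de_genes` have their stated true log2
#' fold change added to the case group; all other genes have true log2 FC 0.
#'
#' @param n_genes Number of genes.
#' @param probes_per_gene Probes measuring each gene (>= 1).
#' @param n_cases,n_controls Samples per group.
#' @param de_genes Named numeric vector: gene id -> true log2 fold change
#'   (case minus control).
#' @param noise_sd Standard deviation of log2-scale measurement noise.
#' @param baseline_mean,baseline_sd Distribution of gene baseline means.
#' @param probe_offset_sd Spread of fixed per-probe offsets.
#' @return A list of class `expr_spec`.
#' @export
expr_spec <- function(n_genes, probes_per_gene = 1L,
                      n_cases, n_controls,
                      de_genes = numeric(),
                      noise_sd = 0.3,
                      baseline_mean = 8, baseline_sd = 1.5,
                      probe_offset_sd = 0.25) {
  n_genes <- check_count(n_genes, "n_genes")
  probes_per_gene <- check_count(probes_per_gene, "probes_per_gene")
  n_cases <- check_count(n_cases, "n_cases")
  n_controls <- check_count(n_controls, "n_controls")
  if (noise_sd <= 0) stop_param("`noise_sd` must be positive")
  if (length(de_genes) && is.null(names(de_genes))) {
    stop_param("`de_genes` must be named by gene id")
  }
  structure(
    list(
      n_genes = n_genes, probes_per_gene = probes_per_gene,
      n_cases = n_cases, n_controls = n_controls,
      de_genes = de_genes, noise_sd = noise_sd,
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      probe_offset_sd = probe_offset_sd
    ),
    class = "expr_spec"
  )
}

#' Simulate a probe-level expression matrix
#'
#' @param spec An [expr_spec()].
#' @param seed Integer seed.
#' @return An `expression_set`: list with `matrix` (probes x samples, log2
#'   scale), `probe_map` (tibble `probe_id`, `gene_id`) and `groups`
#'   (tibble `sample_id`, `group` in case/control).
#' @export
simulate_expression <- function(spec, seed) {
  if (!inherits(spec, "expr_spec")) stop_param("`spec` must be an expr_spec")
  gene_id <- sprintf("G%04d", seq_len(spec$n_genes))
  lfc <- setNames(numeric(spec$n_genes), gene_id)
  if (length(spec$de_genes)) {
    unknown <- setdiff(names(spec$de_genes), gene_id)
    if (length(unknown)) {
      stop_param(paste0("de_genes not in panel: ", paste(unknown, collapse = ", ")))
    }
    lfc[names(spec$de_genes)] <- spec$de_genes
  }
  n_probe <- spec$n_genes * spec$probes_per_gene
  probe_gene <- rep(gene_id, each = spec$probes_per_gene)
  probe_id <- paste0(probe_gene, "_p", rep(seq_len(spec$probes_per_gene), spec$n_genes))
  n_samp <- spec$n_cases + spec$n_controls
  group <- rep(c("case", "control"), c(spec$n_cases, spec$n_controls))
  sample_id <- sprintf("%s%02d", ifelse(group == "case", "CASE", "CTRL"),
                       c(seq_len(spec$n_cases), seq_len(spec$n_controls)))

  withr::with_seed(as.integer(seed), {
    gene_mu <- rnorm(spec$n_genes, spec$baseline_mean, spec$baseline_sd)
    probe_off <- rnorm(n_probe, 0, spec$probe_offset_sd)
    base <- gene_mu[match(probe_gene, gene_id)] + probe_off
    shift <- outer(lfc[probe_gene], as.numeric(group == "case"))
    mat <- base + shift + matrix(rnorm(n_probe * n_samp, 0, spec$noise_sd), n_probe, n_samp)
    dimnames(mat) <- list(probe_id, sample_id)
    structure(
      list(
        matrix = mat,
        probe_map = tibble(probe_id = probe_id, gene_id = probe_gene),
        groups = tibble(sample_id = sample_id, group = group)
      ),
      class = "expression_set"
    )
  })
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf(
    "<expression_set> %d probes x %d samples (%d case / %d control)\n",
    nrow(x$matrix), ncol(x$matrix),
    sum(x$groups$group == "case"), sum(x$groups$group == "control")
  ))
  invisible(x)
}
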