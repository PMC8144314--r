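#' Convert a p-value to a 1-df chi-square statistic
#'
#' Inverse upper-tail transform: the statistic whose chi-square(1) survival
#' probability equals `p`. `p = 1` maps to 0.
#'
#' @param p P-value(s) in `(0, 1]`.
#' @return Chi-square(1) statistic(s).
#' @export
p_to_chisq1 <- function(p) {
  check_prob_open_closed(p, "p")
  qchisq(p, df = 1, lower.tail = FALSE)
}

#' Simulation-based gene test with a multivariate-normal LD null
#'
#' The observed statistic is the sum of the SNPs' 1-df chi-square
#' transforms, `sum(p_to_chisq1(p_i))` -- chi-square with n df if the SNPs
#' are in linkage equilibrium. Under LD the null is simulated: draws
#' `z ~ MVN(0, R)` (R the PSD-repaired LD correlation matrix, via its
#' Cholesky factor) give null statistics `sum(z_i^2)`, and the empirical
#' gene p-value is `(n_exceed + 1) / (n_sims + 1)`, which can never be 0 --
#' at the default final stage of 1e6 simulations the smallest reportable
#' value is ~1.0e-6. An adaptive schedule promotes a gene to the next,
#' larger simulation stage while its current empirical p is at or below
#' that stage's promotion threshold, so only promising genes pay for the
#' big stages. The random stream is derived from `(seed, stream_key)` so
#' per-gene results do not depend on processing order.
#'
#' @param p SNP p-values in `(0, 1]`, ordered as in `ld`.
#' @param ld An `ld_matrix` or correlation matrix; `NULL` for independence.
#' @param stages Increasing vector of simulation counts per stage.
#' @param thresholds Promotion thresholds, one fewer than `stages`: proceed
#'   to stage `k + 1` while the stage-`k` empirical p is `<=` threshold `k`.
#' @param seed Master integer seed.
#' @param stream_key Key (e.g. the gene id) hashed with `seed` to give this
#'   gene its own reproducible stream.
#' @return A one-row tibble: `n_snps`, `observed_stat`, `n_sims`,
#'   `n_exceed`, `gene_p`, `ridge`, plus a `stage_trace` list-column of
#'   per-stage `(n_sims, p)`.
#' @export
vegas_test <- function(p, ld = NULL,
                       stages = c(1e3, 1e4, 1e6),
                       thresholds = c(0.1, 0.001),
                       seed = 1L, stream_key = "gene") {
  check_prob_open_closed(p, "p")
  n <- length(p)
  if (is.unsorted(stages, strictly = TRUE)) {
    stop_param("`stages` must be strictly increasing")
  }
  if (length(thresholds) != length(stages) - 1) {
    stop_param("`thresholds` must have one fewer entry than `stages`")
  }
  observed <- sum(p_to_chisq1(p))
  if (is.null(ld)) {
    L <- diag(1, n)
    ridge <- 0
  } else {
    R <- if (inherits(ld, "ld_matrix")) ld$r else ld
    if (nrow(R) != n) stop_param("LD matrix dimension does not match p-vector")
    rep <- make_psd(R)
    L <- rep$chol
    ridge <- rep$ridge
  }

  gene_seed <- hash_seed(seed, stream_key)
  chunk <- 1e5
  withr::with_seed(gene_seed, {
    trace <- list()
    n_sims <- n_exceed <- 0
    for (k in seq_along(stages)) {
      m <- as.integer(stages[k])
      exceed <- 0L
      done <- 0L
      while (done < m) {
        b <- min(chunk, m - done)
        z <- matrix(rnorm(b * n), b, n) %*% L
        exceed <- exceed + sum(rowSums(z^2) >= observed)
        done <- done + b
      }
      n_sims <- m
      n_exceed <- exceed
      gene_p <- (n_exceed + 1) / (n_sims + 1)
      trace[[k]] <- c(n_sims = n_sims, p = gene_p)
      promote <- k < length(stages) && gene_p <= thresholds[k]
      if (!promote) break
    }
  })
  tibble(
    n_snps = n, observed_stat = observed, n_sims = n_sims,
    n_exceed = n_exceed, gene_p = gene_p, ridge = ridge,
    stage_trace = list(do.call(rbind, trace))
  )
}

#' Run the simulation-based gene test for every mapped gene
#'
#' @param mapped Long assignment tibble from [map_snps()].
#' @param panel Reference `genotype_panel` for per-gene LD; `NULL` treats
#'   SNPs as independent.
#' @param stages,thresholds,seed Passed to [vegas_test()]; each gene's
#'   stream is derived from `(seed, gene_id)`.
#' @return Tibble with one row per gene: `gene_id`, `n_snps`,
#'   `observed_stat`, `n_sims`, `gene_p`, `ridge`; classed `vegas_scan`.
#' @export
vegas_scan <- function(mapped, panel = NULL,
                       stages = c(1e3, 1e4, 1e6),
                       thresholds = c(0.1, 0.001),
                       seed = 1L) {
  out <- mapped |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(d, key) {
      ld <- if (!is.null(panel)) pairwise_r(panel, d$snp_id) else NULL
      res <- vegas_test(d$p, ld,
        stages = stages, thresholds = thresholds,
        seed = seed, stream_key = key$gene_id
      )
      res[, c("n_snps", "observed_stat", "n_sims", "n_exceed", "gene_p", "ridge")]
    }) |>
    dplyr::ungroup()
  class(out) <- c("vegas_scan", class(out))
  out
}
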