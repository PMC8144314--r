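#' Covariance of two correlated Fisher terms
#'
#' The Brown/Kost polynomial approximation to
#' `cov(-2 ln p_i, -2 ln p_j)` for two 1-df tests whose underlying
#' statistics have non-negative correlation `rho`:
#' `rho * (3.25 + 0.75 * rho)`. It is 0 at independence and exactly 4 --
#' the variance of a single `-2 ln p` term -- at perfect duplication.
#'
#' @param rho Non-negative correlation(s) in `[0, 1]`.
#' @return Covariance contribution(s) in `[0, 4]`.
#' @export
pair_covariance <- function(rho) {
  if (any(!is.finite(rho)) || any(rho < 0) || any(rho > 1)) {
    stop_param("`rho` must lie in [0, 1]")
  }
  rho * (3.25 + 0.75 * rho)
}

#' Null variance of the Fisher combination under LD
#'
#' For N SNPs the Fisher statistic `x0^2 = -2 sum(ln p_i)` has null mean
#' `2N`; under dependence its variance is inflated to
#' `sigma^2 = 4N + 2 * sum_{i<j} cov(-2 ln p_i, -2 ln p_j)`, with each
#' pairwise covariance given by [pair_covariance()] applied to the
#' non-negative SNP correlation.
#'
#' @param ld An `ld_matrix` (or bare correlation matrix) for the gene's SNPs.
#' @param rho_mode How to obtain the non-negative correlation from the signed
#'   dosage correlation: `"r2"` (default; the squared correlation, which is
#'   the correlation between two two-sided 1-df association statistics and
#'   empirically calibrates the null) or `"abs_r"` (the magnitude of the
#'   dosage correlation, the covariance model of the original one-sided
#'   derivation).
#' @return `sigma^2` (scalar). Equals `4N` when all off-diagonal
#'   correlations are 0 and `4N^2` when all are 1.
#' @export
null_variance <- function(ld, rho_mode = c("r2", "abs_r")) {
  rho_mode <- match.arg(rho_mode)
  R <- ld_view(ld, rho_mode)
  n <- nrow(R)
  if (n != ncol(R)) stop_param("correlation matrix must be square")
  off <- R[upper.tri(R)]
  4 * n + 2 * sum(pair_covariance(off))
}

#' Set-screen gene test (Brown-corrected Fisher combination)
#'
#' Combines the SNP p-values of one gene with Fisher's statistic
#' `x0^2 = -2 sum(ln p_i)` and corrects for LD by moment matching: the null
#' mean `2N` and LD-inflated variance `sigma^2` (see [null_variance()])
#' determine a scaled statistic `x^2 = x0^2 * 4N / sigma^2` referred to a
#' central chi-square with fractional degrees of freedom `8 N^2 / sigma^2`
#' (Satterthwaite scaling). With independent SNPs (`sigma^2 = 4N`) this
#' reduces exactly to Fisher's method with `2N` df; with `N = 1` the gene
#' p-value equals the input SNP p-value.
#'
#' @param p Vector of SNP p-values in `(0, 1]`, ordered as in `ld`.
#' @param ld An `ld_matrix` or correlation matrix for the same SNPs;
#'   `NULL` means independence.
#' @param rho_mode Passed to [null_variance()].
#' @return A one-row tibble: `n_snps`, `raw_stat`, `sigma2`, `scaled_stat`,
#'   `df`, `gene_p`.
#' @export
set_screen_test <- function(p, ld = NULL, rho_mode = c("r2", "abs_r")) {
  rho_mode <- match.arg(rho_mode)
  check_prob_open_closed(p, "p")
  n <- length(p)
  if (n < 1) stop_param("need at least one SNP p-value")
  if (is.null(ld)) {
    sigma2 <- 4 * n
  } else {
    R <- if (inherits(ld, "ld_matrix")) ld$r else ld
    if (nrow(R) != n) stop_param("LD matrix dimension does not match p-vector")
    sigma2 <- null_variance(ld, rho_mode)
  }
  raw <- -2 * sum(log(p))
  scaled <- raw * 4 * n / sigma2
  df <- 8 * n^2 / sigma2
  gene_p <- pchisq(scaled, df = df, lower.tail = FALSE)
  tibble(
    n_snps = n, raw_stat = raw, sigma2 = sigma2,
    scaled_stat = scaled, df = df, gene_p = max(gene_p, .Machine$double.xmin)
  )
}

#' Run the set-screen test for every mapped gene
#'
#' @param mapped Long assignment tibble from [map_snps()].
#' @param panel Reference `genotype_panel` used for per-gene LD; `NULL`
#'   treats SNPs as independent.
#' @param rho_mode Passed to [null_variance()].
#' @return Tibble with one row per gene: `gene_id`, `n_snps`, `kb` (span of
#'   assigned SNPs in kilobases), `raw_stat`, `sigma2`, `df`, `gene_p`;
#'   classed `setscreen_scan`.
#' @export
set_screen_scan <- function(mapped, panel = NULL, rho_mode = c("r2", "abs_r")) {
  rho_mode <- match.arg(rho_mode)
  out <- mapped |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(d, key) {
      ld <- if (!is.null(panel)) pairwise_r(panel, d$snp_id) else NULL
      res <- set_screen_test(d$p, ld, rho_mode)
      res$kb <- (max(d$pos) - min(d$pos)) / 1000
      res[, c("n_snps", "kb", "raw_stat", "sigma2", "df", "gene_p")]
    }) |>
    dplyr::ungroup()
  class(out) <- c("setscreen_scan", class(out))
  out
}
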