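#' Bonferroni family-wise threshold
#'
#' @param alpha Family-wise significance level in `(0, 1)`.
#' @param m Number of tests (here, shared genes), >= 1.
#' @return The exact threshold `alpha / m`, with a 3-significant-figure
#'   display form in attribute `display` (e.g. `"4.56e-06"`).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (alpha <= 0 || alpha >= 1) stop_param("`alpha` must lie in (0, 1)")
  m <- check_count(m, "m")
  thr <- alpha / m
  attr(thr, "display") <- formatC(signif(thr, 3), format = "e", digits = 2)
  thr
}

#' Intersect two gene-test scans and flag the Bonferroni-significant genes
#'
#' The gene universe is the intersection of the two scans' genes; the
#' threshold is `alpha` divided by the size of that shared universe; a gene
#' is significant iff BOTH methods' p-values are strictly below the
#' threshold. Output is sorted by the larger of the two p-values,
#' ascending, so the jointly strongest genes come first.
#'
#' @param results_a,results_b Per-gene result tibbles with `gene_id` and
#'   `gene_p` columns (e.g. from [set_screen_scan()] and [vegas_scan()]);
#'   `n_snps` and `kb` are carried through when present.
#' @param alpha Family-wise level, default 0.05.
#' @param m Size of the tested gene universe. Defaults to the number of
#'   shared genes in the inputs; supply it explicitly when the inputs are a
#'   pre-filtered subset of a larger screen, so the threshold still refers
#'   to the full number of tests.
#' @return A `gene_decisions` tibble: `gene_id`, `n_snps_a`, `kb`, `p_a`,
#'   `n_snps_b`, `p_b`, `m_shared`, `threshold`, `significant`.
#' @export
decide <- function(results_a, results_b, alpha = 0.05, m = NULL) {
  shared <- shared_genes(results_a, results_b)
  if (!length(shared)) {
    warn("no genes shared between the two result sets")
    out <- tibble(
      gene_id = character(), n_snps_a = integer(), kb = numeric(),
      p_a = numeric(), n_snps_b = integer(), p_b = numeric(),
      m_shared = integer(), threshold = numeric(), significant = logical()
    )
    class(out) <- c("gene_decisions", class(out))
    return(out)
  }
  m <- if (is.null(m)) length(shared) else check_count(m, "m")
  thr <- bonferroni_threshold(alpha, m)
  a <- results_a[match(shared, results_a$gene_id), , drop = FALSE]
  b <- results_b[match(shared, results_b$gene_id), , drop = FALSE]
  out <- tibble(
    gene_id = shared,
    n_snps_a = if ("n_snps" %in% names(a)) a$n_snps else NA_integer_,
    kb = if ("kb" %in% names(a)) a$kb else NA_real_,
    p_a = a$gene_p,
    n_snps_b = if ("n_snps" %in% names(b)) b$n_snps else NA_integer_,
    p_b = b$gene_p,
    m_shared = m,
    threshold = as.numeric(thr),
    significant = pmax(a$gene_p, b$gene_p) < as.numeric(thr)
  )
  out <- out[order(pmax(out$p_a, out$p_b), out$gene_id), , drop = FALSE]
  attr(out, "alpha") <- alpha
  attr(out, "threshold_display") <- attr(thr, "display")
  class(out) <- c("gene_decisions", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.gene_decisions <- function(x, ...) {
  as_tibble(unclass_keep(x))
}

#' @exportS3Method generics::glance
glance.gene_decisions <- function(x, ...) {
  tibble(
    m_shared = if (nrow(x)) x$m_shared[1] else 0L,
    alpha = attr(x, "alpha") %||% NA_real_,
    threshold = if (nrow(x)) x$threshold[1] else NA_real_,
    n_significant = sum(x$significant)
  )
}

unclass_keep <- function(x) {
  class(x) <- setdiff(class(x), c("gene_decisions", "setscreen_scan",
                                  "vegas_scan", "de_results"))
  x
}
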