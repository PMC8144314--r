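#' Per-probe two-group differential expression
#'
#' Case-vs-control statistics on a log2 expression matrix. The default
#' engine is a moderated t: per-probe pooled variances `s_g^2` (d = n1 + n2
#' - 2 df each) are shrunk towards a common prior by empirical Bayes,
#' `s_tilde^2 = (d0 * s0^2 + d * s_g^2) / (d0 + d)`, with the prior df `d0`
#' and prior variance `s0^2` estimated by method-of-moments on the log
#' sample variances (matching the moments of log chi-square); the moderated
#' t is referred to `d0 + d` df. As `d0 -> 0` this reduces to the ordinary
#' pooled-variance t, available directly via `engine = "ordinary"`. If the
#' moment fit fails (non-positive curvature, i.e. the log-variances are
#' less dispersed than a chi-square allows), the prior df is infinite and
#' all probes share `s0^2`; if it cannot be computed at all the engine
#' falls back to the ordinary t with a warning. Tests are two-sided.
#' All-constant probes are flagged and get NA statistics.
#'
#' @param eset An `expression_set` (see [simulate_expression()] /
#'   [read_expression()]), or a bare matrix plus `groups`.
#' @param groups Optional character vector of case/control labels aligned
#'   to matrix columns (ignored when `eset` is an `expression_set`).
#' @param engine `"moderated"` (default) or `"ordinary"`.
#' @param prior Optional list `list(d0 = , s0_sq = )` fixing the empirical
#'   Bayes prior instead of estimating it (useful for studying the
#'   `d0 -> 0` ordinary-t limit).
#' @return A `de_results` tibble: `probe_id`, `log_fc` (log2 case minus
#'   control), `t_stat`, `df`, `p`, `adj_p` (Benjamini-Hochberg across all
#'   testable probes), `constant`. Attributes `d0` and `s0_sq` report the
#'   fitted prior.
#' @export
moderated_t <- function(eset, groups = NULL, engine = c("moderated", "ordinary"),
                        prior = NULL) {
  engine <- match.arg(engine)
  if (inherits(eset, "expression_set")) {
    mat <- eset$matrix
    groups <- eset$groups$group[match(colnames(mat), eset$groups$sample_id)]
  } else {
    mat <- eset
  }
  if (is.null(groups) || !all(groups %in% c("case", "control"))) {
    stop_param("groups must label every column 'case' or 'control'")
  }
  n1 <- sum(groups == "case")
  n2 <- sum(groups == "control")
  if (n1 < 2 || n2 < 2) stop_param("need >= 2 samples per group")

  ca <- mat[, groups == "case", drop = FALSE]
  co <- mat[, groups == "control", drop = FALSE]
  log_fc <- unname(rowMeans(ca) - rowMeans(co))
  ss1 <- unname(rowSums((ca - rowMeans(ca))^2))
  ss2 <- unname(rowSums((co - rowMeans(co))^2))
  d <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / d
  constant <- s2 == 0 & log_fc == 0
  se_scale <- sqrt(1 / n1 + 1 / n2)

  d0 <- 0
  s0_sq <- NA_real_
  if (engine == "moderated" && !is.null(prior)) {
    d0 <- prior$d0
    s0_sq <- prior$s0_sq
  } else if (engine == "moderated") {
    ok <- s2 > 0
    if (sum(ok) < 3) {
      warn("too few variable probes for moderation; using ordinary t")
      engine <- "ordinary"
    } else {
      fit <- fit_f_prior(s2[ok], d)
      if (is.null(fit)) {
        warn("prior moment fit failed; using ordinary t")
        engine <- "ordinary"
      } else {
        d0 <- fit$d0
        s0_sq <- fit$s0_sq
      }
    }
  }
  if (engine == "moderated") {
    post_s2 <- if (is.finite(d0)) (d0 * s0_sq + d * s2) / (d0 + d) else s0_sq + 0 * s2
    df <- if (is.finite(d0)) d0 + d else Inf
  } else {
    post_s2 <- s2
    df <- d
  }
  t_stat <- log_fc / (sqrt(post_s2) * se_scale)
  p <- 2 * pt(abs(t_stat), df = df, lower.tail = FALSE)
  t_stat[constant] <- NA_real_
  p[constant] <- NA_real_
  adj <- rep(NA_real_, length(p))
  adj[!is.na(p)] <- bh_adjust(p[!is.na(p)])
  out <- tibble(
    probe_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    log_fc = log_fc, t_stat = t_stat, df = df, p = p, adj_p = adj,
    constant = constant
  )
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  attr(out, "engine") <- engine
  class(out) <- c("de_results", class(out))
  out
}

# method-of-moments fit of a scaled-F prior to pooled variances:
# e_g = log(s_g^2); under the hierarchical model
#   E[e] = log(s0^2) + digamma(d/2) - log(d/2) - (digamma(d0/2) - log(d0/2))
#   Var[e] = trigamma(d/2) + trigamma(d0/2)
# solve trigamma(d0/2) = var(e) - trigamma(d/2) by Newton on 1/trigamma.
fit_f_prior <- function(s2, d) {
  e <- log(s2)
  ve <- var(e)
  if (!is.finite(ve)) return(NULL)
  target <- ve - trigamma(d / 2)
  if (target <= 0) {
    # less dispersion than sampling alone: infinite prior df, common variance
    s0_sq <- exp(mean(e) - digamma(d / 2) + log(d / 2))
    return(list(d0 = Inf, s0_sq = s0_sq))
  }
  half_d0 <- trigamma_inverse(target)
  d0 <- 2 * half_d0
  s0_sq <- exp(mean(e) - digamma(d / 2) + log(d / 2) +
                 digamma(half_d0) - log(half_d0))
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton solve of trigamma(y) = x for y > 0
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-10) break
  }
  y
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: sort ascending, set
#' `adj_(i) = min_{j >= i} p_(j) * m / j` capped at 1, and restore the
#' input order.
#'
#' @param p P-values in `(0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  check_prob_open_closed(p, "p")
  p.adjust(p, method = "BH")
}

#' Collapse probe-level results to one probe per gene
#'
#' For each gene, keep the probe with the smallest raw p-value (ties broken
#' by lexicographically first probe id, so the result is deterministic).
#' Probes without a gene mapping are excluded and counted.
#'
#' @param results A `de_results` tibble (or any tibble with `probe_id` and
#'   `p`).
#' @param probe_map Tibble with `probe_id` and `gene_id`.
#' @return Tibble with one row per gene carrying the selected probe's
#'   columns plus `gene_id` and `selected = TRUE`; attribute
#'   `n_unmapped_probes` counts excluded probes.
#' @export
collapse_probes <- function(results, probe_map) {
  joined <- dplyr::inner_join(results, probe_map, by = "probe_id")
  n_unmapped <- nrow(results) - nrow(joined)
  out <- joined |>
    dplyr::filter(!is.na(.data$p)) |>
    dplyr::arrange(.data$gene_id, .data$p, .data$probe_id) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::mutate(selected = TRUE)
  attr(out, "n_unmapped_probes") <- n_unmapped
  out
}

#' Linear fold change from a log2 fold change
#'
#' @param log_fc Log2 fold change(s), case minus control.
#' @return Tibble with `log_fc`, `fold` (`2^|log_fc|` rounded to one
#'   decimal for display) and `direction` (`up`/`down`/`none`).
#' @export
fold_change <- function(log_fc) {
  if (any(!is.finite(log_fc))) stop_param("`log_fc` must be finite")
  tibble(
    log_fc = log_fc,
    fold = round(2^abs(log_fc), 1),
    direction = dplyr::case_when(
      log_fc > 0 ~ "up",
      log_fc < 0 ~ "down",
      TRUE ~ "none"
    )
  )
}

#' @exportS3Method generics::tidy
tidy.de_results <- function(x, ...) as_tibble(unclass_keep(x))

#' @exportS3Method generics::glance
glance.de_results <- function(x, ...) {
  tibble(
    n_probes = nrow(x),
    n_constant = sum(x$constant),
    d0 = attr(x, "d0") %||% NA_real_,
    s0_sq = attr(x, "s0_sq") %||% NA_real_,
    n_significant = sum(x$adj_p < 0.05, na.rm = TRUE)
  )
}
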