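# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# P(Z1 < a, Z2 < b) for standard bivariate normal with correlation rho,
# by one-dimensional quadrature over the conditional normal CDF
bvn_lower_orthant <- function(a, b, rho) {
  stats::integrate(
    function(z) stats::pnorm((b - rho * z) / sqrt(1 - rho^2)) * stats::dnorm(z),
    -Inf, a,
    rel.tol = 1e-10
  )$value
}

# expected dosage correlation of two threshold-model SNPs with equal
# allele frequency f and latent correlation rho (haplotype allele
# correlation; summing two independent haplotypes leaves it unchanged)
threshold_dosage_cor <- function(f, rho) {
  a <- stats::qnorm(f)
  p11 <- bvn_lower_orthant(a, a, rho)
  (p11 - f^2) / (f * (1 - f))
}

# brute-force Benjamini-Hochberg step-up: literal definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    j <- seq(i, m)
    adj[ord[i]] <- min(pmin(p[ord[j]] * m / j, 1))
  }
  adj
}

# Cochran-Armitage trend chi-square from a 2 x 3 table, textbook form
trend_oracle <- function(cases, controls, scores = c(0, 1, 2)) {
  n_k <- cases + controls
  N <- sum(n_k)
  R <- sum(cases)
  num <- N * sum(scores * cases) - R * sum(scores * n_k)
  den <- R * (N - R) * (N * sum(scores^2 * n_k) - sum(scores * n_k)^2)
  num^2 * N / den
}

# scalar Pearson correlation written out longhand
pearson_oracle <- function(x, y) {
  xc <- x - sum(x) / length(x)
  yc <- y - sum(y) / length(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# two-sample pooled-variance t statistic, written out longhand
pooled_t_oracle <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# upper-tail chi-square survival via the regularized incomplete gamma
chisq_sf_gamma <- function(x, df) {
  stats::pgamma(x / 2, shape = df / 2, lower.tail = FALSE)
}
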