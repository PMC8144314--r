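test_that("pair covariance polynomial hits its analytic endpoints", {
  expect_equal(pair_covariance(0), 0)
  expect_equal(pair_covariance(1), 4) # Var(-2 ln p) of a duplicated test
  expect_equal(pair_covariance(0.5), 1.8125)
  # monotone on a grid
  grid <- seq(0, 1, by = 0.05)
  expect_true(all(diff(pair_covariance(grid)) > 0))
  expect_error(pair_covariance(-0.1), class = "genewise_parameter_error")
  expect_error(pair_covariance(1.1), class = "genewise_parameter_error")
})

test_that("null variance reduces to 4N under independence and 4N^2 under duplication", {
  expect_equal(null_variance(diag(1, 3)), 12)
  expect_equal(null_variance(matrix(1, 2, 2)), 16)
  # matrix entries taken as the non-negative statistic correlation directly
  expect_equal(null_variance(matrix(c(1, 0.5, 0.5, 1), 2), "abs_r"), 8 + 2 * 1.8125)
  # abs_r vs r2 readings of a signed correlation
  r <- matrix(c(1, -0.6, -0.6, 1), 2)
  expect_equal(null_variance(r, "abs_r"), 8 + 2 * pair_covariance(0.6))
  expect_equal(null_variance(r, "r2"), 8 + 2 * pair_covariance(0.36))
})

test_that("a single-SNP gene returns the SNP p-value unchanged", {
  withr::with_seed(7, {
    for (p in c(0.05, runif(20))) {
      res <- set_screen_test(p)
      expect_equal(res$gene_p, p, tolerance = 1e-12)
      expect_equal(res$df, 2)
    }
  })
  res <- set_screen_test(0.05)
  expect_equal(res$raw_stat, -2 * log(0.05), tolerance = 1e-9)
})

test_that("diagonal LD reduces the set screen to Fisher's method (property)", {
  withr::with_seed(8, {
    worst <- 0
    for (i in 1:1000) {
      n <- sample(1:10, 1)
      p <- runif(n)
      got <- set_screen_test(p, diag(1, n))$gene_p
      fisher <- chisq_sf_gamma(-2 * sum(log(p)), 2 * n)
      worst <- max(worst, abs(got - fisher))
    }
    expect_lt(worst, 1e-10)
  })
})

test_that("correlated two-SNP case matches the hand-evaluated fractional-df chi-square", {
  ld <- matrix(c(1, 0.5, 0.5, 1), 2)
  res <- set_screen_test(c(0.01, 0.01), ld, rho_mode = "abs_r")
  x0 <- -4 * log(0.01)
  expect_equal(res$raw_stat, x0, tolerance = 1e-9)
  expect_equal(res$sigma2, 11.625)
  expect_equal(res$scaled_stat, x0 * 8 / 11.625, tolerance = 1e-12)
  expect_equal(res$df, 32 / 11.625, tolerance = 1e-12)
  expect_equal(res$gene_p, chisq_sf_gamma(x0 * 8 / 11.625, 32 / 11.625), tolerance = 1e-12)

  # independent pair: closed-form chi-square(4) survival e^{-x/2}(1 + x/2)
  res2 <- set_screen_test(c(0.01, 0.04), diag(1, 2))
  x <- -2 * sum(log(c(0.01, 0.04)))
  expect_equal(res2$gene_p, exp(-x / 2) * (1 + x / 2), tolerance = 1e-10)

  expect_error(set_screen_test(c(0.01, 0.02), diag(1, 3)), class = "genewise_parameter_error")
  expect_error(set_screen_test(c(0, 0.5)), class = "genewise_parameter_error")
})

test_that("scaled statistic moment-matches its chi-square null when the covariance model holds", {
  # one-sided correlated normal scores: the regime in which the Brown/Kost
  # covariance polynomial is (near-)exact, with rho the statistic correlation
  n <- 5
  R <- 0.7^abs(outer(1:n, 1:n, "-"))
  sigma2 <- null_variance(R, "abs_r")
  df <- 8 * n^2 / sigma2
  M <- 1e5
  withr::with_seed(10, {
    z <- matrix(rnorm(M * n), M, n) %*% chol(R)
    p <- pnorm(z, lower.tail = FALSE)
    x2 <- (-2 * rowSums(log(p))) * 4 * n / sigma2
  })
  expect_lt(abs(mean(x2) - df), 3 * sd(x2) / sqrt(M))
  v <- var(x2)
  se_var <- sqrt((mean((x2 - mean(x2))^4) - v^2) / M)
  expect_lt(abs(v - 2 * df), 3 * se_var)
})

test_that("for two-sided chi-square p-values the r2 reading outperforms abs_r", {
  # two-sided 1-df statistics correlate as the squared dosage correlation,
  # so feeding r^2 to the covariance polynomial tracks the true null
  # variance of the Fisher sum far better than |r| (the package default)
  n <- 5
  R <- 0.7^abs(outer(1:n, 1:n, "-"))
  M <- 1e5
  withr::with_seed(10, {
    z <- matrix(rnorm(M * n), M, n) %*% chol(R)
    p <- pchisq(z^2, df = 1, lower.tail = FALSE)
    x0 <- -2 * rowSums(log(p))
  })
  # the mean of the Fisher sum is 2N regardless of dependence
  expect_lt(abs(mean(x0) - 2 * n), 3 * sd(x0) / sqrt(M))
  v_true <- var(x0)
  expect_lt(
    abs(null_variance(R, "r2") - v_true),
    abs(null_variance(R, "abs_r") - v_true)
  )
  # r2 tracks the truth to within ~10 percent here; abs_r overshoots by ~35
  expect_lt(abs(null_variance(R, "r2") / v_true - 1), 0.1)
})

test_that("for a fixed p-vector the gene p grows with uniform LD (redundancy)", {
  p <- c(0.001, 0.02, 0.3, 0.6)
  ps <- vapply(c(0, 0.2, 0.4, 0.6, 0.8, 0.9), function(rho) {
    R <- matrix(rho, 4, 4)
    diag(R) <- 1
    set_screen_test(p, R)$gene_p
  }, numeric(1))
  expect_true(all(diff(ps) >= 0))
})

test_that("the per-gene scan reports SNP span in kb alongside the test", {
  bp <- block_panel(3, 4, rho = 0.5, n_samples = 150, seed = 17)
  snps <- dplyr::mutate(bp$panel$snps, p = withr::with_seed(18, runif(12)))
  mapped <- map_snps(bp$genes, snps[, c("snp_id", "chrom", "pos", "p")], "0kbloc")
  scan <- set_screen_scan(mapped, bp$panel)
  expect_equal(nrow(scan), 3)
  expect_equal(scan$n_snps, rep(4L, 3))
  expect_equal(scan$kb, rep(15, 3)) # 3 gaps x 5000 bp
  expect_true(all(scan$gene_p > 0 & scan$gene_p <= 1))
  expect_true(all(scan$sigma2 > 4 * scan$n_snps)) # LD inflates the null variance
})
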