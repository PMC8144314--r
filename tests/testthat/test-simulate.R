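test_that("genotype simulator is deterministic and respects its parameters", {
  spec <- ld_block_spec(10, 2, within_block_rho = 0.5, maf_range = c(0.2, 0.4))
  a <- simulate_genotypes(spec, 100, 11)
  b <- simulate_genotypes(spec, 100, 11)
  expect_identical(a$dosage, b$dosage)
  expect_identical(a$snps, b$snps)
  expect_equal(dim(a$dosage), c(100, 20))
  expect_true(all(a$dosage %in% 0:2))
  expect_true(all(a$snps$maf >= 0.2 & a$snps$maf <= 0.4))
  # different seed, different draw
  expect_false(identical(a$dosage, simulate_genotypes(spec, 100, 12)$dosage))

  big <- simulate_genotypes(ld_block_spec(40, 1, maf_range = c(0.3, 0.3)), 4000, 5)
  emp_f <- colMeans(big$dosage) / 2
  expect_true(all(abs(emp_f - 0.3) < 0.03))

  expect_error(ld_block_spec(0, 1), class = "genewise_parameter_error")
  expect_error(ld_block_spec(5, 1, within_block_rho = 1), class = "genewise_parameter_error")
  expect_error(ld_block_spec(5, 1, maf_range = c(0, 0.5)), class = "genewise_parameter_error")
  expect_error(simulate_genotypes(spec, 1, 1), class = "genewise_parameter_error")
})

test_that("rho = 0 blocks are uncorrelated; AR(1) LD matches the threshold oracle", {
  indep <- simulate_genotypes(ld_block_spec(10, 1, within_block_rho = 0), 5000, 21)
  cc <- cor(indep$dosage)
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.05)

  f <- 0.3
  ld <- simulate_genotypes(
    ld_block_spec(10, 1, within_block_rho = 0.9, maf_range = c(f, f)), 5000, 22
  )
  emp_adj <- mean(vapply(
    1:9, function(j) cor(ld$dosage[, j], ld$dosage[, j + 1]), numeric(1)
  ))
  expect_lt(abs(emp_adj - threshold_dosage_cor(f, 0.9)), 0.1)
  # two steps apart: latent rho^2, still monotone decay
  emp_2 <- mean(vapply(
    1:8, function(j) cor(ld$dosage[, j], ld$dosage[, j + 2]), numeric(1)
  ))
  expect_lt(abs(emp_2 - threshold_dosage_cor(f, 0.81)), 0.1)
  expect_lt(emp_2, emp_adj)
})

test_that("retrospective phenotype sampling fills quotas exactly and validates input", {
  panel <- simulate_genotypes(ld_block_spec(5, 1), 100, 3)
  ph <- simulate_phenotypes(panel, pheno_model(50, 50), 4)
  expect_equal(sum(ph$status == 1), 50)
  expect_equal(sum(ph$status == 0), 50)
  expect_equal(sort(ph$sample_index), 1:100)
  expect_identical(ph, simulate_phenotypes(panel, pheno_model(50, 50), 4))

  expect_error(simulate_phenotypes(panel, pheno_model(80, 80), 1),
    class = "genewise_simulation_error"
  )
  expect_error(pheno_model(10, 10, baseline_prevalence = 0),
    class = "genewise_parameter_error"
  )
  expect_error(pheno_model(10, 10, baseline_prevalence = 1),
    class = "genewise_parameter_error"
  )
  expect_error(
    simulate_phenotypes(panel, pheno_model(10, 10, causal_snps = c(nope = 0.5)), 1),
    class = "genewise_parameter_error"
  )
})

test_that("null phenotypes yield uniform trend-test p-values", {
  panel <- simulate_genotypes(ld_block_spec(50, 40, within_block_rho = 0), 1000, 31)
  ph <- simulate_phenotypes(panel, pheno_model(400, 400), 32)
  tt <- trend_test(panel, ph)
  expect_equal(nrow(tt), 2000)
  ks <- suppressWarnings(stats::ks.test(tt$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("an injected causal SNP is detected with high power", {
  spec <- ld_block_spec(2, 1, within_block_rho = 0.3, maf_range = c(0.3, 0.3))
  model <- pheno_model(2000, 2000,
    causal_snps = c(snp000001 = 0.5),
    baseline_prevalence = 0.35
  )
  hits <- vapply(1:100, function(rep) {
    panel <- simulate_genotypes(spec, 8000, 1000 + rep)
    ph <- simulate_phenotypes(panel, model, 2000 + rep)
    trend_test(panel, ph)$p[1] < 1e-3
  }, logical(1))
  expect_gte(sum(hits), 90)
})

test_that("trend test matches the count-table oracle and prop.trend.test", {
  # symmetric table: cases (10,20,10), controls (10,20,10) -> no trend
  g <- rep(c(0, 1, 2, 0, 1, 2), c(10, 20, 10, 10, 20, 10))
  y <- rep(c(1, 0), c(40, 40))
  sym <- trend_test(matrix(g, ncol = 1), y)
  expect_equal(sym$stat, 0)
  expect_equal(sym$p, 1)

  # random tables against the textbook formula and stats::prop.trend.test
  withr::with_seed(9, {
    for (i in 1:20) {
      cases <- rmultinom(1, 80, c(0.4, 0.4, 0.2))[, 1]
      controls <- rmultinom(1, 120, c(0.5, 0.35, 0.15))[, 1]
      g <- c(rep(0:2, cases), rep(0:2, controls))
      y <- rep(c(1, 0), c(sum(cases), sum(controls)))
      got <- trend_test(matrix(g, ncol = 1), y)$stat
      expect_equal(got, trend_oracle(cases, controls), tolerance = 1e-10)
      ptt <- stats::prop.trend.test(cases, cases + controls, score = 0:2)
      expect_equal(got, unname(ptt$statistic), tolerance = 1e-10)
    }
  })

  # monomorphic SNP: flagged, p = 1
  mono <- trend_test(matrix(rep(1, 20), ncol = 1), rep(c(0, 1), 10))
  expect_true(mono$monomorphic)
  expect_equal(mono$p, 1)

  expect_error(trend_test(matrix(g, ncol = 1), rep(1, length(g))),
    class = "genewise_parameter_error"
  )
})

test_that("expression simulator recovers injected fold changes and is calibrated", {
  spec <- expr_spec(20, 3, 15, 15,
    de_genes = c(G0001 = -1.21), noise_sd = 0.2
  )
  e <- simulate_expression(spec, 41)
  expect_identical(e$matrix, simulate_expression(spec, 41)$matrix)
  expect_equal(dim(e$matrix), c(60, 30))

  is_case <- e$groups$group == "case"
  est <- rowMeans(e$matrix[, is_case]) - rowMeans(e$matrix[, !is_case])
  g1 <- e$probe_map$gene_id == "G0001"
  expect_lt(abs(mean(est[g1]) - (-1.21)), 0.15)
  expect_lt(max(abs(est[!g1])), 0.5) # null genes near zero

  # null calibration: ordinary t rejects ~5% of 2000 null probes
  null_e <- simulate_expression(expr_spec(2000, 1, 10, 10, noise_sd = 0.3), 42)
  de <- moderated_t(null_e, engine = "ordinary")
  expect_lt(abs(mean(de$p < 0.05) - 0.05), 0.02)

  expect_error(expr_spec(10, 1, 5, 5, noise_sd = 0), class = "genewise_parameter_error")
  expect_error(
    simulate_expression(expr_spec(2, 1, 3, 3, de_genes = c(NOPE = 1)), 1),
    class = "genewise_parameter_error"
  )
})
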