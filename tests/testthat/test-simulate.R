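# Synthetic-data generator: catalog, truth and count sampling.

test_that("configuration is validated", {
  expect_error(simulation_config(length_bin_weights = c(0.5, 0.5, 0, 0, 0.5)),
               "sum to 1")
  expect_error(simulation_config(length_bin_weights = c(1, 0, 0, 0)), "length 5")
  expect_error(simulation_config(paternal_bias = 1.5), "paternal_bias")
  expect_error(simulation_config(frac_nonadditive = -0.1), "\\[0, 1\\]")
  expect_error(simulation_config(library_sizes = c(0, 1, 1)), "library_sizes")
  expect_error(simulation_config(dispersion = -1), "dispersion")
})

test_that("catalog lengths follow the bin weights and are reproducible", {
  # degenerate weights: everything lands in the first bin
  cfg1 <- simulation_config(n_genes = 100, length_bin_weights = c(1, 0, 0, 0, 0))
  cat1 <- generate_catalog(cfg1)
  expect_true(all(cat1$length_bp >= 100 & cat1$length_bp < 500))
  expect_false(anyDuplicated(cat1$gene_id) > 0)

  # full-size catalog reproduces the target bin shares within 1 percent
  cfg2 <- simulation_config(n_genes = 32642, seed = 5)
  cat2 <- generate_catalog(cfg2)
  shares <- length_bin_summary(cat2)$percentage / 100
  expect_lt(max(abs(shares - cfg2$length_bin_weights)), 0.01)

  expect_identical(generate_catalog(cfg2), generate_catalog(cfg2))
})

test_that("truth respects additivity, specificity and bias settings", {
  cfg <- small_config(frac_nonadditive = 0, frac_specific = 0)
  tr <- generate_truth(generate_catalog(cfg), cfg)
  expect_true(all(tr$mu_C == (tr$mu_A + tr$mu_B) / 2))
  expect_false(any(tr$nonadditive))
  # no library-specific silence: every gene expressed in all or none
  n_zero <- (tr$mu_A == 0) + (tr$mu_B == 0) + (tr$mu_C == 0)
  expect_true(all(n_zero %in% c(0L, 3L)))

  # zero bias: deviation directions balance within binomial error
  cfg2 <- simulation_config(n_genes = 4000, paternal_bias = 0,
                            frac_nonadditive = 0.5, frac_de_parents = 1,
                            seed = 21)
  tr2 <- generate_truth(generate_catalog(cfg2), cfg2)
  # positive true d <=> hybrid deviated away from the paternal parent
  sig <- tr2$nonadditive & tr2$mu_A != tr2$mu_B
  away_A <- sign(tr2$na_log2_dev[sig]) == sign(tr2$mu_B[sig] - tr2$mu_A[sig])
  expect_gt(stats::binom.test(sum(away_A), length(away_A))$p.value, 1e-4)

  expect_identical(generate_truth(generate_catalog(cfg), cfg),
                   generate_truth(generate_catalog(cfg), cfg))
})

test_that("truth pattern groups match the signs of the true effects", {
  cfg <- small_config(frac_nonadditive = 0.3, frac_de_parents = 0.5)
  tr <- generate_truth(generate_catalog(cfg), cfg)
  has_grp <- tr$pattern_group != "none"
  expect_true(all(has_grp == (tr$de_vs_A | tr$de_vs_B)))
  g <- tr$pattern_group[has_grp]
  up_A <- tr$eff_vs_A[has_grp] > 0
  up_B <- tr$eff_vs_B[has_grp] > 0
  expect_true(all(g[!up_A & !up_B] == "1"))
  expect_true(all(g[!up_A & up_B] == "2"))
  expect_true(all(g[up_A & !up_B] == "3"))
  expect_true(all(g[up_A & up_B] == "4"))
})

test_that("count sampling has the stated moments and determinism", {
  cfg <- small_config()
  cat <- generate_catalog(cfg)
  tr <- generate_truth(cat, cfg)

  # true zero rate -> zero counts, always
  tr0 <- tr
  tr0[, c("mu_A", "mu_B", "mu_C")] <- 0
  cnt0 <- sample_counts(tr0, cat, cfg)
  expect_true(all(cnt0$count_A == 0 & cnt0$count_B == 0 & cnt0$count_C == 0))

  # Poisson limit: 10,000 draws at mean 100 land within 3 standard errors
  cfgp <- simulation_config(n_genes = 10000, dispersion = 0, frac_specific = 0,
                            frac_de_parents = 0, frac_nonadditive = 0,
                            library_sizes = c(A = 1e6, B = 1e6, C = 1e6),
                            seed = 31)
  catp <- data.frame(gene_id = sprintf("g%05d", 1:10000), length_bp = 1000L)
  trp <- data.frame(gene_id = catp$gene_id, mu_A = 100, mu_B = 100, mu_C = 100)
  cntp <- sample_counts(trp, catp, cfgp)
  se <- sqrt(100 / 10000)
  expect_lt(abs(mean(cntp$count_A) - 100), 3 * se)

  cnt1 <- sample_counts(tr, cat, cfg)
  expect_identical(cnt1, sample_counts(tr, cat, cfg))
  expect_equal(attr(cnt1, "library_sizes"),
               c(A = sum(cnt1$count_A), B = sum(cnt1$count_B), C = sum(cnt1$count_C)))
})

test_that("simulate_dataset writes a readable TSV bundle", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(small_config(), dir = dir)
  expect_true(all(file.exists(file.path(dir, c("counts.tsv", "truth.tsv", "config.yaml")))))
  back <- read_counts(file.path(dir, "counts.tsv"))
  expect_equal(back$gene_id, sim$counts$gene_id)
  expect_equal(back$count_C, sim$counts$count_C)
})
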