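# RPKM, expressed calling, Venn partitioning, length and coverage bins.

test_that("RPKM follows the count/length/depth formula", {
  cnt <- make_counts(c(10L, 0L, 5L), c(0L, 0L, 0L), c(0L, 0L, 0L),
                     length_bp = c(1000L, 1000L, 500L),
                     totals = c(1e6, 1e6, 1e6))
  # per-gene totals differ for the third example
  attr(cnt, "library_sizes") <- c(A = 1e6, B = 1e6, C = 1e6)
  rp <- compute_rpkm(cnt, catalog_of(cnt))
  expect_equal(rp$rpkm_A[1], 10)
  expect_equal(rp$rpkm_A[2], 0)
  attr(cnt, "library_sizes") <- c(A = 1e7, B = 1e6, C = 1e6)
  expect_equal(compute_rpkm(cnt, catalog_of(cnt))$rpkm_A[3], 1)
})

test_that("RPKM is invariant under joint scaling of counts and totals", {
  cnt <- make_counts(c(3L, 40L, 7L), c(1L, 2L, 3L), c(9L, 0L, 2L),
                     totals = c(1e5, 2e5, 3e5))
  rp1 <- compute_rpkm(cnt, catalog_of(cnt))
  cnt2 <- cnt
  for (l in c("A", "B", "C")) cnt2[[paste0("count_", l)]] <- cnt[[paste0("count_", l)]] * 10L
  attr(cnt2, "library_sizes") <- attr(cnt, "library_sizes") * 10
  rp2 <- compute_rpkm(cnt2, catalog_of(cnt2))
  expect_equal(rp1$rpkm_A, rp2$rpkm_A)
  expect_equal(rp1$rpkm_C, rp2$rpkm_C)
})

test_that("genes missing from the catalog are reported by id", {
  cnt <- make_counts(1L, 1L, 1L)
  bad_cat <- data.frame(gene_id = "other", length_bp = 500L)
  expect_error(compute_rpkm(cnt, bad_cat), "g001")
})

test_that("expressed calls threshold on min_count", {
  cnt <- make_counts(c(1L, 0L, 30L), c(0L, 0L, 29L), c(5L, 0L, 30L))
  fl1 <- call_expressed(cnt, 1)
  expect_equal(fl1$expr_A, c(TRUE, FALSE, TRUE))
  fl30 <- call_expressed(cnt, 30)
  expect_equal(fl30$expr_A, c(FALSE, FALSE, TRUE))
  expect_equal(fl30$expr_B, c(FALSE, FALSE, FALSE))
  expect_error(call_expressed(cnt, 0), "min_count")
})

test_that("venn partition regions and totals are conserved", {
  # all genes expressed everywhere
  cnt <- make_counts(rep(1L, 4), rep(2L, 4), rep(3L, 4))
  v <- venn_partition(call_expressed(cnt))
  expect_equal(unname(v$regions["ABC"]), 4)
  expect_equal(sum(v$regions), v$regions[["ABC"]])

  # empty input
  v0 <- venn_partition(data.frame(expr_A = logical(0), expr_B = logical(0),
                                  expr_C = logical(0)))
  expect_true(all(unlist(v0$regions) == 0) && v0$grand == 0)

  # property: totals derived by summation for random flag matrices
  for (s in 1:20) {
    set.seed(s)
    fl <- data.frame(expr_A = sample(c(TRUE, FALSE), 50, TRUE),
                     expr_B = sample(c(TRUE, FALSE), 50, TRUE),
                     expr_C = sample(c(TRUE, FALSE), 50, TRUE))
    v <- venn_partition(fl)
    expect_equal(unname(v$totals), c(sum(fl$expr_A), sum(fl$expr_B), sum(fl$expr_C)))
    expect_equal(v$grand, sum(fl$expr_A | fl$expr_B | fl$expr_C))
    expect_equal(sum(v$regions), v$grand)
  }
})

test_that("length bins use left-closed right-open boundaries", {
  expect_equal(length_bin_summary(data.frame(gene_id = "g", length_bp = 120L))$percentage,
               c(100, 0, 0, 0, 0))
  b <- length_bin_summary(data.frame(gene_id = c("a", "b"), length_bp = c(500L, 499L)))
  expect_equal(b$count, c(1L, 1L, 0L, 0L, 0L))
  expect_error(length_bin_summary(data.frame(gene_id = character(0),
                                             length_bp = integer(0))), "empty")
})

test_that("coverage deciles exclude unmatched genes and close on the right", {
  fr <- data.frame(gene_id = sprintf("g%d", 1:5),
                   A = c(1, 1, 1, 1, 1), B = c(0.95, 0.05, 0, 0.5, 0.1))
  cb <- coverage_bins(fr)
  expect_equal(cb$A, c(rep(0L, 9), 5L))
  expect_equal(sum(cb$B), 4L)           # the zero-coverage gene is dropped
  expect_equal(cb$B[10], 1L)            # 0.95 -> (90%,100%]
  expect_equal(cb$B[1], 2L)             # 0.05 and 0.1 -> (0%,10%]
  expect_equal(cb$B[5], 1L)             # 0.5 -> (40%,50%]
  expect_error(coverage_bins(data.frame(A = c(0.5, 1.2))), "outside")

  # a library where 38% of matched genes sit in the top decile
  set.seed(4)
  f <- c(runif(380, 0.901, 1), runif(620, 0.001, 0.9))
  top_share <- coverage_bins(data.frame(A = f))$A[10] / 1000
  expect_equal(top_share, 0.38)
})
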