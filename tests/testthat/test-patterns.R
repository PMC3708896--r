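# Log-ratio profiles, sign-rule groups, hierarchical clustering.

test_that("log ratios are finite and floored at epsilon", {
  ex <- data.frame(gene_id = c("a", "b", "c"),
                   rpkm_A = c(2, 1, 0), rpkm_B = c(2, 2, 1), rpkm_C = c(2, 4, 8))
  attr(ex, "library_sizes") <- c(A = 1, B = 1, C = 1)
  pr <- log_ratio_profiles(ex, epsilon = 0.001)
  expect_equal(pr$log2_CA[1], 0)
  expect_equal(pr$log2_CB[1], 0)
  expect_equal(pr$log2_CA[2], 2)           # C = 4A
  expect_equal(pr$log2_CB[2], 1)           # C = 2B
  expect_true(is.finite(pr$log2_CA[3]) && pr$log2_CA[3] > 10)  # A floored
})

make_deg_stub <- function(ids, sig) {
  structure(data.frame(gene_id = ids, is_deg = sig, stringsAsFactors = FALSE),
            class = c("deg_table", "data.frame"))
}

test_that("sign rule assigns clusters for both-significant and groups for either", {
  ids <- c("up_up", "down_up", "mixed")
  profiles <- data.frame(gene_id = ids,
                         log2_CA = c(2, -2, 1), log2_CB = c(1, 1, -0.5))
  deg_CA <- make_deg_stub(ids, c(TRUE, TRUE, TRUE))
  deg_CB <- make_deg_stub(ids, c(TRUE, FALSE, FALSE))
  pats <- assign_patterns(deg_CA, deg_CB, profiles)

  expect_equal(pats$cluster[pats$gene_id == "up_up"], "4")
  expect_equal(pats$group[pats$gene_id == "up_up"], "4")
  expect_equal(pats$cluster[pats$gene_id == "down_up"], "none")
  expect_equal(pats$group[pats$gene_id == "down_up"], "2")
  expect_equal(pats$group[pats$gene_id == "mixed"], "3")
  expect_equal(pats$basis, c("both-significant", "either-significant",
                             "either-significant"))
})

test_that("groups partition the DEG union and ties count as down", {
  set.seed(33)
  n <- 80
  ids <- sprintf("g%02d", 1:n)
  profiles <- data.frame(gene_id = ids,
                         log2_CA = round(rnorm(n), 1), log2_CB = round(rnorm(n), 1))
  deg_CA <- make_deg_stub(ids, runif(n) < 0.4)
  deg_CB <- make_deg_stub(ids, runif(n) < 0.4)
  pats <- assign_patterns(deg_CA, deg_CB, profiles)
  in_union <- pats$sig_CA | pats$sig_CB
  expect_equal(sum(pats$group != "none"), sum(in_union))
  expect_true(all(pats$group[!in_union] == "none"))
  # exact zero ratios are "down"
  zero <- pats$log2_CA == 0 & in_union
  expect_true(all(pats$group[zero] %in% c("1", "2")))
  # clusters agree with groups wherever both are assigned
  both <- pats$cluster != "none"
  expect_true(all(pats$cluster[both] == pats$group[both]))
})

test_that("hierarchical clustering separates clean sign quadrants", {
  set.seed(34)
  # correlation distance on length-2 profiles reduces to the sign of the
  # within-profile slope, so the fixture keeps slopes consistent per quadrant
  q1 <- cbind(runif(15, 0.5, 1), runif(15, 1.5, 2))       # up/up, rising
  q2 <- cbind(runif(15, -1, -0.5), runif(15, -2, -1.5))   # down/down, falling
  profiles <- data.frame(gene_id = sprintf("g%02d", 1:30),
                         log2_CA = c(q1[, 1], q2[, 1]),
                         log2_CB = c(q1[, 2], q2[, 2]))
  cl <- cluster_profiles(profiles, k = 2)
  lab <- cl$labels
  expect_equal(length(unique(lab[1:15])), 1)
  expect_equal(length(unique(lab[16:30])), 1)
  expect_false(lab[1] == lab[16])
})

test_that("duplicate profiles share a label and k = n gives singletons", {
  profiles <- data.frame(gene_id = c("a", "b", "c", "d"),
                         log2_CA = c(1, 1, -1, 2), log2_CB = c(2, 2, -3, -1))
  cl <- cluster_profiles(profiles, k = 2)
  expect_equal(cl$labels[["a"]], cl$labels[["b"]])
  cl_n <- cluster_profiles(profiles, k = 4)
  expect_equal(sort(unname(cl_n$labels)), 1:4)
  expect_error(cluster_profiles(profiles, k = 5), "at least k")
})

test_that("constant profiles fall back to Euclidean distance with a note", {
  profiles <- data.frame(gene_id = c("a", "b", "c"),
                         log2_CA = c(1, 1, -2), log2_CB = c(2, 1, -2))
  expect_message(cl <- cluster_profiles(profiles, k = 2), "Euclidean")
  expect_equal(length(cl$labels), 3)
})

test_that("cluster labels are permutation-invariant up to relabeling", {
  set.seed(35)
  n <- 24
  profiles <- data.frame(gene_id = sprintf("g%02d", 1:n),
                         log2_CA = rnorm(n), log2_CB = rnorm(n))
  cl1 <- cluster_profiles(profiles, k = 3)
  perm <- sample(n)
  cl2 <- cluster_profiles(profiles[perm, ], k = 3)
  # same partition: co-membership matrices agree after reordering
  co1 <- outer(cl1$labels, cl1$labels, "==")
  l2 <- cl2$labels[match(profiles$gene_id, names(cl2$labels))]
  co2 <- outer(l2, l2, "==")
  expect_true(all(co1 == co2))
})
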