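# Log-ratio profiles and four-way expression-pattern assignment.

#' Per-gene log2 expression ratios of the hybrid over each parent
#'
#' `log2(C/A)` and `log2(C/B)` on RPKM, with zeros floored at `epsilon` so
#' every ratio is finite and signed.
#'
#' @param expression RPKM table from [compute_rpkm()].
#' @param epsilon RPKM floor for zero values.
#' @return data.frame `gene_id`, `log2_CA`, `log2_CB`.
#' @export
log_ratio_profiles <- function(expression, epsilon = 0.001) {
  if (epsilon <= 0) fail("log_ratio_profiles", "'epsilon' must be positive")
  a <- pmax(expression$rpkm_A, epsilon)
  b <- pmax(expression$rpkm_B, epsilon)
  c <- pmax(expression$rpkm_C, epsilon)
  data.frame(
    gene_id = expression$gene_id,
    log2_CA = log2(c / a),
    log2_CB = log2(c / b),
    stringsAsFactors = FALSE
  )
}

#' Assign four-way expression-pattern groups
#'
#' Combines the two hybrid-versus-parent DEG calls with the log-ratio signs
#' into the four canonical patterns: group 1 = down versus both parents,
#' group 2 = down versus the paternal parent (A) but up versus the maternal
#' (B), group 3 = the converse, group 4 = up versus both. A ratio sign is
#' "up" when the log ratio is strictly positive (exact ties count as down, so
#' the groups partition deterministically). A gene receives a `group` when it
#' is a DEG in at least one comparison and additionally a `cluster` (equal to
#' its group) when it is a DEG in both; otherwise `"none"`.
#'
#' @param deg_CA,deg_CB `"deg_table"`s for C-vs-A and C-vs-B.
#' @param profiles log-ratio table from [log_ratio_profiles()].
#' @return data.frame `gene_id`, `log2_CA`, `log2_CB`, `sig_CA`, `sig_CB`,
#'   `group`, `cluster`, `basis` (`"both-significant"`,
#'   `"either-significant"` or `"none"`), covering the union of the two
#'   tested universes.
#' @export
assign_patterns <- function(deg_CA, deg_CB, profiles) {
  ids <- union(deg_CA$gene_id, deg_CB$gene_id)
  sig_CA <- deg_CA$is_deg[match(ids, deg_CA$gene_id)]
  sig_CB <- deg_CB$is_deg[match(ids, deg_CB$gene_id)]
  sig_CA[is.na(sig_CA)] <- FALSE
  sig_CB[is.na(sig_CB)] <- FALSE
  pr <- profiles[match(ids, profiles$gene_id), , drop = FALSE]
  up_A <- pr$log2_CA > 0
  up_B <- pr$log2_CB > 0

  grp_code <- ifelse(!up_A & !up_B, "1",
                     ifelse(!up_A & up_B, "2", ifelse(up_A & !up_B, "3", "4")))
  either <- sig_CA | sig_CB
  both <- sig_CA & sig_CB
  data.frame(
    gene_id = ids,
    log2_CA = pr$log2_CA, log2_CB = pr$log2_CB,
    sig_CA = sig_CA, sig_CB = sig_CB,
    group = ifelse(either, grp_code, "none"),
    cluster = ifelse(both, grp_code, "none"),
    basis = ifelse(both, "both-significant",
                   ifelse(either, "either-significant", "none")),
    stringsAsFactors = FALSE
  )
}

#' Hierarchical clustering of log-ratio profiles
#'
#' Agglomerative average-linkage clustering with distance
#' `1 - Pearson correlation` between gene profile vectors, cut at `k`
#' clusters. With length-2 profiles the correlation is degenerate (every
#' defined value is +1 or -1), so this clustering is provided for concordance
#' with the sign-rule assignment rather than as the primary grouping.
#' Zero-variance (constant) profiles have no defined correlation; distances
#' involving them fall back to Euclidean distance rescaled to `[0, 2]`, and a
#' message notes how many genes were affected.
#'
#' @param profiles data.frame from [log_ratio_profiles()] (usually restricted
#'   to the both-significant DEGs).
#' @param k number of clusters (`1 <= k <=` number of genes).
#' @return list with `tree` (an `hclust`) and `labels` (named integer cluster
#'   assignment from `cutree`).
#' @export
cluster_profiles <- function(profiles, k = 4L) {
  X <- as.matrix(profiles[, c("log2_CA", "log2_CB")])
  rownames(X) <- profiles$gene_id
  n <- nrow(X)
  if (n < k) fail("cluster_profiles", "need at least k genes")
  D <- 1 - suppressWarnings(stats::cor(t(X)))
  if (anyNA(D)) {
    const <- apply(X, 1, stats::sd) == 0
    message(sprintf("cluster_profiles: %d constant profile(s); Euclidean fallback",
                    sum(const)))
    E <- as.matrix(stats::dist(X))
    if (max(E) > 0) E <- 2 * E / max(E)
    D[is.na(D)] <- E[is.na(D)]
  }
  diag(D) <- 0
  tree <- stats::hclust(stats::as.dist(D), method = "average")
  labels <- stats::cutree(tree, k = k)
  list(tree = tree, labels = labels)
}
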