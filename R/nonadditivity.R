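# Midparent value and additive/nonadditive classification of hybrid genes.

#' Construct the midparent pseudo-library
#'
#' The midparent value (MPV) of a gene is the average of its two parental
#' RPKM values — the additive expectation for the hybrid. Because the exact
#' test operates on counts, the MPV is back-projected onto a pseudo-library:
#' total `round((N_A + N_B)/2)` reads and per-gene pseudo-count
#' `round(MPV_RPKM * length_kb * total / 1e6)` (both rounded half-up), so the
#' count/total pair reproduces the MPV RPKM up to rounding. The construction
#' is symmetric in the parents.
#'
#' @param counts count matrix.
#' @param catalog gene catalog (`gene_id`, `length_bp`).
#' @return data.frame `gene_id`, `mpv_rpkm`, `pseudo_count`, with the
#'   pseudo-library total in attribute `pseudo_total`.
#' @export
midparent <- function(counts, catalog) {
  rpkm <- compute_rpkm(counts, catalog)
  totals <- library_sizes(counts)
  mpv <- (rpkm$rpkm_A + rpkm$rpkm_B) / 2
  pseudo_total <- round_half_up((totals[["A"]] + totals[["B"]]) / 2)
  len_kb <- catalog$length_bp[match(counts$gene_id, catalog$gene_id)] / 1000
  out <- data.frame(
    gene_id = counts$gene_id,
    mpv_rpkm = mpv,
    pseudo_count = round_half_up(mpv * len_kb * pseudo_total / 1e6),
    stringsAsFactors = FALSE
  )
  attr(out, "pseudo_total") <- pseudo_total
  out
}

#' Classify hybrid genes as additive or nonadditive
#'
#' Tests each gene's hybrid count against its midparent pseudo-count with the
#' Audic-Claverie exact test (the pseudo-library is treated as an ordinary
#' library), adjusts by Benjamini-Hochberg over the tested universe (genes
#' expressed in the hybrid or with pseudo-count >= 1), and labels genes with
#' at least `fc_min`-fold change versus MPV and FDR at most `fdr_max` as
#' nonadditive; all other tested genes are additive.
#'
#' @param counts count matrix.
#' @param catalog gene catalog.
#' @param mpv optional precomputed [midparent()] table.
#' @param min_count hybrid detection threshold for the universe.
#' @param fc_min,fdr_max,epsilon thresholds as in [call_degs()].
#' @param n_detected number of detected genes used as the denominator of the
#'   reported percentage; defaults to the number of genes expressed in at
#'   least one of the three libraries.
#' @return data.frame of class `"additivity_table"`: `gene_id`, `mpv_rpkm`,
#'   `pseudo_count`, `hybrid_count`, `hybrid_rpkm`, `fold_change`, `log2fc`
#'   (hybrid over MPV), `p_value`, `fdr`, `label`
#'   (`"additive"`/`"nonadditive"`), `deviation_direction`
#'   (`"above"`/`"below"`/`"none"`). Attributes carry `n_nonadditive`,
#'   `n_detected` and `percent_nonadditive` (percent of detected genes,
#'   rounded half-up to 3 decimals).
#' @export
classify_additivity <- function(counts, catalog, mpv = NULL, min_count = 1L,
                                fc_min = 2, fdr_max = 0.001, epsilon = 0.001,
                                n_detected = NULL) {
  check_counts_df(counts, "classify_additivity")
  if (is.null(mpv)) mpv <- midparent(counts, catalog)
  totals <- library_sizes(counts)
  pseudo_total <- attr(mpv, "pseudo_total")
  rpkm <- compute_rpkm(counts, catalog)

  if (is.null(n_detected)) {
    expr <- call_expressed(counts, min_count)
    n_detected <- sum(expr$expr_A | expr$expr_B | expr$expr_C)
  }

  universe <- counts$count_C >= min_count | mpv$pseudo_count >= 1
  idx <- which(universe)
  # fold change is taken against the pseudo-count's implied RPKM (the same
  # quantization the exact test sees), so a hybrid count equal to the
  # pseudo-count has fold change exactly 1
  len_kb <- catalog$length_bp[match(counts$gene_id, catalog$gene_id)] / 1000
  mpv_eff <- mpv$pseudo_count[idx] / len_kb[idx] / (pseudo_total / 1e6)
  fm <- pmax(mpv_eff, epsilon)
  fh <- pmax(rpkm$rpkm_C[idx], epsilon)
  log2fc <- log2(fh / fm)
  fc <- pmax(fh, fm) / pmin(fh, fm)
  p <- ac_test(mpv$pseudo_count[idx], counts$count_C[idx], pseudo_total, totals[["C"]])
  fdr <- bh_adjust(p)
  nonadd <- fc >= fc_min & fdr <= fdr_max

  out <- data.frame(
    gene_id = counts$gene_id[idx],
    mpv_rpkm = mpv$mpv_rpkm[idx],
    pseudo_count = mpv$pseudo_count[idx],
    hybrid_count = counts$count_C[idx],
    hybrid_rpkm = rpkm$rpkm_C[idx],
    fold_change = fc, log2fc = log2fc,
    p_value = p, fdr = fdr,
    label = ifelse(nonadd, "nonadditive", "additive"),
    deviation_direction = ifelse(!nonadd, "none", ifelse(log2fc > 0, "above", "below")),
    stringsAsFactors = FALSE
  )
  attr(out, "n_nonadditive") <- sum(nonadd)
  attr(out, "n_detected") <- n_detected
  attr(out, "percent_nonadditive") <- round_half_up(100 * sum(nonadd) / n_detected, 3)
  class(out) <- c("additivity_table", "data.frame")
  out
}

#' Cross-tabulate nonadditive genes with DEG status and pattern groups
#'
#' Bookkeeping of how the nonadditive set overlaps the two DEG sets: how many
#' nonadditive genes are DEGs in either hybrid/parent comparison, and how
#' those split over the four expression-pattern groups.
#'
#' @param additivity an `"additivity_table"` from [classify_additivity()].
#' @param patterns a pattern assignment from [assign_patterns()].
#' @return list: `n_nonadditive`, `n_deg_overlap` (nonadditive genes that are
#'   DEG against at least one parent), and `by_group` (named counts over
#'   groups 1-4 for the overlapping genes).
#' @export
nonadditive_deg_overlap <- function(additivity, patterns) {
  na_genes <- additivity$gene_id[additivity$label == "nonadditive"]
  m <- patterns[match(na_genes, patterns$gene_id), , drop = FALSE]
  in_deg <- !is.na(m$group) & m$group != "none"
  by_group <- table(factor(m$group[in_deg], levels = c("1", "2", "3", "4")))
  list(
    n_nonadditive = length(na_genes),
    n_deg_overlap = sum(in_deg),
    by_group = stats::setNames(as.integer(by_group), names(by_group))
  )
}
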