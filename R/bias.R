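# Normalized parental-bias statistic over the DEG union.

#' Parental-bias statistic d
#'
#' For each gene, the relative divergence of the hybrid from each parent is
#' the absolute RPKM difference divided by the hybrid RPKM; `d` is the
#' paternal relative divergence minus the maternal one:
#' `d = |C - A|/C - |C - B|/C`. A positive `d` means the gene's expression
#' diverged more from the paternal parent (A) than from the maternal (B).
#' Genes with zero hybrid RPKM are evaluated with `C` floored at `epsilon`;
#' genes with zero RPKM in all three libraries are excluded (`NA`) and a
#' message reports how many.
#'
#' @param rpkm_A,rpkm_B,rpkm_C per-gene RPKM vectors.
#' @param epsilon floor applied to a zero hybrid RPKM.
#' @return numeric vector of `d` values (`NA` for all-zero genes), with the
#'   number of floored hybrids in attribute `n_floored`.
#' @export
bias_statistic <- function(rpkm_A, rpkm_B, rpkm_C, epsilon = 0.001) {
  all_zero <- rpkm_A == 0 & rpkm_B == 0 & rpkm_C == 0
  floored <- rpkm_C == 0 & !all_zero
  if (any(all_zero)) {
    message(sprintf("bias_statistic: %d all-zero gene(s) excluded", sum(all_zero)))
  }
  cc <- pmax(rpkm_C, epsilon)
  d <- abs(cc - rpkm_A) / cc - abs(cc - rpkm_B) / cc
  d[all_zero] <- NA_real_
  attr(d, "n_floored") <- sum(floored)
  d
}

#' Summarize the sign distribution of the bias statistic
#'
#' Exact counts of positive, negative and zero `d` values (zero means
#' `|d| < zero_tol`, making "exactly zero" well-defined on floating point)
#' with percentages rounded half-up to the nearest percent. `NA` values
#' (excluded genes) are dropped before counting.
#'
#' @param d vector from [bias_statistic()].
#' @param zero_tol absolute tolerance for calling `d` zero.
#' @return list: `n_scored`, `n_positive`, `n_negative`, `n_zero`,
#'   `pct_positive`, `pct_negative`, `pct_zero`.
#' @export
bias_summary <- function(d, zero_tol = 1e-12) {
  d <- d[!is.na(d)]
  if (!length(d)) fail("bias_summary", "no scored genes")
  zero <- abs(d) < zero_tol
  pos <- d > 0 & !zero
  neg <- d < 0 & !zero
  n <- length(d)
  list(
    n_scored = n,
    n_positive = sum(pos), n_negative = sum(neg), n_zero = sum(zero),
    pct_positive = round_half_up(100 * sum(pos) / n),
    pct_negative = round_half_up(100 * sum(neg) / n),
    pct_zero = round_half_up(100 * sum(zero) / n)
  )
}

#' Summed fold change of the DEGs in a comparison
#'
#' Total of the per-DEG expression differences of one comparison: by default
#' the sum of the (max/min, >= 1) fold changes of all DEGs; alternatively the
#' sum of `|log2fc|`. Comparisons with more, or more strongly shifted, DEGs
#' yield larger totals.
#'
#' @param deg a `"deg_table"` from [call_degs()].
#' @param method `"fold"` (default) or `"log2"`.
#' @return single numeric total (0 for an empty DEG set).
#' @export
summed_fold_change <- function(deg, method = c("fold", "log2")) {
  method <- match.arg(method)
  d <- deg[deg$is_deg, , drop = FALSE]
  if (!nrow(d)) return(0)
  switch(method,
         fold = sum(d$fold_change),
         log2 = sum(abs(d$log2fc)))
}
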