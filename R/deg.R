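# DEG calling between the hybrid and one parent.

#' Call differentially expressed genes for one comparison
#'
#' Applies the Audic-Claverie exact test to the hybrid-versus-parent count
#' pair of every gene expressed (per `min_count`) in at least one library of
#' the pair, adjusts p-values by Benjamini-Hochberg over that tested
#' universe, and labels genes with `fold_change >= fc_min` and
#' `fdr <= fdr_max` as DEGs (defaults: two-fold, FDR 0.001). Fold change is
#' computed on RPKM — not raw counts — so unequal library depths do not
#' masquerade as differential expression; zero RPKM values are floored at
#' `epsilon` before forming ratios.
#'
#' @param counts count matrix (`gene_id`, `count_A`..`count_C`, attribute
#'   `library_sizes`).
#' @param expression RPKM table from [compute_rpkm()].
#' @param comparison `"C-vs-A"` (hybrid vs paternal parent) or `"C-vs-B"`
#'   (hybrid vs maternal parent).
#' @param min_count detection threshold defining the tested universe.
#' @param fc_min minimum fold change (>= 1).
#' @param fdr_max maximum FDR in `(0, 1]`.
#' @param epsilon RPKM floor for zero values (default 0.001).
#' @return data.frame of class `"deg_table"`, one row per tested gene:
#'   `gene_id`, reference and hybrid counts (`x`, `y`) and RPKM, `fold_change`
#'   (max/min ratio, >= 1), `log2fc` (hybrid over reference), `p_value`,
#'   `fdr`, `direction` (`"up"`/`"down"` in the hybrid; a ratio of exactly 1
#'   counts as down), `is_deg`. The comparison label and thresholds ride
#'   along as attributes.
#' @export
call_degs <- function(counts, expression, comparison = c("C-vs-A", "C-vs-B"),
                      min_count = 1L, fc_min = 2, fdr_max = 0.001,
                      epsilon = 0.001) {
  comparison <- match.arg(comparison)
  if (fc_min < 1) fail("call_degs", "'fc_min' must be >= 1")
  if (!(fdr_max > 0 && fdr_max <= 1)) fail("call_degs", "'fdr_max' must lie in (0, 1]")
  if (epsilon <= 0) fail("call_degs", "'epsilon' must be positive")
  check_counts_df(counts, "call_degs")
  ref <- if (comparison == "C-vs-A") "A" else "B"
  totals <- library_sizes(counts)

  x <- counts[[paste0("count_", ref)]]
  y <- counts$count_C
  universe <- x >= min_count | y >= min_count
  idx <- which(universe)
  ord <- match(counts$gene_id, expression$gene_id)
  r_ref <- expression[[paste0("rpkm_", ref)]][ord]
  r_hyb <- expression$rpkm_C[ord]

  fr <- pmax(r_ref[idx], epsilon)
  fh <- pmax(r_hyb[idx], epsilon)
  log2fc <- log2(fh / fr)
  fc <- pmax(fh, fr) / pmin(fh, fr)
  p <- ac_test(x[idx], y[idx], totals[[ref]], totals[["C"]])
  fdr <- bh_adjust(p)

  out <- data.frame(
    gene_id = counts$gene_id[idx],
    x = x[idx], y = y[idx],
    rpkm_ref = r_ref[idx], rpkm_hybrid = r_hyb[idx],
    fold_change = fc, log2fc = log2fc,
    p_value = p, fdr = fdr,
    direction = ifelse(log2fc > 0, "up", "down"),
    is_deg = fc >= fc_min & fdr <= fdr_max,
    stringsAsFactors = FALSE
  )
  attr(out, "comparison") <- comparison
  attr(out, "fc_min") <- fc_min
  attr(out, "fdr_max") <- fdr_max
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Summarize a DEG table
#'
#' @param deg a `"deg_table"` from [call_degs()].
#' @return list: comparison label, tested-universe size, DEG count, up and
#'   down counts in the hybrid, and the summed fold change of the DEGs.
#' @export
deg_summary <- function(deg) {
  d <- deg[deg$is_deg, , drop = FALSE]
  list(
    comparison = attr(deg, "comparison"),
    n_tested = nrow(deg),
    n_deg = nrow(d),
    n_up = sum(d$direction == "up"),
    n_down = sum(d$direction == "down"),
    summed_fold_change = sum(d$fold_change)
  )
}
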