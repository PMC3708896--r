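# RPKM computation, expressed-gene calling, Venn partitioning and binning.

#' Compute RPKM expression values
#'
#' RPKM (reads per kilobase of exon per million assigned reads) for each gene
#' and library: `count / (length_bp/1000) / (library_total/1e6)`. Library
#' totals come from the count matrix's `library_sizes` attribute (column sums
#' when absent).
#'
#' @param counts count matrix (`gene_id`, `count_A`, `count_B`, `count_C`).
#' @param catalog gene catalog (`gene_id`, `length_bp`).
#' @return data.frame `gene_id`, `rpkm_A`, `rpkm_B`, `rpkm_C`, with the
#'   library totals carried in the `library_sizes` attribute.
#' @export
compute_rpkm <- function(counts, catalog) {
  check_counts_df(counts, "compute_rpkm")
  idx <- match(counts$gene_id, catalog$gene_id)
  if (anyNA(idx)) {
    missing <- counts$gene_id[is.na(idx)]
    fail("compute_rpkm", "genes absent from catalog: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5) else "")
  }
  len_kb <- catalog$length_bp[idx] / 1000
  if (any(len_kb <= 0)) fail("compute_rpkm", "gene lengths must be positive")
  totals <- library_sizes(counts)
  if (any(totals <= 0)) fail("compute_rpkm", "library totals must be positive")
  out <- data.frame(gene_id = counts$gene_id, stringsAsFactors = FALSE)
  for (l in LIBS) {
    out[[paste0("rpkm_", l)]] <-
      counts[[paste0("count_", l)]] / len_kb / (totals[[l]] / 1e6)
  }
  attr(out, "library_sizes") <- totals
  out
}

#' Call expressed genes per library
#'
#' A gene is expressed in a library when its read count reaches `min_count`
#' (default 1 read; the detection rule is deliberately simple and exposed).
#'
#' @param counts count matrix.
#' @param min_count minimum read count (>= 1).
#' @return data.frame `gene_id`, logical `expr_A`, `expr_B`, `expr_C`.
#' @export
call_expressed <- function(counts, min_count = 1L) {
  check_counts_df(counts, "call_expressed")
  if (min_count < 1) fail("call_expressed", "'min_count' must be >= 1")
  out <- data.frame(gene_id = counts$gene_id, stringsAsFactors = FALSE)
  for (l in LIBS) out[[paste0("expr_", l)]] <- counts[[paste0("count_", l)]] >= min_count
  out
}

#' Three-set Venn partition of expressed genes
#'
#' Counts the seven regions of the A/B/C expression Venn diagram and derives
#' the per-library totals and grand total by summation.
#'
#' @param flags data.frame from [call_expressed()] (or any logical columns
#'   `expr_A`, `expr_B`, `expr_C`).
#' @return object of class `"venn_partition"`: list with `regions` (named
#'   A, B, C, AB, AC, BC, ABC — pairwise regions exclude the triple), `totals`
#'   (per library) and `grand` (genes expressed anywhere).
#' @export
venn_partition <- function(flags) {
  a <- flags$expr_A; b <- flags$expr_B; c <- flags$expr_C
  if (is.null(a) || is.null(b) || is.null(c)) {
    fail("venn_partition", "need logical columns expr_A, expr_B, expr_C")
  }
  regions <- c(
    A = sum(a & !b & !c), B = sum(!a & b & !c), C = sum(!a & !b & c),
    AB = sum(a & b & !c), AC = sum(a & !b & c), BC = sum(!a & b & c),
    ABC = sum(a & b & c)
  )
  venn_totals(regions)
}

#' Assemble a Venn partition from region counts
#'
#' Builds the partition object directly from the seven exclusive region
#' counts (e.g. the numbers printed on a published Venn diagram) and derives
#' the per-library and grand totals.
#'
#' @param regions named numeric vector with entries `A`, `B`, `C` (specific),
#'   `AB`, `AC`, `BC` (pairwise-only) and `ABC` (triple intersection).
#' @return a `"venn_partition"` object (see [venn_partition()]).
#' @export
venn_totals <- function(regions) {
  need <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  if (!all(need %in% names(regions))) {
    fail("venn_totals", "regions must be named ", paste(need, collapse = ", "))
  }
  regions <- regions[need]
  totals <- c(
    A = unname(regions["ABC"] + regions["AB"] + regions["AC"] + regions["A"]),
    B = unname(regions["ABC"] + regions["AB"] + regions["BC"] + regions["B"]),
    C = unname(regions["ABC"] + regions["AC"] + regions["BC"] + regions["C"])
  )
  structure(list(regions = regions, totals = totals, grand = sum(regions)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Three-set Venn partition of expressed genes\n")
  cat("  regions:", paste(sprintf("%s=%g", names(x$regions), x$regions), collapse = " "), "\n")
  cat("  totals: ", paste(sprintf("%s=%g", names(x$totals), x$totals), collapse = " "), "\n")
  cat("  grand total:", x$grand, "\n")
  invisible(x)
}

#' Gene-length distribution over the standard five bins
#'
#' Tabulates catalog lengths into the bins `[100,500)`, `[500,1000)`,
#' `[1000,1500)`, `[1500,2000)`, `[2000,Inf)` (left-closed, right-open) and
#' reports counts and percentages rounded half-up to 2 decimals.
#'
#' @param catalog gene catalog (`gene_id`, `length_bp`), typically restricted
#'   to detected genes.
#' @return data.frame `bin`, `count`, `percentage`.
#' @export
length_bin_summary <- function(catalog) {
  if (nrow(catalog) == 0) fail("length_bin_summary", "empty gene set")
  bin <- findInterval(catalog$length_bp, LENGTH_BIN_LOWER)
  if (any(bin == 0)) fail("length_bin_summary", "gene lengths below 100 bp")
  counts <- tabulate(bin, 5L)
  data.frame(
    bin = LENGTH_BIN_LABELS,
    count = counts,
    percentage = round_half_up(100 * counts / sum(counts), 2),
    stringsAsFactors = FALSE
  )
}

#' Bin genes by covered fraction of their sequence
#'
#' Decile bins `(0,10%]`, ..., `(90%,100%]` of the per-gene fraction of the
#' gene model covered by reads; genes with fraction 0 (not matched) are
#' excluded. Coverage fractions are taken as input — computing them from
#' alignments is outside this package.
#'
#' @param fractions data.frame with `gene_id` and one numeric column per
#'   library (values in `[0, 1]`).
#' @return data.frame with a `bin` column and one count column per input
#'   library column.
#' @export
coverage_bins <- function(fractions) {
  num_cols <- names(fractions)[vapply(fractions, is.numeric, logical(1))]
  if (!length(num_cols)) fail("coverage_bins", "no numeric coverage columns")
  labels <- sprintf("(%d%%,%d%%]", seq(0, 90, 10), seq(10, 100, 10))
  out <- data.frame(bin = labels, stringsAsFactors = FALSE)
  for (cl in num_cols) {
    f <- fractions[[cl]]
    if (any(!is.finite(f)) || any(f < 0) || any(f > 1)) {
      fail("coverage_bins", sprintf("column '%s' has fractions outside [0, 1]", cl))
    }
    f <- f[f > 0]
    # nudge guards binary-representation error at exact decile boundaries
    out[[cl]] <- tabulate(ceiling(f * 10 - 1e-9), 10L)
  }
  out
}
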