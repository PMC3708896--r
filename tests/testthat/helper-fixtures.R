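# Shared fixtures: tiny hand-built count matrices and a small simulation.

# count matrix with explicit library totals
make_counts <- function(count_A, count_B, count_C, length_bp = NULL,
                        totals = NULL) {
  n <- length(count_A)
  df <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n)),
    length_bp = if (is.null(length_bp)) rep(1000L, n) else as.integer(length_bp),
    count_A = as.integer(count_A),
    count_B = as.integer(count_B),
    count_C = as.integer(count_C),
    stringsAsFactors = FALSE
  )
  if (!is.null(totals)) attr(df, "library_sizes") <- stats::setNames(as.numeric(totals),
                                                                     c("A", "B", "C"))
  df
}

catalog_of <- function(counts) counts[, c("gene_id", "length_bp")]

# small, fast simulation used by several module tests
small_config <- function(...) {
  simulation_config(n_genes = 800L,
                    library_sizes = c(A = 4e5, B = 4e5, C = 4e5),
                    seed = 99L, ...)
}
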