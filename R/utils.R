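# Internal helpers shared across modules.

LIBS <- c("A", "B", "C")

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.125 -> 0.13 at 2 digits), the
#' convention used for all reported percentages. Base `round()` rounds half to
#' even, which disagrees with how the summary tables print shares.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(7.7965, 3)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# stop() with a stage/function prefix, no call in the condition
fail <- function(stage, ...) {
  stop(sprintf("%s: %s", stage, paste0(...)), call. = FALSE)
}

# validate a probability-like scalar
check_prob <- function(x, name, stage) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    fail(stage, sprintf("'%s' must lie in [0, 1]", name))
  }
  invisible(x)
}

# library totals attached to a count matrix (named A/B/C); fall back to
# column sums when the attribute is absent
library_sizes <- function(counts) {
  tot <- attr(counts, "library_sizes")
  if (is.null(tot)) {
    tot <- vapply(LIBS, function(l) sum(counts[[paste0("count_", l)]]), numeric(1))
  }
  tot
}

check_counts_df <- function(counts, stage) {
  need <- c("gene_id", paste0("count_", LIBS))
  miss <- setdiff(need, names(counts))
  if (length(miss)) fail(stage, "count table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(counts$gene_id)) {
    fail(stage, "duplicate gene ids: ",
         paste(unique(counts$gene_id[duplicated(counts$gene_id)])[1:5], collapse = ", "))
  }
  invisible(counts)
}
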