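# Table readers and writers for the standard TSV formats.

#' Read a three-library count table
#'
#' Expects a tab-separated file with a header containing `gene_id`,
#' `count_A`, `count_B`, `count_C` (a `length_bp` column is carried along if
#' present). Counts must be non-negative integers and gene ids unique; parse
#' errors name the offending column, id or line.
#'
#' @param path file path.
#' @param totals optional named library totals (A, B, C); column sums are
#'   used when absent.
#' @return count matrix data.frame with attribute `library_sizes`.
#' @export
read_counts <- function(path, totals = NULL) {
  if (!file.exists(path)) fail("read_counts", "no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", paste0("count_", LIBS))
  miss <- setdiff(need, names(df))
  if (length(miss)) fail("read_counts", "missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id)) {
    dup <- unique(df$gene_id[duplicated(df$gene_id)])
    fail("read_counts", "duplicate gene id(s): ", paste(utils::head(dup, 5), collapse = ", "))
  }
  for (l in LIBS) {
    col <- paste0("count_", l)
    v <- df[[col]]
    bad <- which(!is.finite(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      fail("read_counts", sprintf("column '%s': non-integer or negative count at line(s) %s",
                                  col, paste(utils::head(bad + 1L, 5), collapse = ", ")))
    }
    df[[col]] <- as.integer(v)
  }
  if (is.null(totals)) {
    totals <- vapply(LIBS, function(l) sum(df[[paste0("count_", l)]]), numeric(1))
  } else {
    if (length(totals) != 3) fail("read_counts", "'totals' must have 3 entries")
    totals <- stats::setNames(as.numeric(totals), LIBS)
  }
  attr(df, "library_sizes") <- totals
  df
}

#' Read gene lengths from a TSV or BED file
#'
#' Two layouts are accepted: a headered TSV with columns `gene_id` and
#' `length_bp` (or `length`), or a headerless BED-style table whose first
#' three columns are gene id, start and end (0-based half-open, so length =
#' end - start).
#'
#' @param path file path.
#' @return gene catalog data.frame (`gene_id`, `length_bp`).
#' @export
read_lengths <- function(path) {
  if (!file.exists(path)) fail("read_lengths", "no such file: ", path)
  first <- readLines(path, n = 1)
  if (grepl("gene_id", first, fixed = TRUE)) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    len_col <- intersect(c("length_bp", "length"), names(df))[1]
    if (is.na(len_col)) fail("read_lengths", "no length_bp/length column")
    out <- data.frame(gene_id = df$gene_id, length_bp = as.integer(df[[len_col]]),
                      stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 3) fail("read_lengths", "BED input needs at least 3 columns")
    out <- data.frame(gene_id = as.character(df[[1]]),
                      length_bp = as.integer(df[[3]] - df[[2]]),
                      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(out$gene_id)) {
    fail("read_lengths", "duplicate gene id(s): ",
         paste(utils::head(unique(out$gene_id[duplicated(out$gene_id)]), 5), collapse = ", "))
  }
  bad <- which(!is.finite(out$length_bp) | out$length_bp < 1)
  if (length(bad)) {
    fail("read_lengths", "non-positive length at line(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  out
}

#' Write a data.frame as headered TSV
#'
#' RPKM and other real-valued columns are written at fixed 6-decimal
#' precision so write/read round-trips are stable.
#'
#' @param df data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
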