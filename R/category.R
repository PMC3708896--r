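# Functional-category contrasts between additive and nonadditive genes.

#' Contrast category membership of additive versus nonadditive genes
#'
#' For each functional category, builds the 2x2 table (in-category versus
#' not) x (nonadditive versus additive) over the labelled genes, applies
#' Fisher's exact test, adjusts across categories by Benjamini-Hochberg, and
#' reports the enrichment direction from the sample odds ratio (proportion
#' in-category among nonadditive versus among additive genes). A gene may
#' carry several categories. Categories with no labelled member in either
#' class are skipped with a message.
#'
#' @param labels data.frame `gene_id`, `label`
#'   (`"additive"`/`"nonadditive"`), e.g. from [classify_additivity()].
#' @param annotation data.frame `gene_id`, `category` (one row per
#'   membership).
#' @return data.frame, one row per category: member counts in each class,
#'   class totals, `odds_ratio` (sample estimate; `Inf` convention for empty
#'   cells), `p_value`, `fdr`, `direction` (`"nonadditive"`, `"additive"` or
#'   `"none"` for an odds ratio of exactly 1).
#' @export
contrast_categories <- function(labels, annotation) {
  if (!all(c("gene_id", "label") %in% names(labels))) {
    fail("contrast_categories", "labels need columns gene_id, label")
  }
  if (!all(c("gene_id", "category") %in% names(annotation))) {
    fail("contrast_categories", "annotation needs columns gene_id, category")
  }
  is_na_gene <- labels$label == "nonadditive"
  n_nonadd <- sum(is_na_gene)
  n_add <- sum(!is_na_gene)
  na_set <- labels$gene_id[is_na_gene]

  cats <- unique(annotation$category)
  rows <- lapply(cats, function(cat) {
    members <- unique(annotation$gene_id[annotation$category == cat])
    members <- members[members %in% labels$gene_id]
    a <- sum(members %in% na_set)        # nonadditive, in category
    b <- length(members) - a             # additive, in category
    if (a + b == 0) return(NULL)         # no labelled member in either class
    cc <- n_nonadd - a
    dd <- n_add - b
    ft <- stats::fisher.test(matrix(c(a, b, cc, dd), nrow = 2))
    or <- (a * dd) / (b * cc)            # sample odds ratio, Inf when b*cc = 0
    if (is.nan(or)) or <- 1              # 0/0: no information
    data.frame(
      category = cat,
      nonadditive_in = a, additive_in = b,
      nonadditive_total = n_nonadd, additive_total = n_add,
      odds_ratio = or, p_value = ft$p.value,
      stringsAsFactors = FALSE
    )
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped) message(sprintf("contrast_categories: %d empty categorie(s) skipped", skipped))
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) fail("contrast_categories", "no category has labelled members")
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_value)
  out$direction <- ifelse(out$odds_ratio > 1, "nonadditive",
                          ifelse(out$odds_ratio < 1, "additive", "none"))
  out
}
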