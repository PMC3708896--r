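# End-to-end pipeline runner.

#' Run the full three-library comparison pipeline
#'
#' Executes, in order: RPKM quantification and expressed-gene Venn
#' partitioning, length-bin summary, the two hybrid-versus-parent DEG
#' comparisons, midparent nonadditivity classification, expression-pattern
#' assignment, the parental-bias summary over the DEG union, and (when an
#' annotation is supplied) the additive/nonadditive category contrast. Any
#' stage failure aborts with the stage name. Given identical inputs and
#' seeds the emitted summary is byte-identical.
#'
#' @param counts count matrix (e.g. from [read_counts()] or
#'   [simulate_dataset()]).
#' @param catalog gene catalog (e.g. from [read_lengths()]).
#' @param min_count,fc_min,fdr_max,epsilon thresholds passed to the stages.
#' @param annotation optional `gene_id`/`category` table for
#'   [contrast_categories()].
#' @param saturation_depths optional depth grid; when supplied, a saturation
#'   curve is computed for each library.
#' @param seed seed for the saturation subsampling.
#' @param out_dir optional directory; when set, per-stage TSVs and a
#'   `summary.json` bundle are written there.
#' @return list with elements `venn`, `length_bins`, `deg_CA`, `deg_CB`,
#'   `additivity`, `patterns`, `bias`, `overlap`, optional `categories` and
#'   `saturation`, plus `summary` (the headline statistics).
#' @export
run_report <- function(counts, catalog, min_count = 1L, fc_min = 2,
                       fdr_max = 0.001, epsilon = 0.001, annotation = NULL,
                       saturation_depths = NULL, seed = 1L, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      fail("run_report", sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  rpkm <- stage("quantify", compute_rpkm(counts, catalog))
  expr_flags <- stage("quantify", call_expressed(counts, min_count))
  venn <- stage("quantify", venn_partition(expr_flags))
  detected <- expr_flags$expr_A | expr_flags$expr_B | expr_flags$expr_C
  bins <- stage("quantify", length_bin_summary(catalog[catalog$gene_id %in%
                                                         counts$gene_id[detected], , drop = FALSE]))

  deg_CA <- stage("deg", call_degs(counts, rpkm, "C-vs-A", min_count, fc_min, fdr_max, epsilon))
  deg_CB <- stage("deg", call_degs(counts, rpkm, "C-vs-B", min_count, fc_min, fdr_max, epsilon))
  sum_CA <- deg_summary(deg_CA)
  sum_CB <- deg_summary(deg_CB)

  additivity <- stage("nonadditive",
                      classify_additivity(counts, catalog, min_count = min_count,
                                          fc_min = fc_min, fdr_max = fdr_max,
                                          epsilon = epsilon, n_detected = sum(detected)))

  profiles <- stage("patterns", log_ratio_profiles(rpkm, epsilon))
  patterns <- stage("patterns", assign_patterns(deg_CA, deg_CB, profiles))
  overlap <- stage("patterns", nonadditive_deg_overlap(additivity, patterns))

  deg_union <- union(deg_CA$gene_id[deg_CA$is_deg], deg_CB$gene_id[deg_CB$is_deg])
  bias <- stage("bias", {
    ix <- match(deg_union, rpkm$gene_id)
    d <- bias_statistic(rpkm$rpkm_A[ix], rpkm$rpkm_B[ix], rpkm$rpkm_C[ix], epsilon)
    bias_summary(d)
  })

  categories <- if (!is.null(annotation)) {
    stage("contrast", contrast_categories(
      data.frame(gene_id = additivity$gene_id, label = additivity$label,
                 stringsAsFactors = FALSE),
      annotation))
  }

  saturation <- if (!is.null(saturation_depths)) {
    stage("saturate", lapply(stats::setNames(LIBS, LIBS), function(l) {
      cnt <- counts[[paste0("count_", l)]]
      saturation_curve(cnt, saturation_depths[saturation_depths <= sum(cnt)],
                       min_count = min_count, seed = seed)
    }))
  }

  group_counts <- table(factor(patterns$group[patterns$group != "none"],
                               levels = c("1", "2", "3", "4")))
  summary <- list(
    genes_total = nrow(counts),
    genes_detected = venn$grand,
    venn_regions = as.list(venn$regions),
    venn_totals = as.list(venn$totals),
    deg_C_vs_A = sum_CA[c("n_deg", "n_up", "n_down", "summed_fold_change")],
    deg_C_vs_B = sum_CB[c("n_deg", "n_up", "n_down", "summed_fold_change")],
    deg_union = length(deg_union),
    pattern_groups = as.list(stats::setNames(as.integer(group_counts), names(group_counts))),
    n_both_significant = sum(patterns$basis == "both-significant"),
    nonadditive = list(
      n = attr(additivity, "n_nonadditive"),
      n_detected = attr(additivity, "n_detected"),
      percent = attr(additivity, "percent_nonadditive"),
      deg_overlap = overlap$n_deg_overlap,
      overlap_by_group = as.list(overlap$by_group)
    ),
    bias = bias
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_tsv(deg_CA, file.path(out_dir, "deg_C_vs_A.tsv"))
    write_tsv(deg_CB, file.path(out_dir, "deg_C_vs_B.tsv"))
    write_tsv(as.data.frame(additivity), file.path(out_dir, "nonadditive.tsv"))
    write_tsv(patterns, file.path(out_dir, "patterns.tsv"))
    write_tsv(bins, file.path(out_dir, "length_bins.tsv"))
    if (!is.null(categories)) write_tsv(categories, file.path(out_dir, "category_contrast.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  res <- list(venn = venn, length_bins = bins, deg_CA = deg_CA, deg_CB = deg_CB,
              additivity = additivity, patterns = patterns, overlap = overlap,
              bias = bias, summary = summary)
  if (!is.null(categories)) res$categories <- categories
  if (!is.null(saturation)) res$saturation <- saturation
  res
}
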