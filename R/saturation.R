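# Read-subsampling saturation analysis for one library.

#' Saturation curve by read subsampling
#'
#' Subsamples reads without replacement from one library's per-gene counts at
#' each requested depth (an exact multivariate-hypergeometric draw) and counts
#' how many genes reach `min_count` sampled reads. Within a replicate the
#' draws are nested — each depth's sample is a prefix of the deepest sample —
#' so every replicate's curve is monotone nondecreasing by construction.
#'
#' @param counts non-negative integer vector of per-gene read counts (names
#'   are gene ids if present).
#' @param depths numeric vector of subsampling depths (reads); each must lie
#'   in `[0, sum(counts)]`.
#' @param min_count detection threshold on sampled reads (default 1).
#' @param n_reps number of independent replicates averaged.
#' @param seed RNG seed.
#' @return object of class `"saturation_curve"`: data.frame `depth`,
#'   `detected` (mean over replicates), with per-replicate counts in the
#'   `replicates` attribute and `min_count`/`total` attributes.
#' @export
saturation_curve <- function(counts, depths, min_count = 1L, n_reps = 3L, seed = 1L) {
  if (any(counts < 0)) fail("saturation_curve", "counts must be non-negative")
  total <- sum(counts)
  depths <- sort(unique(as.numeric(depths)))
  if (any(depths < 0) || any(depths > total)) {
    fail("saturation_curve", "depths must lie in [0, total reads]")
  }
  n_genes <- length(counts)
  breaks <- cumsum(as.numeric(counts))
  max_depth <- max(depths)
  reps <- matrix(0, nrow = length(depths), ncol = n_reps)
  set.seed(seed %% .Machine$integer.max)
  for (r in seq_len(n_reps)) {
    # distinct read positions; a uniform sample's prefix is itself a uniform
    # subsample, which is what makes the depths nested
    pos <- if (max_depth > 0) sample.int(total, max_depth) else integer(0)
    gene <- findInterval(pos - 1L, breaks) + 1L
    for (i in seq_along(depths)) {
      d <- depths[i]
      reps[i, r] <- if (d == 0) 0L else {
        sum(tabulate(gene[seq_len(d)], n_genes) >= min_count)
      }
    }
  }
  structure(
    data.frame(depth = depths, detected = rowMeans(reps)),
    replicates = reps, min_count = min_count, total = total,
    class = c("saturation_curve", "data.frame")
  )
}

#' Locate the saturation depth of a detection curve
#'
#' Returns the smallest grid depth after which the marginal gain in detected
#' genes per additional million reads drops below `gain_threshold` times the
#' total number of genes detected at full grid depth; `NA` when the curve
#' never plateaus on the grid. A flat curve saturates at its first depth.
#'
#' @param curve a [saturation_curve()] (or data.frame `depth`, `detected`).
#' @param gain_threshold relative marginal-gain cutoff (default 0.005, i.e.
#'   0.5 percent of the detected total per million reads).
#' @return saturation depth (reads), or `NA` if never reached.
#' @export
saturation_point <- function(curve, gain_threshold = 0.005) {
  if (nrow(curve) < 3) fail("saturation_point", "need at least 3 grid points")
  d <- curve$depth
  y <- curve$detected
  full <- y[length(y)]
  gain_per_million <- diff(y) / (diff(d) / 1e6)
  ok <- which(gain_per_million < gain_threshold * full)
  if (!length(ok)) return(NA_real_)
  d[ok[1]]
}
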