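# Synthetic three-library datasets with known ground truth.
#
# The generator emulates the structure the downstream analysis assumes: a gene
# catalog with the observed length distribution, lognormal baseline expression,
# parent-divergent genes, a tunable fraction of genes whose hybrid mean
# deviates from the parental midpoint, library-specific (truly silent
# elsewhere) genes, and negative-binomial count sampling.

# length bins: left-closed right-open; the last bin is open-ended
LENGTH_BIN_LOWER <- c(100L, 500L, 1000L, 1500L, 2000L)
LENGTH_BIN_LABELS <- c("100-500", "500-1000", "1000-1500", "1500-2000", ">=2000")

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. Defaults
#' describe a full-size study: 32,642 genes with the observed five-bin length
#' distribution, library depths equal to the three libraries'
#' uniquely-assigned read totals, and modest fractions of library-specific,
#' parent-divergent and nonadditive genes.
#'
#' @param n_genes number of genes in the catalog.
#' @param length_bin_weights five probabilities over the length bins
#'   `[100,500)`, `[500,1000)`, `[1000,1500)`, `[1500,2000)`, `[2000,Inf)`;
#'   must sum to 1.
#' @param library_sizes three positive assigned-read totals for libraries A
#'   (paternal), B (maternal), C (hybrid). Per-gene expected counts are
#'   proportional to `rate * length_kb` and normalized so each library's
#'   expected total equals its configured size (see [expected_counts()]).
#' @param frac_specific per-library probability that a gene is expressed only
#'   in that library (true-zero mean elsewhere, not dropout); scalar or
#'   length 3 (A, B, C).
#' @param frac_de_parents probability a gene's parental means differ; the
#'   signed log2 separation is drawn from Normal(0, `de_log2_sd`).
#' @param de_log2_sd scale of the symmetric parental log2-divergence draw.
#' @param frac_nonadditive probability the hybrid mean deviates from the
#'   parental midpoint; the deviation magnitude is
#'   `na_log2_min + Exponential(na_log2_rate)` in log2 units, so every drawn
#'   deviation is at least `na_log2_min`.
#' @param na_log2_min minimum |log2| deviation of a nonadditive gene from the
#'   midparent value.
#' @param na_log2_rate rate of the exponential tail above `na_log2_min`.
#' @param paternal_bias real in `[-1, 1]`; the probability that a nonadditive
#'   deviation is directed away from the paternal parent A (toward B) is
#'   `(1 + paternal_bias)/2`. Positive values emulate directional expression
#'   change away from the paternal parent.
#' @param dispersion negative-binomial overdispersion `phi`
#'   (variance `m + phi * m^2`); 0 gives Poisson sampling.
#' @param base_meanlog,base_sdlog lognormal parameters of the baseline
#'   expression rate (RPKM units).
#' @param seed integer master seed; catalog, truth and count draws use three
#'   fixed offsets of it so each stage is independently reproducible.
#' @return a validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 32642L,
                              length_bin_weights = c(0.1546, 0.3071, 0.2541, 0.1362, 0.1480),
                              library_sizes = c(A = 8594083, B = 5479383, C = 6267830),
                              frac_specific = c(A = 0.0426, B = 0.0284, C = 0.0277),
                              frac_de_parents = 0.20,
                              de_log2_sd = 1.5,
                              frac_nonadditive = 0.08,
                              na_log2_min = 1,
                              na_log2_rate = 2,
                              paternal_bias = 0.25,
                              dispersion = 0.05,
                              base_meanlog = 1.0,
                              base_sdlog = 1.2,
                              seed = 1L) {
  stage <- "simulation_config"
  if (!is.numeric(n_genes) || length(n_genes) != 1 || n_genes < 1) {
    fail(stage, "'n_genes' must be a positive integer")
  }
  if (length(length_bin_weights) != 5) fail(stage, "'length_bin_weights' must have length 5")
  check_prob(length_bin_weights, "length_bin_weights", stage)
  if (abs(sum(length_bin_weights) - 1) > 1e-8) {
    fail(stage, "'length_bin_weights' must sum to 1")
  }
  if (length(library_sizes) != 3 || any(library_sizes < 1)) {
    fail(stage, "'library_sizes' must be 3 values >= 1")
  }
  if (length(frac_specific) == 1) frac_specific <- rep(frac_specific, 3)
  if (length(frac_specific) != 3) fail(stage, "'frac_specific' must have length 1 or 3")
  check_prob(frac_specific, "frac_specific", stage)
  if (sum(frac_specific) > 1) fail(stage, "'frac_specific' probabilities sum above 1")
  check_prob(frac_de_parents, "frac_de_parents", stage)
  check_prob(frac_nonadditive, "frac_nonadditive", stage)
  if (de_log2_sd < 0 || na_log2_min < 0 || na_log2_rate <= 0) {
    fail(stage, "effect-scale parameters must be non-negative (rate positive)")
  }
  if (paternal_bias < -1 || paternal_bias > 1) fail(stage, "'paternal_bias' must lie in [-1, 1]")
  if (dispersion < 0) fail(stage, "'dispersion' must be non-negative")
  cfg <- list(
    n_genes = as.integer(n_genes),
    length_bin_weights = as.numeric(length_bin_weights),
    library_sizes = stats::setNames(as.numeric(library_sizes), LIBS),
    frac_specific = stats::setNames(as.numeric(frac_specific), LIBS),
    frac_de_parents = frac_de_parents,
    de_log2_sd = de_log2_sd,
    frac_nonadditive = frac_nonadditive,
    na_log2_min = na_log2_min,
    na_log2_rate = na_log2_rate,
    paternal_bias = paternal_bias,
    dispersion = dispersion,
    base_meanlog = base_meanlog,
    base_sdlog = base_sdlog,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  cfg
}

# three named substreams off the master seed (kept below 2^31)
sub_seed <- function(config, stream = c("catalog", "truth", "counts")) {
  off <- c(catalog = 101L, truth = 202L, counts = 303L)[[match.arg(stream)]]
  (config$seed + off) %% .Machine$integer.max
}

#' Generate a gene catalog
#'
#' Draws gene lengths per the configured five-bin distribution: a bin is
#' chosen by the bin weights, the length is uniform within finite bins, and
#' the open-ended `>=2000` bin uses a shifted geometric tail (2000 + Geom with
#' mean 1000 bp).
#'
#' @param config a [simulation_config()].
#' @return data.frame with columns `gene_id`, `length_bp`.
#' @export
generate_catalog <- function(config) {
  if (!inherits(config, "simulation_config")) fail("generate_catalog", "need a simulation_config")
  set.seed(sub_seed(config, "catalog"))
  n <- config$n_genes
  bin <- sample.int(5L, n, replace = TRUE, prob = config$length_bin_weights)
  len <- integer(n)
  for (b in 1:4) {
    idx <- which(bin == b)
    if (length(idx)) {
      len[idx] <- LENGTH_BIN_LOWER[b] +
        floor(stats::runif(length(idx)) * (LENGTH_BIN_LOWER[b + 1] - LENGTH_BIN_LOWER[b]))
    }
  }
  idx <- which(bin == 5L)
  if (length(idx)) len[idx] <- 2000L + stats::rgeom(length(idx), prob = 1 / 1000)
  data.frame(
    gene_id = sprintf("gene%06d", seq_len(n)),
    length_bp = as.integer(len),
    stringsAsFactors = FALSE
  )
}

#' Generate ground-truth expression means and labels
#'
#' Baseline rates are lognormal; with probability `frac_de_parents` a signed
#' Normal(0, `de_log2_sd`) log2 shift separates the parents symmetrically
#' about the baseline. The hybrid mean is the arithmetic midpoint of the
#' parental means unless the gene is nonadditive, in which case it is shifted
#' by a signed log2 deviation of magnitude at least `na_log2_min`;
#' `paternal_bias` skews the deviation direction away from parent A (toward
#' B). Library-specific genes get a true-zero mean in the other two
#' libraries. The `nonadditive` label records whether the final hybrid mean
#' differs from the final parental midpoint (so a gene silenced in one
#' library by the specificity draw can be nonadditive by construction).
#'
#' True differential expression versus a parent (`de_vs_A`, `de_vs_B`) means
#' the true hybrid/parent ratio is at least two-fold in either direction;
#' `pattern_group` combines the two effect signs (1 = down/down,
#' 2 = down vs A/up vs B, 3 = up vs A/down vs B, 4 = up/up) for genes that
#' are true DE against at least one parent, else `"none"`.
#'
#' @param catalog data.frame from [generate_catalog()].
#' @param config a [simulation_config()].
#' @return data.frame (one row per gene) with true means `mu_A`, `mu_B`,
#'   `mu_C` (RPKM-scale rates), `specific_to`, signed effects, DE and
#'   nonadditivity labels and `pattern_group`.
#' @export
generate_truth <- function(catalog, config) {
  if (!inherits(config, "simulation_config")) fail("generate_truth", "need a simulation_config")
  set.seed(sub_seed(config, "truth"))
  n <- nrow(catalog)

  base <- stats::rlnorm(n, meanlog = config$base_meanlog, sdlog = config$base_sdlog)
  de <- stats::runif(n) < config$frac_de_parents
  e <- ifelse(de, stats::rnorm(n, 0, config$de_log2_sd), 0)
  mu_A <- base * 2^(e / 2)
  mu_B <- base * 2^(-e / 2)

  nonadd_draw <- stats::runif(n) < config$frac_nonadditive
  mag <- config$na_log2_min + stats::rexp(n, rate = config$na_log2_rate)
  toward_B <- stats::runif(n) < (1 + config$paternal_bias) / 2
  # moving toward B is moving away from the paternal parent A
  base_sign <- ifelse(mu_B > mu_A, 1, ifelse(mu_B < mu_A, -1,
                                             sample(c(-1, 1), n, replace = TRUE)))
  delta <- ifelse(nonadd_draw, ifelse(toward_B, base_sign, -base_sign) * mag, 0)
  mu_C <- (mu_A + mu_B) / 2 * 2^delta

  # library-specific genes: silent in the other two libraries
  u <- stats::runif(n)
  p <- config$frac_specific
  specific_to <- rep("none", n)
  specific_to[u < p["A"]] <- "A"
  specific_to[u >= p["A"] & u < p["A"] + p["B"]] <- "B"
  specific_to[u >= p["A"] + p["B"] & u < sum(p)] <- "C"
  mu_A[specific_to %in% c("B", "C")] <- 0
  mu_B[specific_to %in% c("A", "C")] <- 0
  mu_C[specific_to %in% c("A", "B")] <- 0

  mpv <- (mu_A + mu_B) / 2
  nonadditive <- mu_C != mpv
  na_log2_dev <- ifelse(nonadditive,
                        ifelse(mu_C == 0, -Inf,
                               ifelse(mpv == 0, Inf, log2(mu_C / mpv))),
                        0)

  eff <- function(mu_ref) {
    ifelse(mu_ref == 0 & mu_C == 0, 0,
           ifelse(mu_ref == 0, Inf, ifelse(mu_C == 0, -Inf, log2(mu_C / mu_ref))))
  }
  eff_A <- eff(mu_A)
  eff_B <- eff(mu_B)
  de_vs_A <- abs(eff_A) >= 1
  de_vs_B <- abs(eff_B) >= 1

  grp <- rep("none", n)
  any_de <- de_vs_A | de_vs_B
  up_A <- eff_A > 0
  up_B <- eff_B > 0
  grp[any_de & !up_A & !up_B] <- "1"
  grp[any_de & !up_A & up_B] <- "2"
  grp[any_de & up_A & !up_B] <- "3"
  grp[any_de & up_A & up_B] <- "4"

  data.frame(
    gene_id = catalog$gene_id,
    mu_A = mu_A, mu_B = mu_B, mu_C = mu_C,
    specific_to = specific_to,
    de_vs_A = de_vs_A, eff_vs_A = eff_A,
    de_vs_B = de_vs_B, eff_vs_B = eff_B,
    nonadditive = nonadditive, na_log2_dev = na_log2_dev,
    pattern_group = grp,
    stringsAsFactors = FALSE
  )
}

#' Expected per-gene counts under a configuration
#'
#' A gene's expected count in a library is proportional to its true rate
#' times its length in kb, normalized so the library's expected total equals
#' the configured assigned-read total:
#' `E[count_iL] = rate_iL * len_kb_i / sum_j(rate_jL * len_kb_j) * N_L`.
#'
#' @param truth data.frame from [generate_truth()].
#' @param catalog data.frame from [generate_catalog()].
#' @param config a [simulation_config()].
#' @return numeric matrix, one column per library (A, B, C).
#' @export
expected_counts <- function(truth, catalog, config) {
  len_kb <- catalog$length_bp / 1000
  out <- sapply(LIBS, function(l) {
    raw <- truth[[paste0("mu_", l)]] * len_kb
    tot <- sum(raw)
    if (tot == 0) raw else raw / tot * config$library_sizes[[l]]
  })
  colnames(out) <- LIBS
  out
}

#' Sample a three-library count matrix from the truth
#'
#' Per-gene counts are negative-binomial with mean given by
#' [expected_counts()] (proportional to `rate * length_kb * library_size`,
#' normalized so each library's expected total matches its configured
#' assigned-read total) and variance `m + dispersion * m^2`;
#' `dispersion = 0` degenerates to Poisson. Realized per-library totals
#' (column sums) are attached as the `library_sizes` attribute, so RPKM is
#' computed against what was actually "sequenced".
#'
#' @param truth data.frame from [generate_truth()].
#' @param catalog data.frame from [generate_catalog()].
#' @param config a [simulation_config()].
#' @return data.frame `gene_id`, `length_bp`, `count_A`, `count_B`, `count_C`
#'   with attribute `library_sizes` (realized totals).
#' @export
sample_counts <- function(truth, catalog, config) {
  if (!inherits(config, "simulation_config")) fail("sample_counts", "need a simulation_config")
  set.seed(sub_seed(config, "counts"))
  means <- expected_counts(truth, catalog, config)
  out <- data.frame(gene_id = catalog$gene_id, length_bp = catalog$length_bp,
                    stringsAsFactors = FALSE)
  for (l in LIBS) {
    m <- means[, l]
    if (any(m < 0)) fail("sample_counts", "negative expected count")
    if (any(m > 2^31)) fail("sample_counts", "expected count overflows integer range")
    cnt <- if (config$dispersion == 0) {
      stats::rpois(length(m), m)
    } else {
      stats::rnbinom(length(m), mu = m, size = 1 / config$dispersion)
    }
    out[[paste0("count_", l)]] <- as.integer(cnt)
  }
  attr(out, "library_sizes") <- vapply(LIBS, function(l) sum(out[[paste0("count_", l)]]),
                                       numeric(1))
  out
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running catalog, truth and count generation; optionally
#' writes the standard TSV bundle plus a YAML echo of the configuration.
#'
#' @param config a [simulation_config()].
#' @param dir optional output directory for `counts.tsv`, `truth.tsv`,
#'   `config.yaml`.
#' @return list with elements `catalog`, `truth`, `counts`, `config`.
#' @export
simulate_dataset <- function(config = simulation_config(), dir = NULL) {
  catalog <- generate_catalog(config)
  truth <- generate_truth(catalog, config)
  counts <- sample_counts(truth, catalog, config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.table(counts, file.path(dir, "counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  }
  list(catalog = catalog, truth = truth, counts = counts, config = config)
}
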