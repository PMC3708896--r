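---
title: "Methods: three-library transcriptome comparison for allopolyploids"
author: "trioseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-library transcriptome comparison for allopolyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioseq)
```

## The design this package analyzes

An allopolyploid hybrid merges the genomes of two parental species. When its
transcriptome and those of both parents are sequenced against a common
reference, three per-gene read-count libraries result: A (paternal parent),
B (maternal parent) and C (the hybrid). `trioseq` answers the questions such
a trio raises: which genes are expressed where; which differ between the
hybrid and each parent; which deviate from the *midparent value* (the
additive expectation); in which direction the hybrid's expression moved; and
whether sequencing went deep enough.

The design has no biological replicates — each library is a single pool —
which constrains every statistical choice below. This mirrors the classic
single-library RNA-Seq comparisons the pipeline was built for.

## Normalization and detection

Expression is normalized as RPKM (reads per kilobase of exon model per
million assigned reads):

$$\mathrm{RPKM}_{iL} = \frac{x_{iL}}{(\ell_i/1000)\,(N_L/10^6)},$$

with $x_{iL}$ the read count of gene $i$ in library $L$, $\ell_i$ the gene
length in bp and $N_L$ the library's assigned-read total. A gene is called
*expressed* in a library when its count reaches `min_count` (default 1 read;
the threshold is exposed because no universally agreed detection rule
exists). Expressed-gene flags feed a three-set Venn partition whose
per-library totals and grand total are derived purely by summation, so they
are conserved by construction.

Saturation analysis subsamples reads without replacement at a grid of
depths (an exact multivariate hypergeometric draw, implemented by mapping a
uniform sample of read positions to genes). Each depth's sample is a prefix
of the deepest one, so every replicate's detection curve is monotone, not
merely monotone in expectation. The saturation depth is the first grid point
after which the marginal gain falls below 0.5% of the detected total per
additional million reads (tunable).

## The exact test

With one library per condition, the only information about a gene is its
count pair $(x, y)$ and the library totals $(N_1, N_2)$. Under equal
underlying expression, the probability of the second count given the first
is

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{\!y}
  \frac{(x+y)!}{x!\,y!\,\left(1 + N_2/N_1\right)^{x+y+1}},$$

a negative-binomial law in $y$ with size $x+1$ and success probability
$N_1/(N_1+N_2)$ — the Audic–Claverie statistic for digital expression data.
The two-sided p-value doubles the smaller inclusive tail,
$p = \min\!\big(1,\ 2\min(P(Y \le y \mid x),\, P(Y \ge y \mid x))\big)$.

Numerical notes:

* All factorials go through `lgamma`, so counts of order $10^5$ neither
  overflow nor lose precision.
* The tail away from the distribution's bulk is summed term by term; the
  other tail is recovered from $P(Y\le y) + P(Y\ge y) = 1 + p(y\mid x)$.
  Both tails are clamped to $[p(y\mid x), 1]$.
* Because the tails are inclusive and the law conditions on $x$, swapping
  the roles of the two libraries changes the p-value by at most one point
  mass of the pmf. The two orientations agree asymptotically but not
  exactly at small counts; the tests assert the discreteness bound rather
  than exact symmetry.
* For extremely separated pairs the true p-value underflows double
  precision and 0 is returned; no decision in the pipeline depends on
  distinguishing p-values below ~1e-300.

Multiple testing uses the Benjamini–Hochberg step-up adjustment
(`stats::p.adjust`), applied separately within each comparison's tested
universe — never pooled across comparisons, since the universes differ.

## DEG calling

For each hybrid-versus-parent comparison, the tested universe is every gene
expressed in at least one library of the pair. Fold change is computed on
RPKM (so unequal depths cannot masquerade as differential expression), with
zero RPKM floored at `epsilon` (default 0.001 RPKM) to keep ratios finite;
`log2fc` is hybrid over parent, and `direction` is "up" exactly when
`log2fc > 0`. A gene is a DEG when `fold_change >= 2` and `fdr <= 0.001`
(both tunable). The summed fold change of a DEG set is reported with two
switchable definitions — the sum of the $\ge 1$ fold changes (default) or
the sum of $|\mathrm{log_2 fc}|$ — because presence/absence genes floored at
`epsilon` dominate the former on data with true zeros.

## Midparent nonadditivity

The midparent value of a gene is the average of its parental RPKMs,
$\mathrm{MPV}_i = (\mathrm{RPKM}_{iA} + \mathrm{RPKM}_{iB})/2$ — the
expression an exactly additive hybrid would show. The exact test needs
counts, so the MPV is back-projected onto a pseudo-library with total
$\mathrm{round}((N_A+N_B)/2)$ and pseudo-count
$\mathrm{round}(\mathrm{MPV}_i \cdot \ell_i/1000 \cdot N_{\mathrm{MPV}}/10^6)$,
rounding half-up. The pseudo-library is then treated as an ordinary library
(no variance inflation), matching the replicate-free design. Genes with at
least a two-fold change against the MPV at FDR $\le 0.001$ are
*nonadditive*; all other tested genes are *additive*. Two deliberate
choices:

* MPV is defined on RPKM, not raw counts (the natural reading of
  "expression level"; raw-count averaging would weight parents by depth).
* The fold change is taken against the pseudo-count's *implied* RPKM, i.e.
  the same quantized value the test sees. A hybrid count equal to the
  pseudo-count therefore has fold change exactly 1; the difference from the
  raw-MPV ratio is below one part in twice the pseudo-count.

The nonadditive share is reported as a percentage of all detected genes,
rounded half-up to 3 decimals (all reported percentages round half away
from zero, matching how such tables are conventionally printed; base R's
round-half-to-even would disagree in edge cases).

## Expression patterns

Per-gene profiles are $(\log_2 C/A,\ \log_2 C/B)$ on floored RPKM. The
headline grouping is a sign rule: group 1 = down versus both parents,
group 2 = down versus A but up versus B, group 3 = the converse, group 4 =
up versus both; a ratio of exactly 1 counts as "down" so the four groups
partition deterministically. A gene gets a *group* when it is a DEG in at
least one comparison and additionally a *cluster* (equal to its group) when
significant in both.

Agglomerative average-linkage clustering with distance
$1 - \mathrm{Pearson}$ is provided for concordance. On length-2 profiles
Pearson correlation is degenerate — every defined value is $\pm 1$,
determined by the sign of the within-profile slope — so the dendrogram
separates slope classes, not quadrants, and the sign rule remains the
primary assignment. Constant profiles (zero variance) have no defined
correlation; distances involving them fall back to Euclidean distance
rescaled to $[0, 2]$, with a message. Ties in `hclust` resolve by input
order, so clustering is deterministic for a fixed gene order and invariant
as a partition under permutation.

## Parental bias

For each DEG (union of the two comparisons), the bias statistic is

$$d_i = \frac{|C_i - A_i|}{C_i} - \frac{|C_i - B_i|}{C_i}$$

on RPKM: the relative divergence from the paternal parent minus that from
the maternal parent, so $d > 0$ means expression moved further from the
paternal parent. $d$ is antisymmetric under swapping the parents. Genes
with zero hybrid RPKM are evaluated with $C$ floored at `epsilon` (flagged);
all-zero genes are excluded. Sign counts treat $|d| < 10^{-12}$ as zero so
"exactly zero" is well-defined in floating point; percentages round half-up
to whole percent. A positive-share majority, tested against binomial
sampling, recovers the direction of a simulated paternal bias.

## Category contrasts

Given an external gene-to-category annotation (never fetched — GO/KEGG
pipelines are out of scope), each category is tested with Fisher's exact
test on the 2x2 table (in-category vs not) x (nonadditive vs additive),
BH-adjusted across categories, with direction from the sample odds ratio.
Proportions, not raw counts, drive the comparison, since the two classes
have very different sizes.

## The synthetic-data generator

The simulator produces datasets with the structure the analysis assumes,
plus ground truth for calibration and recovery studies. Defaults describe a
full-size study and were fixed once:

| knob | default | emulates |
|---|---|---|
| `n_genes` | 32,642 | genes detected against the reference |
| `length_bin_weights` | .1546/.3071/.2541/.1362/.1480 | the observed five-bin length distribution |
| `library_sizes` | 8,594,083 / 5,479,383 / 6,267,830 | uniquely assigned reads per library |
| `frac_specific` | .0426/.0284/.0277 | library-specific genes in the expression Venn |
| `frac_de_parents`, `de_log2_sd` | 0.20, 1.5 | parental divergence (symmetric Normal log2 shift) |
| `frac_nonadditive`, `na_log2_min`, `na_log2_rate` | 0.08, 1, 2 | nonadditive deviations of at least `na_log2_min` log2 units (shifted-exponential magnitude) |
| `paternal_bias` | 0.25 | the observed positive/negative bias asymmetry |
| `dispersion` | 0.05 | mild overdispersion (NB; 0 = Poisson) |
| `base_meanlog`, `base_sdlog` | 1.0, 1.2 | lognormal baseline expression |

Structure: parental means sit symmetrically about a lognormal baseline,
$\mu_A = b\,2^{e/2}$, $\mu_B = b\,2^{-e/2}$; the hybrid mean is the
arithmetic midpoint unless nonadditive, in which case it is shifted by a
signed log2 deviation whose direction points away from the paternal parent
with probability $(1+\mathrm{paternal\_bias})/2$. Library-specific genes
get true-zero means elsewhere (true silence, not dropout). Expected counts
are proportional to $\mu \cdot \ell_\mathrm{kb}$, normalized per library so
the expected total equals the configured assigned-read total
(`expected_counts()` exposes the formula); counts are negative-binomial
with variance $m + \phi m^2$. One master seed drives three fixed substreams
(catalog / truth / counts) so stages regenerate independently.

Two semantic consequences worth knowing:

* The `nonadditive` truth label means "hybrid mean differs from the
  parental midpoint", evaluated *after* specificity silencing. A gene
  silenced in the hybrid but expressed in a parent is nonadditive by
  construction, so the realized nonadditive fraction exceeds
  `frac_nonadditive` when `frac_specific > 0` — at the defaults the called
  share is roughly double the drawn fraction. Real library-specific genes
  are mostly weakly expressed detection dropouts; the simulator's silenced
  genes can be strongly expressed, which overstates this route to
  nonadditivity relative to real data.
* A purely divergent additive gene (hybrid at the midpoint) can never be a
  two-fold DEG against the *higher* parent, since
  $(1 + 2^{-e})/2 > 1/2$ for every divergence $e$; both-comparison DEGs
  therefore come essentially from nonadditive genes, in the simulation as
  in the biology.

What passing recovery tests on these data do **not** show: robustness to
mapping artifacts, homoeolog cross-mapping between the merged genomes,
transcript-length biases within a gene, or dropout-style detection noise —
none of which the generator emulates.

## Calibration experiments and problem sizes

The test suite and the acceptance script run four standing experiments,
sized to give stable answers in seconds:

* **Type-I control** — 10,000 purely additive genes, Poisson sampling
  (`dispersion = 0`, no specific genes): the nonadditivity caller at
  FC $\ge 2$ / FDR $\le 0.001$ should produce at most 50 calls.
* **Recovery** — 5,000 genes, 10% nonadditive with deviations of at least
  2 log2 units, Poisson sampling, baseline raised (`base_meanlog = 3`) so a
  large subset clears expected counts of 100 in every library; recall and
  precision on that subset should reach 0.9, and sign-rule groups should
  match truth for at least 95% of recovered genes whose true effects exceed
  the two-fold threshold in both comparisons. Poisson sampling is the
  appropriate calibration model here because the exact test assumes it;
  with overdispersed counts any replicate-free exact test becomes
  anti-conservative, and precision at these thresholds degrades — a known
  limitation of the design, not of the implementation.
* **Bias direction** — 12,000 genes, `paternal_bias = +0.5`, default
  dispersion, sized to yield over 2,000 DEGs; the positive-$d$ majority
  should be binomially significant.
* **Saturation** — a constructed library (10,000 genes x 100 reads plus 30
  genes x 100,000) whose marginal detection gain drops below threshold just
  after 400,000 reads; the located plateau must land within one grid step.

## Known limitations

* No replicate-aware inference; biological variance is not modeled, so
  p-values describe sampling noise only.
* The epsilon floor makes fold changes of presence/absence genes
  arbitrarily large; the default summed-fold-change definition is dominated
  by them when true zeros exist (use `method = "log2"` for a bounded
  alternative).
* Hierarchical clustering on two-dimensional log-ratio profiles is
  degenerate under correlation distance, as noted above.
* BH adjustment is not idempotent (re-adjusting adjusted values inflates
  them); `bh_adjust` is a single-pass step-up procedure.
* Coverage fractions are accepted as input; computing them from alignments
  is out of scope, as are read mapping, annotation lookups and enrichment
  databases.
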