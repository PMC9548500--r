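---
title: "Methods: CNA-based clonality analysis for single-cell RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNA-based clonality analysis for single-cell RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalcna)
```

This vignette is the package's own account of the models and numerical
choices behind each stage, in the spirit of how differential-expression
and ordination packages document their methods: what is assumed, what is
tunable and why, what the synthetic-data generator does and does not
emulate, and where the design was genuinely open.

## The scientific problem

When a patient carries two (or more) tumors, treatment depends on whether
the lesions share a clonal origin (metastasis) or arose independently
(second primary). Somatic copy-number alterations (CNAs) are an
informative fingerprint: two lesions descended from one ancestral clone
inherit its chromosome-arm gains and losses, while independent tumors
accumulate different ones. From single-cell RNA-seq alone, CNAs can be
inferred because expression, averaged over enough adjacent genes, tracks
DNA copy number. The package implements that inference, a correlation
test of profile similarity with an explicit null, and the surrounding
analysis chain (QC, differential expression, gene-set
over-representation, single-site RNA-editing detection), each stage
exercised against a generator with known ground truth.

## Normalization and quality control

Expression is normalized per cell as `log(count / total * 10,000 + 1)`,
natural log by default. The log base is not dictated by the formula's
common printed form; we read `log` as natural log (the prevailing
convention for this normalization) and expose `log_base = "two"` for the
alternative. Zero counts map to exactly zero, so sparsity is preserved.

Cell-level filters follow the printed inequalities literally, with
boundary semantics as stated: detected genes in `[300, 3000]`
(inclusive), UMIs `>= 500`, mitochondrial fraction `< 0.2` (a cell at
exactly 0.2 is dropped), and mean normalized housekeeping expression
`> 0.8`. The housekeeping mean is computed on the normalized log scale —
the normalization formula precedes the housekeeping criterion, so that is
the scale the threshold refers to. The housekeeping list is an input
(`read_gene_list()`, one symbol per line, or the generator's `category`
flag); no list is shipped as authoritative because published lists vary.
Gene-level filtering (detected in `>= 10` kept cells) runs after cell
filtering; the order is a fixed convention of this package, consistent
with cell metrics being defined before gene metrics.

### Doublet detection

The detector follows the simulated-doublet nearest-neighbour scheme:
synthesize `round(2n)` artificial doublets by summing the raw counts of
uniformly sampled observed cell pairs; log-normalize everything jointly;
keep the `n_hvg = 1000` most variable genes (variance computed on
observed cells); fit PCA (`n_pcs = 20`) on observed cells and project the
simulated doublets into it; score each observed cell by the fraction `f`
of its `k` nearest neighbours that are simulated, rescaled by the
simulation prior `rho = n_sim / (n_sim + n)`:

```
score = f / (f + (1 - f) * rho / (1 - rho))
```

so 0.5 means "as doublet-like as a simulated doublet". The default
`k = round(0.5 * sqrt(n))` is a heuristic for a graph over the *n*
observed cells; because neighbours are searched among `n + n_sim`
points, `k` is scaled by `(1 + n_sim_ratio)` for the joint search
(`adjust_k_joint = TRUE`), the convention of the method family this
re-implements. Disable the flag to use `k` verbatim.

Two properties of this algorithm matter for interpreting scores.
*Homotypic* doublets (same class twice) are nearly indistinguishable from
singlets after normalization — worse, simulated homotypic doublets
average away noise and concentrate at the class centroid, so typical
singlets near a centroid acquire moderate scores. This is a property of
the scheme, not of the data: thresholds should be read off the score
histogram (the bundled example uses 0.75 rather than the nominal 0.5 for
exactly this reason), and detection claims are meaningful for
*heterotypic* doublets between separated classes. The detector's AUROC
on that task (two classes with strong marker programs, 10% true
doublets) is ≥ 0.9 in the acceptance tests.

## CNA inference

The inference is a deterministic pipeline over the normalized matrix,
with non-malignant cells (typically T and B cells) as the copy-neutral
reference:

1. drop genes with mean normalized expression over all included cells
   below `min_mean_expr = 0.1`;
2. center each gene on its reference-cell mean;
3. clip to `[-3, 3]` — limiting the leverage of highly expressed genes;
4. order genes by (chromosome, start; ties by gene id) and smooth each
   cell's vector within each chromosome with a `window = 101`-gene
   pyramidal moving average (weights `1, 2, ..., 51, ..., 2, 1`,
   renormalized; truncated and renormalized at chromosome edges —
   windows never cross chromosome boundaries, because CNAs are
   intra-chromosomal events);
5. subtract each cell's median across genes (removing per-cell baseline
   shifts the centering cannot);
6. re-center each gene on the post-step-5 reference mean, so reference
   cells average to exactly zero for every gene.

The parameter defaults are the established defaults of the
moving-average CNA method family; none is stated by the analyses this
reproduces, so all are configurable and recorded in the result object.
Two deliberate conventions: the gene-inclusion cutoff uses *normalized*
means (one scale throughout), and step 6 uses the reference mean computed
*after* the median correction, which makes "reference cells average to
exactly zero" an exact identity. A consequence worth knowing: a query
cell constructed as an exact copy of the per-gene reference mean comes
out exactly zero only when the reference cells' median residuals vanish;
otherwise it differs by the (vanishingly small) mean of those medians.

The smoother is implemented as two running sums over a zero-padded
vector — a triangular window is the convolution of two uniform windows —
divided by the same operator applied to a vector of ones. That gives the
truncated, renormalized edge behaviour exactly, in O(genes x cells), and
is verified to 1e-12 against a straight-line loop implementation in the
tests. Chromosome ordering is numeric-aware ("2" before "10", non-numeric
labels after), so results are invariant to input row order.

No hidden-Markov smoothing or subclustering post-processing is applied:
the downstream statistic is a correlation of mean profiles, which the
smoothed residuals already support, and leaving denoising off keeps the
algorithm fully specified. There is no integer copy-number calling or
ploidy estimation — profiles are relative expression residuals.

## The clonality test

Mean CNA profiles are computed per group (`mean_cna_profiles()`; one
group per tumor, or per tumor x malignant cluster — both groupings are
supported because published figures use both). Similarity is Pearson's
*r* over the common gene index. The null distribution is the set of
off-diagonal correlations among pairs of tumors designated unrelated:
both members must lie outside the tested set (pairs mixing a tested and
an untested tumor are excluded too), and designated related pairs (e.g.
known primary/metastasis pairs) are removed.

Two p-value recipes are implemented, and the result records which was
used:

* `empirical`: `p = (1 + #{null >= r_obs}) / (1 + N)` — assumption-free,
  granularity limited to `1/(N+1)`;
* `gaussian` (default): fit a normal to the null after Fisher's
  `z = atanh(r)` transform and report the upper tail at `z_obs`. The
  transform makes the null more nearly normal near |r| → 1, and a
  parametric tail can resolve p-values finer than the empirical
  fraction — which is why it is the default: reported p-values in this
  literature (e.g. 0.0017 against ~100 unrelated pairs) have finer
  granularity than an empirical rule can produce.

The test is one-sided, upper tail only: the scientific claim is "more
similar than unrelated tumors", never the reverse. Calibration is
checked in the tests: for mutually unrelated simulated tumors the
empirical p-value is approximately uniform (Kolmogorov–Smirnov distance
< 0.15 over 200 replicates), and a truly shared clone among unrelated
tumors is recovered with r > 0.8 and p < 0.05 in ≥ 95% of replicates.

## Differential expression and over-representation

Per gene, a two-sided Wilcoxon rank-sum test compares normalized
expression between two disjoint cell groups. For group sizes both
`<= exact_max_n = 10` the p-value is exact by full enumeration of the
`choose(n1 + n2, n1)` rank assignments (ties handled by enumerating the
observed midranks), with the two-sided rule `2 * min(P(W <= w),
P(W >= w))` capped at 1; larger groups use the normal approximation with
tie correction and continuity correction. Fold changes are computed on
the linear normalized scale with a pseudocount:
`log2FC = log2((mean_A + 1) / (mean_B + 1))` where `mean_X` averages
`exp(normalized) - 1` — the convention of mainstream single-cell
toolkits, consistent with fold changes reported to two decimals in this
literature. Genes are tested only when expressed in ≥ 10% of either
group and `|log2FC| >= 0.25` (both configurable; the display threshold
of 0.25 motivates the latter default). Bonferroni correction uses
`m =` the number of genes actually tested, the usual reporting
convention; `m` is attached to the result.

Over-representation takes a thresholded DE list (defaults: absolute
linear fold change > 1.8, adjusted p < 0.05; volcano figures often use
1.5 — both are plain arguments, nothing is hard-coded) and tests each
gene set by the upper-tail hypergeometric probability `P(X >= k)` with
the *tested* genes as the universe; q-values are Benjamini–Hochberg over
sets represented in the universe. Ranked-list (KS/NES permutation) GSEA
is deliberately out of scope: the input here is a thresholded list, for
which over-representation is the faithful analysis.

## RNA-editing detection

A single-base edit (C>U editing appears as C reference / T alternate in
cDNA) is called per cell from read-level records: reads below the
quality floor (`min_base_quality = 20`) or with base N are discarded;
reads are collapsed per (cell, UMI) to the majority base, ties
discarding the UMI — UMI consensus suppresses sequencing error and PCR
jackpots; a cell with no surviving UMI is *unobserved*, with
`>= min_alt_umis = 1` alternate UMIs *edited*, otherwise *unedited*.
Unobserved is never counted as unedited: summary fractions divide by
covered cells only, so sparse coverage does not deflate edited
fractions. One alternate UMI suffices by default because the analyses
this supports report per-cell presence/absence; raise the threshold for
stringency.

One subtlety: "raising `min_base_quality` can only reduce edited cells"
is *not* a theorem under majority collapse — removing a low-quality
reference read can flip a tied or reference-majority UMI to the
alternate base (e.g. a UMI with reads C@q10 and T@q30 is a discarded tie
at threshold 0, but becomes an alternate UMI at threshold 15). At
realistic within-UMI discordance rates (sequencing error ~1–2%) such
flips are vanishingly rare and the monotone behaviour holds, which is
how the tests exercise it; `min_alt_umis` monotonicity is unconditional.

`reads_from_bam()` (optional, requires Rsamtools) extracts the same read
table from a coordinate-sorted BAM at a 1-based position, CIGAR-aware,
taking barcode and UMI from the `CB`/`UB` tags.

## The synthetic-data generator

The generator is a stated world, deliberately minimal:

* per-gene baseline means are drawn once from a gamma distribution
  (shape 0.5 across genes — a long-tailed expression distribution) and
  shared by all samples;
* a cell of clone *k* has expected expression
  `baseline(g) x copy multiplier of the segment containing g (1 if
  none) x library-size factor`, library sizes log-normal per sample
  (defaults `meanlog = log(10,000)`, `sdlog = 0.3` — a typical 10x
  depth distribution);
* observed counts are negative binomial with one global dispersion
  (default 0.3, variance `mu + 0.3 mu^2`) — the standard minimal model
  for UMI counts, sufficient to exercise rank-based downstream
  statistics;
* CNAs act multiplicatively on expected expression — exactly the
  assumption under which expression-smoothing CNA inference works;
* housekeeping genes get a 30x baseline boost so typical singlets clear
  the `hk_mean > 0.8` criterion with room to spare; mitochondrial genes
  are scaled to an expected 5% of each cell's counts, comfortably below
  the 0.2 cap;
* doublets are additive in counts: two parents drawn independently
  (classes sampled uniformly, heterotypic when at least two classes
  exist), flagged in the truth table with both parent classes;
* optional class marker programs (`marker_genes_per_class`,
  `marker_boost`, default off): disjoint panels of ordinary genes
  boosted per class. Off by default so that, with no clone segments,
  malignant and reference classes are exchangeable in distribution — the
  generator's neutral case. Turned on when a scenario requires
  transcriptionally distinct cell types (doublet detection between
  "well-separated classes" is meaningless without them: real cell types
  differ by order-of-magnitude marker expression, which is what the
  boost emulates);
* editing reads: per cell `Poisson(coverage_mean)` reads grouped into
  molecules (~0.7 UMIs per read, giving PCR duplicates); a molecule in
  an edited (sample, class) stratum carries the alternate base with
  probability `edit_rate`; each read reports its molecule's base,
  flipped to the alternate with probability `error_rate` when the
  molecule is unedited. Editing is a molecule-level event — that is what
  makes per-cell alternate-UMI counts a well-defined ground truth
  (attached as the `umi_truth` attribute), and with `error_rate = 0`
  the caller's UMI-consensus calls agree with it exactly.

What the generator does **not** emulate — and therefore what a green
test does not establish robustness against: splicing structure, batch
effects, cell-cycle variation, ambient RNA / empty droplets, gene-gene
correlation beyond CNA segments and marker panels, chromosome-position
dependent expression trends, allele-specific effects. Results on real
data additionally depend on annotation quality and on how well the
chosen reference cells approximate copy-neutral expression.

Determinism: every stochastic entry point takes an explicit `seed`,
restores the caller's RNG state, and fixes every emitted byte; the
end-to-end pipeline run twice with one seed produces identical output
checksums (verified in the acceptance tests).

## Pipeline orchestration

`pipeline_config()` collects per-stage settings; `validate_config()`
schema-checks before any compute and reports *all* violations at once;
`run_pipeline()` executes simulate/load → QC → CNA → clonality → DE →
ORA → editing, writing TSV/MTX outputs plus `run_report.json` with
per-stage counts, seed and MD5 checksums, and halting with a
stage-named error on failure. Stages with a `NULL` config block are
skipped. The bundled `example_pipeline_config()` (five tumors, two
sharing a clone, editing active in one sample) runs end-to-end in a few
seconds and doubles as the acceptance-script workload. Its QC block
relaxes `min_genes`/`min_umi` to suit the small simulated gene panel and
sets the doublet threshold to 0.75 (see the doublet section); the
package-level defaults remain the printed thresholds.

## Known limitations

* CNA profiles are relative, smoothed expression residuals: no integer
  copy numbers, no ploidy, no whole-genome validation.
* The gaussian clonality p-value assumes the transformed null is
  adequately normal; with very few unrelated pairs the empirical rule's
  granularity is the honest limit.
* Wilcoxon DE assumes exchangeability within groups; no covariate
  adjustment (patient, batch) is available.
* The doublet detector cannot see homotypic doublets, and its absolute
  scores depend on the simulation prior; use the histogram, not the
  nominal 0.5, to set thresholds on real data.
* Editing detection targets one specified site; there is no genome-wide
  editing discovery and no germline-variant disambiguation.
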