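# clonalcna

Tools for asking a deceptively simple clinical question with single-cell
RNA-seq: when a patient presents with two tumors, is the second lesion a
metastasis of the first or an independent primary? The package answers it
the way head-and-neck cancer studies do — by inferring copy-number
alteration (CNA) profiles from expression, correlating tumors' mean CNA
profiles, and testing the observed similarity against an empirical null
built from unrelated tumor pairs — and bundles the surrounding single-cell
analysis chain so the whole workflow is reproducible end to end:

* **Quality control**: per-cell metrics (detected genes, UMIs,
  mitochondrial fraction, housekeeping expression) with the standard
  thresholds (genes ≥ 300 & ≤ 3000, UMIs ≥ 500, mitochondrial ratio
  < 0.2, housekeeping mean > 0.8, genes detected in < 10 cells removed),
  plus a simulated-doublet nearest-neighbour doublet detector.
* **CNA inference** from normalized expression, using immune cells (T/B
  cells) as the copy-neutral reference: reference-centering, clipping at
  ±3, a 101-gene pyramidal moving average within chromosomes, and median
  re-centering.
* **Clonality testing**: Pearson *r* between tumors' mean CNA profiles;
  one-sided p-values against the distribution of *r* among designated
  unrelated pairs, either empirically (plus-one rule) or from a normal
  fit on Fisher-z transformed null correlations.
* **Differential expression**: per-gene two-sided Wilcoxon rank-sum tests
  (exact by enumeration for tiny groups, tie- and continuity-corrected
  normal approximation otherwise) with Bonferroni correction and
  pseudocount fold changes.
* **Over-representation analysis** of thresholded DE gene lists against
  GMT gene-set collections (upper-tail hypergeometric, BH q-values).
* **RNA-editing detection** at a specified single base (e.g. the
  APOBEC3A-mediated DDOST 558C>U site) from read-level records, with
  UMI-majority consensus and per-(sample, class) edited-cell fractions.
* **A synthetic-data generator** — negative-binomial counts for
  multi-tumor datasets with known clone CNA segments, immune reference
  cells, doublets, mitochondrial/housekeeping genes and editing-site
  reads — so every stage is testable against ground truth without any
  external download.

## The statistics in brief

Expression is normalized as `log(count / total * 10,000 + 1)`. For cell
*j* and gene *g* (ordered by chromosome and position), the CNA score is

```
cna[g, j] = smooth_w( clip_c( x[g, j] - mean_ref(x[g, .]) ) ) - med_j - mean_ref(.)
```

with window *w* = 101 genes (pyramidal weights `1, 2, …, 51, …, 2, 1`,
truncated and renormalized at chromosome edges), clip *c* = 3, per-cell
median `med_j`, and a final per-gene re-centering on the reference cells.
Tumor pair similarity is Pearson's *r* between mean CNA profiles; under
the null hypothesis of unrelated tumors, `atanh(r)` for unrelated pairs
is fit with a normal distribution and the one-sided p-value is its upper
tail at the observed pair.

## Worked example

The bundled configuration simulates five tumors (~1,100 cells, 490
genes): `T1` and `T2` share a malignant clone (2× gain on chromosome 1,
loss of 3p-like segment on chromosome 3), `T3`–`T5` carry distinct
private clones, and the editing site is active only in `T3` epithelial
cells.

```r
library(clonalcna)

config <- example_pipeline_config("example_run", seed = 1)
report <- run_pipeline(config)
report[, c("stage", "status", "n_in", "n_out")]
#>   stage     status  n_in n_out
#> 1 simulate  ok      1135  1135
#> 2 qc        ok      1135  1066
#> 3 cna       ok      1066  1066
#> 4 clonality ok         5     1
#> 5 de        ok       343   180
#> 6 ora       ok         3     3
#> 7 editing   ok      5541  1061

readr::read_tsv("example_run/clonality_pvalues.tsv")
#>   pair      r         p_value      method
#> 1 T1|T2 0.9992482 7.817438e-59 gaussian_fisher_z
```

The shared-clone pair is detected with *r* ≈ 0.999 against a null of
unrelated pairs whose median *r* is ≈ 0.10, so the one-sided p-value is
vanishingly small: the two lesions share a clonal origin. The editing
summary shows the site called almost exclusively in `T3` epithelial
cells (edited fraction 0.88 of covered cells, versus ≤ 0.02 — sequencing
error level — everywhere else):

```r
readr::read_tsv("example_run/editing_summary.tsv")
#>   sample_id cell_class n_cells_total n_cells_covered n_cells_edited edited_fraction
#> 5 T3        Epi                  115             115            101      0.878
#> 6 T3        non-Epi               98              98              1      0.010
#> ...
```

Each stage can equally be driven directly: `simulate_tumor_counts()`,
`lognormalize()`, `cell_qc_metrics()` |> `apply_qc()`,
`infer_cna_matrix()` |> `mean_cna_profiles()` |> `test_clonality()`
(with `tidy()`, `glance()`, `autoplot()`), `wilcoxon_de()` |>
`ora_from_de()`, and `call_site_editing()` |> `summarize_editing()`.
See the methods vignette (`vignettes/cna-clonality-methods.Rmd`) for the
model, parameter and calibration details.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch — simulating the example
multi-tumor dataset with the given seed, then running QC, CNA inference,
the clonality test, differential expression, over-representation and
editing detection — checks that every stage completes, and writes the
result JSON to `--out`.
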