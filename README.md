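# plowbatch

Quality-aware batch effect detection and correction for RNA-seq.

Public expression datasets rarely document their processing batches, yet
batch effects confound clustering and differential expression. Batch
membership often leaves a fingerprint in *sample quality*: given a
per-sample probability of being low quality (`p_low`, produced upstream by
a quality classifier over FASTQ-derived features and supplied here as a
metadata column), this package

* **detects** batches from quality — a tie-corrected Kruskal–Wallis rank
  test of `p_low` across batches,

  H = [12/(N(N+1)) · Σⱼ Rⱼ²/nⱼ − 3(N+1)] / (1 − ΣT/(N³−N)),

  plus a **design bias** statistic, (γ+1)/2 for the Pearson gamma of
  |Δp_low| against the different-group indicator, which warns when quality
  aligns with biology and correction would remove signal;
* **corrects** expression data by confounder-adjusted PCA — the leading
  eigenvectors of Xᵀ(I − λK)X with kernel K = YYᵀ (trace-normalized) built
  from `p_low`, the known batch labels, or both, with the penalty weight λ
  chosen as the smallest grid value making every component nearly
  orthogonal to the confounder — and removes quality outliers with a
  deterministic largest-gap rule on sorted `p_low`;
* **evaluates** corrections with cluster validation indices on the
  embedding (Pearson gamma, Dunn index, within/between distance ratio; the
  first two increase, the third decreases as clustering improves) and
  their deltas against the uncorrected PCA.

A negative-binomial simulator with quality-coupled batch artifacts makes
every stage testable without downloading data.

## Worked example

The package ships a small synthetic dataset (300 genes x 16 samples,
2 groups x 2 batches, batch effect coupled to quality):

```r
library(plowbatch)
counts  <- system.file("extdata", "synthetic_counts.tsv",  package = "plowbatch")
samples <- system.file("extdata", "synthetic_samples.tsv", package = "plowbatch")
summary <- run_pipeline(counts, samples, pipeline_config())
summary
#> dataset_summary: 300 genes x 16 samples
#> Quality-based batch detection
#>   Kruskal-Wallis H = 11.29 (df = 1), p = 0.000778
#>   design bias (p_low vs group) = 0.480
#>   mean p_low per batch:
#>     b1: 0.234 (n = 8)
#>     b2: 0.623 (n = 8)
#> outlier_result (largest_gap): 0 outlier(s)
#> metric deltas vs uncorrected (gamma-ranked):
#>            variant delta_pearson_gamma delta_dunn1 delta_wb_ratio n_samples
#> 1            batch           0.2463562  -0.0134072     -0.2189469        16
#> 2 batch_no_outlier           0.2463562  -0.0134072     -0.2189469        16
#> 3             plow           0.2002803  -0.1460131     -0.1775757        16
#> 4  plow_no_outlier           0.2002803  -0.1460131     -0.1775757        16
#> 5             both           0.1433252  -0.1727164     -0.1035579        16
#> 6  both_no_outlier           0.1433252  -0.1727164     -0.1035579        16
```

Reading the output: the batches differ sharply in quality (mean `p_low`
0.23 vs 0.62; Kruskal–Wallis p ≈ 8e-4), while design bias ≈ 0.48 (near the
uninformative 0.5) says quality does *not* align with the biological
groups — so quality-based correction is safe to try. No quality outliers
were found, so the `_no_outlier` variants equal their counterparts.
Correcting with `p_low` alone improves group clustering almost as much as
correcting with the true batch labels (gamma +0.200 vs +0.246, within/
between ratio −0.178 vs −0.219): here, quality is a usable stand-in for
the unknown batch.

The same workflow is scriptable from a shell via the bundled CLI:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "plowbatch.R", package = "plowbatch"))')
Rscript $CLI simulate --seed 5 --out-prefix sim_
Rscript $CLI detect   --samples sim_samples.tsv --out report.json
Rscript $CLI run      --counts sim_counts.tsv --samples sim_samples.tsv --out-dir out/
```

See `vignettes/quality-aware-batch-correction.Rmd` for the statistical
model, parameter meanings and known limitations.

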