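---
title: "Quality-aware batch effect detection and correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-aware batch effect detection and correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plowbatch)
```

## The problem

Batches — samples processed together by one handler, on one run date, with
one reagent lot — leave systematic, non-biological fingerprints in RNA-seq
data. When batch labels are recorded, correcting for them is routine; in
public datasets they are often missing or unreliable. The premise of this
package is that batch membership frequently leaks into *measurable sample
quality*: a per-sample probability of being low quality, `p_low`, produced
upstream by a quality classifier (for example a random-forest model over
FASTQ-derived features), can stand in for the unknown batch label. The
package takes a gene-by-sample count matrix and a metadata table with
`group`, `batch` (when known) and `p_low`, and provides:

1. **Detection** — are the batches distinguishable by quality? A
   tie-corrected Kruskal–Wallis rank test of `p_low` across batches, plus a
   *design bias* statistic warning when quality aligns with the biological
   groups themselves.
2. **Correction** — confounder-adjusted PCA with `p_low`, the batch label,
   or both as confounders, plus a deterministic quality-outlier filter.
3. **Evaluation** — three cluster validation indices (Pearson gamma, Dunn
   index, within/between distance ratio) computed on the corrected
   embedding with the biological groups as clusters, and their deltas
   against the uncorrected embedding.

## Detection statistics

**Kruskal–Wallis.** With midranks for ties, rank sums $R_j$ over $n_j$
observations per batch and $N$ samples total,

$$H = \frac{\frac{12}{N(N+1)} \sum_j R_j^2/n_j - 3(N+1)}
          {1 - \sum_t (t^3 - t)/(N^3 - N)},$$

with $p$ from the $\chi^2$ upper tail at $k-1$ degrees of freedom. The
chi-square approximation is used throughout because realistic datasets have
tens of samples; an exact permutation p-value (full enumeration of distinct
label assignments) is available via `p_method = "permutation"` for ten or
fewer samples. Note that at such sizes the chi-square tail can differ from
the discrete permutation tail by well over 0.05 in absolute terms — the
approximation is a convenience at scale, not a small-sample tool. A constant
`p_low` vector returns $H = 0$, $p = 1$ ("no detection") by contract rather
than erroring mid-pipeline.

**Design bias.** Pearson gamma — the correlation between the pairwise
distance vector and the 0/1 different-cluster indicator — computed on the
one-dimensional distances $|p^{low}_i - p^{low}_j|$ against the
different-*group* indicator, then rescaled to $[0, 1]$ as $(\gamma+1)/2$.
Values well above 0.5 mean samples cluster by quality along group lines, so
a quality-based correction risks removing biological signal. The distance on
`p_low` is the absolute difference (plain 1-D Euclidean); no rescaling of
`p_low` is applied since gamma is correlation-based and therefore invariant
to affine changes of the distance scale. Constant `p_low` returns 0.5
(no information).

## Confounder-adjusted PCA

Standard PCA extracts the leading eigenvectors of $X^\top X$ for the
column-centered samples-by-genes matrix $X$. Given a confounder design $Y$
(samples x q: a centered one-hot batch block, a standardized `p_low` column,
or both side by side — optionally extended with externally computed
surrogate variables), the adjusted PCA penalizes variance lying along the
kernel $K = YY^\top$, trace-normalized to $n$, and solves

$$\max_{v^\top v = 1}\; v^\top X^\top (I - \lambda K)\, X v.$$

With $\lambda = 0$ this is exactly PCA. When there are more genes than
samples the eigenproblem is solved in the $n$-dimensional sample space via
$G = XX^\top$ (with $S = \Lambda^{1/2} Q^\top (I-\lambda K) Q
\Lambda^{1/2}$ for $G = Q\Lambda Q^\top$), which reproduces the dense
gene-space spectrum to numerical precision; the tests assert agreement to
1e-8. Component signs are fixed so the largest-magnitude loading entry is
positive, making score files reproducible across platforms.

**Choosing the penalty weight.** `select_lambda()` walks an increasing grid
(default 0 to 20 in 41 steps) and returns the smallest value at which every
component's *penalty ratio* $r_i = (v_i^\top X^\top K X v_i)/(v_i^\top
X^\top X v_i)$ falls below a tolerance (default 0.05); if none qualifies it
returns the minimizer and flags non-convergence. Two consequences of the
trace-$n$ normalization are worth understanding:

* For a single standardized continuous confounder $y$, the kernel's one
  nonzero eigenvalue is $n$, so $r_i = n \cdot \mathrm{cor}^2(y, s_i)$ for
  component scores $s_i$. The ratio is *not* bounded by 1, and a tolerance
  of 0.05 demands $|\mathrm{cor}| \le \sqrt{0.05/n}$ — near-exact
  orthogonality. In practice the selected $\lambda$ therefore essentially
  projects the embedding off the confounder direction.
* Because chance correlations between a finite sample's `p_low` and any
  fixed direction scale like $1/\sqrt{n}$, correcting for an
  *uninformative* quality score is not a no-op: it removes one
  quasi-random sample-space direction, and with it whatever fraction of
  biological signal happens to lie along it. This is precisely the risk the
  design-bias statistic is meant to flag, and it is the reason quality
  correction should be preceded by detection.

**Combined correction** (batch *and* `p_low`) concatenates the two blocks
into one design before building the kernel. Sequential correction would be
order-dependent; the joint kernel is not.

## Quality outliers

The manual practice this automates is scanning a per-sample quality bar
plot for a sudden jump to high values. `detect_quality_outliers()` sorts
`p_low` ascending and finds the largest consecutive gap within the upper
half of the sorted values; if it reaches `min_gap` (default 0.3), every
sample above the gap is an outlier. Restricting the scan to the upper half
guarantees that a gap among good-quality samples never flags low-`p_low`
samples. Ties between equal gaps resolve to the highest cut (fewest samples
flagged). A fixed `p_low` threshold is available as an alternative, and an
explicit sample list can always be passed downstream, which is how a known
hand-curated removal would be reproduced.

## Cluster metrics

All three indices use Euclidean distances on the first `n_components`
(default 2) score columns, with biological groups as clusters:

* `pearson_gamma` — correlation of pairwise distances with the 0/1
  different-cluster indicator; higher is better.
* `dunn_index` — minimum between-cluster separation over maximum
  within-cluster diameter; a worst-case indicator (one scattered cluster
  drags it down). All-singleton clusterings return `Inf`; fully coincident
  points return 0.
* `wb_ratio` — mean within-cluster distance over mean between-cluster
  distance; lower is better.

Coincident embeddings make gamma undefined; it is reported as 0 with a
`degenerate` flag so JSON reports stay machine-readable. The indices are
sensitive to removing a large fraction of samples, so `metrics_delta()`
records the sample counts of both sides and `compare_corrections()` flags
variants whose n differs from the baseline; no further adjustment is
attempted. Whether to feed the metrics 2-D PCA coordinates or full
expression-space distances is a genuine choice; the package uses the
embedding coordinates, matching the visual assessment the indices are
meant to replace.

## Normalization and the differential-expression stage

Counts are normalized by median-of-ratios size factors (genes with any zero
count are excluded from the median; an all-zero-free gene is required) and
transformed as $\log_2(\mathrm{count}/s_j + \mathrm{pseudocount})$. This is
deliberately a light-weight transform: it shares the depth-correction step
with regularized-log transforms but performs no shrinkage, and no result in
this package depends on shrinkage behavior.

The differential-expression stage is a per-gene two-sided Wilcoxon rank-sum
test with Benjamini–Hochberg adjustment, counting genes below `de_alpha`
(default 0.05). It is a distribution-free *substitute* for a
negative-binomial GLM: DEG counts serve only as a soft indicator of whether
a correction recovers group signal, and are not comparable to counts from
model-based pipelines. For corrected variants the test runs on the
normalized values with the confounder design regressed out gene-wise
(regression residuals). A low-rank reconstruction from the adjusted
components was rejected for this purpose: a rank-2 matrix propagates group
separation into essentially every gene and saturates the DEG count.

## The simulator

`simulate_dataset()` draws negative-binomial counts (variance
$\mu + \phi\mu^2$, default dispersion $\phi = 0.1$) with lognormal per-gene
baselines around `baseline_mean` (default 100, log-sd 1 — giving
size-factor estimation a realistic dynamic range). Defaults describe a
2-group x 2-batch design with 10 samples per cell (40 samples x 2000
genes): 10% of genes carry a group effect of log2FC 1.5, a disjoint 10%
carry a batch effect of log2FC 2, `p_low` sits at 0.2 with Gaussian noise
(sd 0.05) and is shifted by +0.4 in the second batch, and the batch
perturbation of each sample scales with its `p_low` (`quality_coupling =
1`). Setting `quality_coupling = 0` and `plow_batch_shift = 0` yields the
opposite regime: a full-strength batch effect that quality knows nothing
about. `inject_outliers()` corrupts k random samples with gene-wise
lognormal noise and a +0.5 `p_low` shift.

What the simulator emulates: multiplicative group/batch structure on NB
counts, quality-coupled or quality-independent batch artifacts, and grossly
degraded outlier samples. What it does not: library-size confounding beyond
size factors, gene–gene correlation, count-level quality artifacts (GC
bias, degradation gradients), more than one artifact channel, or the
behavior of a real upstream quality classifier. Tests passing on simulated
data therefore demonstrate the mechanics of detection/correction, not
end-to-end performance on real archives.

How strongly quality couples to batch in real data is unknown dataset by
dataset; `quality_coupling` is a free simulator knob, not an estimate, and
the package's detection report is the tool for judging a real dataset.

## Numerical choices and degenerate inputs

* Eigenproblems use symmetric `eigen()` after explicit symmetrization;
  the row-space path drops eigenvalues below `1e-12` of the largest.
* `acpca` refuses matrices whose column means exceed `1e-6` of the data
  scale (centering is the caller's responsibility and is done once, at the
  module boundary).
* Constant `p_low`: detection returns no-detection values (H = 0, p = 1,
  design bias 0.5); the confounder builder errors, since a constant column
  cannot be standardized.
* All randomness flows through a single integer seed per simulation call
  (`withr::with_seed`); no global RNG state is disturbed.
* The on-disk orientation is genes x samples; statistics operate on
  samples x features, transposed exactly once at the boundary. Missing
  `p_low` values are a hard error for quality-based operations — silent
  imputation would corrupt the central statistic.

## Problem sizes used by the test suite

The packaged example dataset is 300 genes x 16 samples (simulator seed 7,
quality-coupled defaults), small enough to keep the repository light while
exercising every pipeline stage. Property tests run on random instances up
to n = 30 samples; replicated correction experiments use 50 simulations of
16 x 1000 (quality-coupled regime) and 40 x 2000 (quality-independent
regime). These sizes were chosen to make the full suite complete in well under a
minute on a laptop while keeping the statistical assertions well-powered.

## Known limitations

* `p_low` is an input; the package neither computes it nor validates that
  it came from a sensible classifier.
* Quality-based correction removes at most the quality direction(s); batch
  effects orthogonal to quality (e.g. biologically rooted artifacts)
  survive it by construction. The quality-independent simulation regime
  demonstrates this: the batch axis remains in the embedding after `p_low`
  correction.
* Conversely, when `p_low` happens to align with the biological groups
  (high design bias), correction removes signal. Check the detection
  report first.
* The cluster indices treat all group separations as desirable and cannot
  credit biologically expected similarity between distinct groups; such
  judgments remain manual, and the package exposes raw metrics only.
* DEG counts from the rank-test substitute are indicative, not comparable
  to negative-binomial GLM results.
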