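---
title: "Covariance-based decomposition of bulk RNA-seq: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariance-based decomposition of bulk RNA-seq: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`cscdecon` estimates the cell-type composition of bulk RNA-seq samples from
an annotated single-cell reference. Throughout, `G` is the number of genes
shared by the two datasets after filtering, `C` the number of cell types,
`J` the number of single-cell subjects and `I` the number of bulk samples.
All matrices are genes × columns, and all expression enters the model on
the counts-per-million (CPM) scale.

From the single-cell data we observe directly:

* the **reference profile** `Z` (G × C): mean CPM of each gene within each
  cell type, cells pooled across subjects;
* the **observed proportions** `P` (C × J): each subject's fraction of
  cells per type;
* the **pseudo-bulk** `Y = Z P` (G × J): the expression a bulk sample with
  subject j's composition would show if the platforms agreed.

A bulk sample's composition solves the simplex-constrained least-squares
problem `min ‖Z p − x‖²` with `p ≥ 0`, `Σp = 1` — a convex quadratic
program, solved exactly by a dual active-set method
(`quadprog::solve.QP`).

Because bulk and single-cell platforms differ systematically, the bulk
matrix is first transformed so its multivariate distribution matches the
pseudo-bulk's:

```
Xᵐ = Ȳ + √(J/(J+1)) · S_Y,s^{1/2} · S_X,s^{−1/2} · (X − X̄)
```

`S_Y` and `S_X` are the sample covariances of `Y` (divisor J) and `X`
(divisor I) — note the divisor-n convention, deliberately not the unbiased
n−1, so every moment in the package agrees with the same definition.
`√(J/(J+1))` deflates the single-cell-derived dispersion for the small
number of subjects. A gene-wise baseline (`mode = "univariate"`) applies
the same location–scale map per gene and ignores correlation; `mode =
"none"` skips the transform entirely (ablation, noiseless checks).

### Shrinkage

With G in the hundreds-to-thousands and J, I in the tens, both sample
covariances are singular, so each is replaced by its Ledoit–Wolf linear
shrinkage estimate `(1−ρ)S + ρνI`, `ν = trace(S)/G`, with the plug-in
intensity that minimizes the expected squared Frobenius loss, clipped to
[0, 1]. The estimate is positive-definite whenever the data are not all
zero, which is what makes `S_X,s^{−1/2}` well defined. The implementation
was verified against an independent implementation of the same estimator
(scikit-learn's) to ~1e-9 on fixed fixtures; those values are frozen in
the test suite.

Numerically, the shrunk covariance is `α·I + B Bᵀ` with `B` of rank ≤ n,
so powers ±1/2 are applied through an SVD of `B` in O(G·n²) without ever
forming the G × G matrix; the tests pin this factored route to the dense
eigendecomposition (`sym_root`, `sym_inv_root`) on small inputs. The
symmetric root is used (not Cholesky): it is the unique SPD root, so
results do not depend on variable ordering. `S_Y,s^{1/2} S_X,s^{−1/2}` is
applied in that order and not symmetrized. A relative eigenvalue floor
(default 1e-8) guards inverse roots; with shrinkage active it is inactive.

### Marker genes

Using all common genes lets genes expressed in many types blur the
estimates, so the transform and solve run on cluster markers only. For
each gene and type, `pct_in` is the fraction of that type's cells
detecting the gene (count > 0, the standard percent-detected definition)
and `pct_out` the fraction among all other cells. A (gene, type) pair is
retained when `pct_in − pct_out ≥ threshold` (default 0.5; ties kept), and
genes retained for more than one type are dropped entirely, so marker sets
are disjoint. Two deliberate readings: the rule is directional
(`pct_in > pct_out`) — the absolute-difference form would admit
"anti-markers" detected everywhere *except* the cluster, contradicting the
idea of a marker; and the rule is applied to all genes rather than after a
hurdle-model DE screen, because the percentage rule is the only criterion
with an explicit formula. A Wilcoxon rank-sum/BH pre-filter
(`use_de_prefilter = TRUE`) is available for users who want a significance
screen first. A cell type left with no markers is an error, not a silent
drop: estimates for the remaining types would be biased by the missing
column, and closely related types sharing all markers is a real failure
mode the user should see.

### Pre-processing

`align_genes` intersects the gene sets and fixes a lexicographic order, so
all downstream matrices are deterministic and estimates are invariant to
input gene order (tested). `filter_genes` then removes zero-variance
single-cell genes, bulk-silent genes, and mitochondrial genes —
recognized by gene-id prefix (default `MT-`/`mt-`, case-insensitive,
configurable), since annotation-free data offer no better signal.
Filtering happens on counts, then both datasets are CPM-normalized: the
filters are scale-free (zero variance and all-zero rows survive
normalization unchanged), and normalizing after subsetting keeps each
column an honest distribution over the genes actually in play. All-zero
cells are warned about and tolerated; CPM leaves them zero.

## Tunable parameters

| Parameter | Default | Role |
|---|---|---|
| `threshold` | 0.5 | detection-difference cut for markers; smaller keeps more genes |
| `mito_prefixes` | `MT-`, `mt-` | mitochondrial gene recognition |
| `floor` | 1e-8 | relative eigenvalue floor in inverse roots |
| `mode` | multivariate | transform: multivariate / univariate / none |
| `use_de_prefilter` | FALSE | Wilcoxon+BH screen before the marker rule |

## The synthetic world

`simulate_single_cell` emulates the statistical structure the benchmark
depends on, not any particular simulator's internals:

* baseline gene means log-normal (meanlog 1, sdlog 1 — median ~3 counts,
  a realistic droplet-like depth at the default 10 000 genes);
* each gene differentially expressed in each type with probability
  `de_prob = 0.7`; multiplicative factors log-normal with location 3 and
  scale 1, inverted with probability 1/2;
* gene–gene co-expression via 10 gene blocks sharing a per-cell latent
  log-normal factor (sd 0.3, a moderate module-level correlation);
* per-cell library sizes log-normal (sd 0.2); counts negative binomial
  with BCV 0.3 (`size ≈ 11`);
* cells assigned uniformly to 8 subjects; each subject's type proportions
  are a uniform (Dirichlet(1)) simplex draw — the maximum-entropy reading
  of "random percentages".

Values not pinned by the benchmark configuration (co-expression strength,
library spread, BCV, baseline means, 8 subjects, 20 bulk samples) were
chosen once as field-typical and are not calibrated against any outcome.

Bulk samples come in three designs. `"subject"` (default) aggregates each
subject's cells — realized pseudo-bulk with count-level noise, the design
on which the univariate and multivariate transforms genuinely differ.
`"noiseless"` forms `Y = Z P` exactly; on this design the bulk *is* the
pseudo-bulk, the two shrunk covariances coincide and cancel, and the
univariate and multivariate transforms agree algebraically — useful as the
strictest noiseless benchmark but useless for ranking the two transforms.
`"fresh"` draws independent mixing proportions per bulk sample
(`simulate_bulk`, optional gamma noise); it is a much harder setting,
because the transforms re-center the bulk onto the mean of only J = 8
subject mixtures, and the resulting subject-sampling error dominates the
estimates. This hierarchy is worth knowing before trusting any single
benchmark number: the transform-based estimators assume the single-cell
subjects represent the bulk cohort's composition distribution.

What a green simulation test does **not** establish: robustness to
platform-specific gene biases (the very thing the transform exists for —
the simulator draws both datasets from one platform model), to
mis-annotated or missing cell types, to batch effects in the reference, or
to bulk cohorts whose composition distribution differs from the
single-cell subjects'.

## Numerical choices

* Covariance divisor n everywhere (moments, shrinkage intensity,
  transforms); mixing conventions between the moment and the intensity
  silently changes the shrinkage.
* Constant-column bulk is mapped to `Ȳ` directly (the transform's exact
  limit) rather than erroring inside the shrinkage estimator.
* Rank-deficient references: a 1e-10 ridge on the Gram matrix selects the
  minimum-norm solution among tied optima, with a warning naming the
  collinear types; estimates are renormalized onto the simplex after
  clipping solver-level negatives (≤ 1e-9).
* Per-iteration benchmark seeds are `seed + iteration − 1`, so mode
  comparisons share identical data and everything is reproducible
  bit-for-bit from the configuration.

## Known limitations

* The method inherits the reference-representativeness assumption: if the
  single-cell proportions are biased for the tissue, the transform pulls
  bulk estimates toward that bias.
* Marker selection with a hard 0.5 threshold can leave closely related
  types uncovered (an error by design); lowering the threshold trades
  specificity for coverage.
* With very few subjects (J ≤ 3) the pseudo-bulk covariance is estimated
  from almost no information and shrinkage drives the multivariate
  transform toward the univariate one.
* Pooled Spearman correlation over all (type, sample) entries is nearly 1
  whenever per-entry errors are small relative to the spread of the true
  proportions; it separates methods only when errors are large, so MSE and
  MAE are the more informative accuracy summaries on near-noiseless
  benchmarks.
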