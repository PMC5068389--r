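---
title: "Methods: unconditional mixture models for mixed-stock analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unconditional mixture models for mixed-stock analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otomix)
```

## The problem and the model

Juvenile fish from different nursery habitats (here, Mediterranean coastal
lagoons) record habitat-specific chemical fingerprints in their otoliths: a
vector of element:Ca ratios laid down during residence. When older fish from
these nurseries mix in the open sea, a sample of the mixed stock can be
modeled as a finite mixture,

$$f(x) = \sum_{k=1}^{K} p_k \, g(x;\, \mu_k, \Sigma_k),$$

with three groups of parameters: the number of contributing sources $K$, the
mixing proportions $p_k$ (the primary estimand), and the baseline nursery
signatures $\theta_k = (\mu_k, \Sigma_k)$, taken multivariate normal on $J$
standardized element:Ca ratios (the package default panel has $J = 7$: Li,
B, Mg, Rb, Sr, Y, Ba).

The *conditional* tradition fixes $\theta_k$ at values estimated from
juvenile (nursery-source) samples and estimates only $p_k$ from the mixed
stock. This fails whenever some nurseries were never found or sampled. The
approach implemented here is *unconditional*: the EM algorithm maximizes the
joint likelihood of the labeled nursery-source data and the unlabeled
mixed-stock data, so signatures of sampled ("known") sources are refined by
the mixed data, and signatures of unsampled ("unknown") sources are
estimated from the mixture alone. With $K_S$ of the $K$ sources sampled,
anything from fully supervised ($K_S = K$) to fully unsupervised
($K_S = 0$) estimation is the same model.

### Likelihood and EM updates

Labeled rows enter the likelihood through their own source's density;
unlabeled rows through the mixture density. In the E-step only mixed rows
receive responsibilities $z_{jk} \propto p_k\, g(y_j;\theta_k)$; labeled
rows have fixed unit membership. The M-step:

* $p_k$ is the mean responsibility over mixed rows **only**. Nursery
  sampling effort is set by design, not by stock composition, so labeled
  counts carry no information about the mixing proportions.
* $\mu_k, \Sigma_k$ are weighted moments of component $k$'s labeled rows
  (weight 1) plus all mixed rows (weight $z_{jk}$), with the ML ($1/n$-type)
  covariance. Setting `update_known = FALSE` in `em_controls()` freezes the
  sampled sources' signatures at their nursery-sample values, which gives a
  conditional-style fit; the unconditional update is the default.

Each M-step covariance passes through `regularize_cov()`: eigenvalues are
floored at `eig_floor` ($10^{-6}$) and, if needed, the smallest multiple of
the identity is added so that $\det\Sigma \ge$ `cov_det_floor` ($10^{-9}$).
A determinant bound of this form is the practical reading of the
positive-definiteness constraint on standardized data; the floors are
configurable and sit far below any realistically fitted volume, so they act
only on degenerate iterates (empty components, duplicated points).

Convergence is declared when the relative log-likelihood change drops below
`rel_tol` ($10^{-8}$), with `max_iter` = 1000. The log-likelihood trace is
stored; the monotonicity of EM is asserted in the test suite at tolerance
$10^{-9}$.

### Initialization

The starting point follows the stage order: (1) `init_known()` — per-source
sample means and covariances ($n-1$ denominator) from the labeled data;
sources with fewer than $J + 2$ rows fall back to the pooled within-source
covariance; (2) `seeded_kmeans()` — Lloyd iterations over the mixed data in
which the known sources' means are *fixed* centroids and $K_U = K - K_S$
*mobile* centroids are updated, best of `kmeans_restarts` (10) starts by
within-cluster sum of squares; (3) `init_unknown()` — sample moments of the
mobile clusters (pooled-covariance fallback for thin or empty clusters);
(4) `init_proportions()` — hard equal-prior density assignment of each
mixed row, zero counts floored at $1/(2n)$.

Mixture likelihoods are multimodal, and a single initialization chain
demonstrably lands in inferior local maxima: initializing the same data at
the generating parameters reached a higher log-likelihood in the majority
of trial fits. `fit_mixture()` therefore explores `em_restarts` (4)
independent initializations with short EM runs (`short_iter` = 30
iterations) whenever $K_U > 0$, and runs the best by log-likelihood to
convergence — the usual short-run strategy for mixture fitting. With
$K_U = 0$ the initialization is deterministic and a single chain is used.

### Number of sources

`estimate_k()` fits the ladder $K = \max(1, K_S), \dots, K_{\max}$ (default
8) and selects the minimum-BIC model, ties going to the smaller $K$
(parsimony). The lower end repairs the degenerate $K_S = 0$ case, where a
zero-component model is meaningless. BIC uses
$q = KJ + KJ(J+1)/2 + (K-1)$ free parameters and $n$ = all rows entering
the joint likelihood (labeled + mixed). AIC is available through the
`criterion` argument. Selection strength is summarized by the
median-minus-minimum criterion gap (`delta_bic`) across the ladder.

## The simulation framework

`run_scenario()` repeats, $R$ times per (cohort, $K_S$) cell: draw which
$K_S$ sources are "known"; parametric-bootstrap a nursery dataset (25
fish per known source) and a 100-fish mixed dataset whose composition is
**exact** — the proportion vector $\{0.1, 0.2, 0.3, 0.4\}$ is randomly
permuted across sources and $100\,p_k$ fish are drawn from source $k$ — so
the allocated proportions are the exact per-run truth that the bias
metrics assume (multinomial composition is available as an option); fit at
the true $K = 4$ (and optionally run model selection); match components to
sources; record. Every run derives deterministic child seeds from the
scenario seed, so any run is independently reproducible and the whole
experiment is a pure function of its configuration and one base seed.

### Metrics

With $m$ indexing the four proportion levels and $r$ the runs:

* $BI_{\hat p} = \sum_m \frac{1}{R}\sum_r |\hat p_{mr} - p_{mr}|$ — mean
  absolute error per level, summed; bounded in $[0, 2]$.
* $SE_{\hat p} = \frac{1}{M}\sum_m \sqrt{\frac{1}{R}\sum_r (\hat p_{mr} -
  p_{mr})^2}$ — taken literally from its defining equation, this is an
  RMSE about the truth (it includes bias), not a dispersion about the mean.
* $BI_{\hat\theta} = \frac{1}{JK}\sum_j\sum_k |\frac{1}{R}\sum_r
  (\hat\mu_{kr,j} - \mu_{k,j})|$ — the absolute value sits outside the run
  average, so this is systematic displacement only.
* $SE_{\hat\theta}$ — per source, the effective standard deviation
  $\det^{1/2J}$ of the covariance of $\hat\mu_{kr}$ across runs, averaged
  over sources.
* $BI_{\hat K} = \overline{\hat K} - K$; $SE_{\hat K}$ is the population
  standard deviation of $\hat K$ across runs — the dispersion of the
  estimator itself ($\hat K$ split evenly between 3 and 4 gives 0.5), not
  a $\mathrm{sd}/\sqrt{R}$ precision of its mean.

Label switching is resolved before any metric: components tagged with a
known source are pinned to it; the remaining components are assigned to the
remaining sources by minimum total squared distance between centroids
(exhaustive over the small assignment space). Runs whose fit fails are
dropped and counted; metrics use the effective $R$.

## The synthetic baselines, and the separation convention

`random_baseline()` generates $K$ positive-definite covariances (random
orthogonal eigenvectors, log-uniform eigenvalues over a 16-fold range,
rescaled so each source's effective standard deviation
$\det^{1/2J}$ sits near `spread`, default 0.5 with a ±15% jitter — the
observed per-source range is roughly 0.35–0.65), places centroids in random
directions, and rescales them about the unweighted grand centroid so the
average squared pairwise Mahalanobis separation hits the target exactly.
`make_virtual_cohort()` re-uses a baseline's covariances untouched and
rescales only the means, reproducing the virtual separation grid
$\{0.5, 1.5, \dots, 5.5\}$ to $10^{-10}$.

The reference metric of the separation index deserves a note, because
reported separation summaries in this literature rarely state it.
`average_separation()` defaults to the
pooled within-source covariance — the textbook convention, and the right
probe for real datasets — and accepts `"identity"` or any explicit matrix.
The *generators*, however, default to the identity convention: separations
are expressed on the unit scale of the standardized data, i.e. directly in
standard deviations. Two observations motivate this: the reported
separations are phrased in "standard deviations" of data standardized to
unit variance, and the reported within-source average squared distances
(about 2.5 at $J = 7$) are of the order $2\,\mathrm{tr}(\Sigma_k)$ expected
under a unit reference metric with per-source effective sd near 0.5,
whereas a pooled-covariance metric would put them near $2J = 14$. Under the
pooled convention the same nominal separations produce a far harder
estimation problem than the reported behavior of the method implies.

What the generator does **not** emulate: real covariance structure among
element ratios. Elements retained in otolith studies are selected *for*
discrimination, so real within-source variance is likely small along
between-centroid directions; random-orientation covariances have no such
alignment. Synthetic cells at low $K_S$ and low separation are therefore
plausibly *harder* than their real-data counterparts at the same nominal
separation, and the bias levels measured there should be read as
conservative upper bounds for data with favorable covariance geometry.
Passing tests demonstrate correctness of the estimator and the direction
and ordering of the bias responses, not the exact bias magnitudes of any
particular real dataset.

## Numerical choices and degenerate inputs

* Standardization uses the $n - 1$ sample sd; a zero-variance variable is a
  named error.
* Rescaling a set with coincident centroids, separations of singleton sets,
  and non-integral exact compositions ($n \cdot m_k$ not whole) are errors,
  not silent repairs.
* $K = 1$ fits use the pooled closed form (no iteration); labeled-only
  fits return per-source estimates with proportions flagged undefined.
* Empty mobile K-means clusters are re-seeded at the worst-fit point;
  empty components during EM keep their parameters for the iteration.
* Ties in hard assignment and in model selection go to the first (lowest)
  index — deterministic on re-runs.
* All defaults were chosen so results are insensitive to halving or
  doubling them; they are recorded in `em_controls()`.

## Problem sizes

The packaged experiments use the design sample sizes (25 fish per known
source, 100-fish mixed stocks, proportions 0.1/0.2/0.3/0.4) with 200
resampling runs per scenario cell for the bias metrics and 100 runs for
the model-selection experiment; the numbered analysis scripts default to
lighter replicate counts (30–50) suitable for interactive use and accept a
replicate count as an argument. Full-scale studies simply raise `R`.

## Known limitations

* Gaussian components only; no Box–Cox or other marginal normalization is
  provided — data are assumed already transformed and standardized.
* The number-of-sources estimator inherits the well-known underestimation
  of information-criterion selection in mixtures; treat the selected $K$
  as a lower bound (the analysis scripts quantify this).
* Bias in fitted covariance matrices is not assessed; signature metrics
  concern the mean vectors.
* Component matching is centroid-based; with grossly misplaced components
  the induced pairing (and hence the bias attribution to proportion
  levels) is itself an estimate.
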