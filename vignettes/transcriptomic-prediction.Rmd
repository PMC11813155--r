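---
title: "Transcriptome-based prediction of line-mean phenotypes: models and methods"
author: "transpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome-based prediction of line-mean phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transpred)
```

## The problem

Reference panels of fully inbred lines (flies, mice, plants) pair a
line-by-gene expression matrix with replicated phenotype measurements.
Because every line is measured on many individuals, the analyzed response
is a *line mean*, whose broad-sense heritability

\[
H^2_m = \frac{\sigma^2_G}{\sigma^2_G + \sigma^2_E / f}
\]

(with \(f\) individuals per line) is far higher than the individual-level
heritability — around 0.8 for typical panel traits. The statistical task is
to predict the line mean of a held-out line from its transcriptome. All
regression methods in this package share the linear model

\[
\mathbf{y} = \mathbf{X}\boldsymbol\beta + \mathbf{e},
\]

with \(\mathbf{y}\) the centered \(n\)-vector of line means and
\(\mathbf{X}\) the centered \(n \times m\) expression matrix,
\(m \gg n\). Methods differ in how they regularize \(\boldsymbol\beta\).

## The model panel

* **PCR / PLSR** (`fit_pcr`, `fit_plsr`) replace \(\mathbf{X}\) with
  \(k\) orthogonal score vectors — principal components (maximum variance)
  or partial-least-squares components (maximum covariance with
  \(\mathbf{y}\)). \(k\) is chosen by 5-fold cross-validation inside the
  training set, minimizing squared prediction error with ties broken
  toward smaller \(k\); \(k = 0\) (an intercept-only model) is an
  admissible winner and is flagged as a degenerate fit. PLSR uses the
  wide-kernel algorithm, which iterates on the \(n \times n\)
  cross-product matrix and never forms an \(m \times m\) object; a
  component whose score iteration does not settle within `max_iter`
  iterations (default 100, raisable to 500 for hard traits) marks the fit
  `converged = FALSE` — a recorded failure, not an exception.
* **Ridge / LASSO** (`fit_ridge`, `fit_lasso`) are the
  \(\ell_2\)/\(\ell_1\)-penalized fits, computed by the glmnet
  coordinate-descent path solver over 100 log-spaced penalties spanning
  four decades, with \(\lambda\) selected by the same 5-fold scheme
  (CV-minimum rule by default; the one-SE rule behind `rule = "1se"`).
  Predictors are standardized inside the solver and coefficients are
  returned on the original scale, which is what fixes the meaning of
  \(\lambda\). A LASSO solution with no active coefficients is an
  intercept-only model and is recorded as a failure.
* **BayesC / GO-BayesC** (`fit_bayesc`, `fit_go_bayesc`) place a
  spike-and-slab prior \(\beta_j \sim \pi N(0, \sigma^2_\beta) +
  (1-\pi)\,\delta_0\) on each effect and sample the posterior by Gibbs:
  indicator and effect jointly from the exact per-coordinate conditional,
  \(\pi\) from a beta conditional, variances from scaled-inverse-\(\chi^2\)
  conditionals. The two-group variant gives the genes of a selected GO
  term and the remaining genes independent \((\pi, \sigma^2_\beta)\)
  pairs; a term covering the whole universe collapses exactly to BayesC.
* **TBLUP / GO-TBLUP** (`fit_tblup`, `fit_go_tblup`) aggregate all genes
  into random effects \(\mathbf{t} \sim N(0, \mathbf{T}\sigma^2_t)\) with
  \(\mathbf{T} = \mathbf{W}\mathbf{W}'/m\) the transcriptomic relationship
  matrix over standardized expression \(\mathbf{W}\). The sampler runs in
  the eigenbasis of the training kernel (each sweep is \(O(n)\) after one
  eigendecomposition); test lines are predicted by the conditional
  expectation given the training effects through the kernel cross-block.
  The GO variant fits two kernels built from the in-term and out-of-term
  gene blocks and reports the posterior GO variance share
  \(\sigma^2_{t,GO}/(\sigma^2_{t,GO}+\sigma^2_{t,notGO})\).
* **VARBVS** (`fit_varbvs`) is the variational counterpart of BayesC:
  fully factorized coordinate-ascent approximation per hyperparameter
  state, over 20 prior-inclusion values log-spaced between \(1/m\) and
  \(1/2\); states are combined by importance weights proportional to
  \(\exp(\mathrm{ELBO})\). Slab and residual variances are re-estimated
  per state by their closed-form ELBO maximizers.
* **MR.ASH** (`fit_mrash`) generalizes the slab to a scale mixture of
  normals over a fixed variance grid, estimating the mixture weights from
  the data (empirical Bayes) by coordinate-ascent variational inference,
  optionally initialized from the LASSO solution.

Random-forest or neural-network style predictors are not reimplemented;
the evaluation harness accepts any function with the wrapper signature, so
off-the-shelf learners can be plugged in.

## Prior calibration

The Bayesian models need concrete hyperprior scales. Following standard
whole-genome-regression practice, `calibrate_priors()` derives them from a
single interpretable number: the expected proportion of phenotypic
variance explained by the predictors, \(R^2\), set to 0.8 by default to
match the broad-sense heritability of line means. The residual
scaled-inverse-\(\chi^2\) scale is set so its prior mode equals
\((1 - R^2)\,\mathrm{Var}(y)\); each variance component receives a share
of \(R^2\,\mathrm{Var}(y)\) (equal shares for the two GO components by
default, configurable), divided by \(\pi \sum_j \mathrm{Var}(x_j)\) for
effect components or by \(\mathrm{mean}(\mathrm{diag}\,\mathbf{T})\) for
kernel components. All inverse-\(\chi^2\) priors use 5 degrees of freedom
and \(\pi\) has a Beta(5, 5) hyperprior (prior count 10, mean 0.5).

Two numerical points deserve emphasis:

* **Chain initialization.** `fit_bayesc` starts its chain at
  \(\pi = 0.1\) (the `pi_init` argument), not at the hyperprior mean.
  Started dense, the slab variance calibrated at \(\pi = 0.5\) is so small
  that every gene can enter at negligible cost and the sampler settles
  into a ridge-like mode with hundreds of tiny effects from which the
  per-coordinate updates cannot escape in any practical number of sweeps.
  Started sparse, \(\pi\) climbs freely when the trait really is
  polygenic; on dense simulated traits the two starts agree, while on
  sparse traits only the sparse start finds the selective mode.
* **MCMC schedules.** Defaults are 130,000 iterations with 30,000 burn-in
  for the spike-and-slab samplers and 85,000 with 10,000 burn-in for the
  kernel samplers, thinned every 50th draw — 2,000 and 1,500 retained
  draws. `(n_iter - burn_in)` must be an exact multiple of `thin`.
  Visual trace inspection is replaced by automated diagnostics: effective
  sample size at least 100 and |Geweke z| at most 3 per variance
  component, reported in every fit and raised as a warning (never an
  error) when violated.

## Variational details

Both variational fits assert, on every iteration, that their objective
did not decrease beyond a \(10^{-8}\) relative tolerance — a decrease is a
hard error, because coordinate ascent guarantees monotonicity and a
violation means an update is wrong. Convergence is declared at relative
change below `tol` (default \(10^{-8}\)) or 1,000 outer iterations,
whichever comes first; runs that exhaust the iteration budget return
`converged = FALSE` but remain usable.

MR.ASH needs two guards that are easy to miss. First, the variance grid
(zero plus 19 geometric points) is floored at \(10^{-2}\) times the
largest univariate effect variance: components much smaller than that are
statistically indistinguishable from the point mass, and the weight split
between them would be arbitrary. Second, the weight update uses a
null-biased Dirichlet penalty — `null_bias = 10` extra prior counts on
the point mass, the adaptive-shrinkage convention — which makes the
reported \(\pi_0\) interpretable as a null weight instead of drifting
into near-zero slabs on null data. The reported `elbo_trace` is the
penalized objective that the updates actually ascend.

## Evaluation protocol

`make_splits(n, n_reps = 25, test_fraction = 0.1)` draws 25 random 90/10
partitions (test size `round(0.1 n)`, e.g. 20 of 198 lines), replicate
\(k\) seeded with `base_seed + k`. Every method in a comparison consumes
the *identical* plan; within a replicate each method derives its own RNG
stream from the replicate seed and the method name, so chains differ but
splits do not. Accuracy is the Pearson correlation between observed and
predicted phenotypes in the test set; a constant prediction (an
intercept-only model) has no defined correlation and is recorded as a
failure with its cause. Per method, `aggregate_accuracy()` reports the
mean and standard error of r over successful replicates only (SE = sample
SD divided by the square root of the number of successes), the failure
percentage, and an exclusion flag for methods failing more than 40% of
replicates in at least one stratum (e.g. one sex).

Centering conventions: regression methods center the training columns and
response, apply the training means to the test lines, and add the
training mean back to predictions. Kernel methods standardize the full
expression matrix once and condition on the training block of the kernel
— the usual practice for relationship-matrix models, where the kernel is
a property of the panel rather than of one split.

## The GO scan and gene analysis

`scan_terms()` fits the chosen GO-informed model once per retained term
(terms need at least 5 member genes in the expression universe,
`min_size` in `load_genesets()`), evaluating each under the shared split
plan; `select_top_terms()` ranks by mean r and keeps the top
\(\max(1, \lfloor 0.01 N \rfloor)\) terms — 26 of 2,628 and 25 of 2,580
with the published term universes — breaking ties by term id;
`gene_frequency()` counts how often each gene appears across the selected
terms and reports genes at or above a count threshold (default 4, the
histogram-chosen value; `count_threshold_elbow()` offers a 5%-tail
heuristic but is never applied silently).

## The synthetic panel generator

The generator exists so that every stage is testable without any external
dataset. It emulates the *shape* of panel data, not its biology:

* **Expression**: \(\mathbf{X} = \mathbf{L}\mathbf{F}'/\sqrt{k} +
  \mathbf{E}\) with standard-normal factors and loadings, so the \(k\)
  latent factors (default 10) carry half of each gene's expected
  variance. The \(1/\sqrt{k}\) scale matters: with unscaled loadings the
  factors would carry \(k/(k+1)\) — over 90% — of every gene's variance,
  leaving an effectively rank-\(k\) matrix on which sparse and dense
  architectures are indistinguishable (any kernel captures a
  10-dimensional signal). Half-shared variance is strong but
  non-degenerate co-expression.
* **Architectures**: `dense` (all genes causal), `sparse` (`n_causal`
  random genes), `go_enriched` (causal genes inside a designated term).
  Effects are Gaussian on the standardized expression scale, so the
  heritability calibration is architecture-independent.
* **Trait**: line-level residual noise is calibrated against the realized
  genetic variance so that \(\mathrm{Var}(g) / (\mathrm{Var}(g) +
  \sigma^2_{e,\mathrm{line}})\) equals the target \(H^2_m\) (default
  0.8); when \((\sigma^2_G, \sigma^2_E, f)\) are given explicitly the
  genetic values are rescaled to \(\sigma^2_G\) exactly and the noise is
  \(\sigma^2_E/f\). The realized heritability is recorded per dataset.
* **Sexes**: `simulate_sex_pair()` draws two independent expression
  matrices with effect vectors correlated at \(\rho\) across sexes
  (default 1, the low-dimorphism limit; lower values emulate dimorphic
  traits).
* **Gene sets**: random memberships with sizes in a given range,
  optionally one designated term containing all causal genes.

What the generator does **not** emulate: count-level noise and library
normalization (it produces already-processed line means), modular or
hierarchical co-expression (one global factor layer only), annotation
structure beyond flat membership, and any covariate adjustment
(infection status, inversions). Consequently, passing tests demonstrate
the estimators' statistical correctness under a controlled generative
model — not robustness to the preprocessing artifacts of real panels.

## Experiment sizes used in the checks

The package's own test suite runs its two large experiments at sizes
chosen to exercise the full pipeline: the method comparison at
\(n = 200\) lines, \(m = 2{,}000\) genes, 25 shared splits with Gibbs
schedules scaled to about 1,500 retained sweeps; the GO-scan recovery at
\(n = 150\), \(m = 1{,}000\), 100 terms, 3 evaluation replicates per
term, with independent genes (`n_factors = 0`) so that set membership —
not co-expression — drives term ranking. Oracle checks (exact
enumeration over \(2^5\) models, closed-form BLUP, soft thresholding,
kernel identities) run at their natural small sizes with the standard
full schedules.

## Numerical choices and degenerate inputs

* Zero-variance genes cannot be standardized; they are excluded with a
  warning and listed in `excluded_genes` (CV subsets can create them, so
  this is not an error).
* Kernel eigenvalues below \(10^{-8} \cdot \mathrm{tr}(\mathbf{T})/n\)
  are clipped to zero; conditioning uses the resulting pseudo-inverse.
  The GO kernels are each scaled by their own gene count, making
  \(m_{GO}\mathbf{T}_{GO} + m_{notGO}\mathbf{T}_{notGO} = m\mathbf{T}\)
  an exact identity; a global-\(m\) scaling differs only by a constant
  absorbed into the variance components, and the prior calibration uses
  \(\mathrm{mean}(\mathrm{diag}\,\mathbf{T})\), so predictions are
  unchanged.
* CV fold assignment shuffles indices once under the seed and deals five
  contiguous blocks; all CV ties break toward the smaller model.
* `align_lines()` errors on unmatched line ids unless told to drop them,
  so silent sample loss cannot occur.

## Known limitations

* The Gibbs samplers are single-chain; the diagnostics catch gross
  non-convergence but cannot prove mixing across well-separated modes.
* Variational PIPs are known to be overconfident under strong predictor
  correlation; the enumeration-oracle agreement is therefore only
  asserted on near-orthogonal designs.
* The GO scan refits every term independently; with thousands of terms
  and full schedules this is a compute-heavy (though embarrassingly
  parallel) computation.
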