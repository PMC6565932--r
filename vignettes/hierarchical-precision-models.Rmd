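---
title: "Hierarchical Bayesian models for multi-subject partial-correlation networks"
author: "hierprec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian models for multi-subject partial-correlation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hierprec)
```

## The problem

Functional connectivity studies record a multivariate time series per
subject — activations of $p$ regions of interest over $n_s$ time points —
and summarise each subject's network by a Gaussian graphical model: the
demeaned series $Y_s \in \mathbb{R}^{p \times n_s}$ is modelled as i.i.d.
draws from $N(0, \Omega_s^{-1})$, and the off-diagonal entries of the
precision matrix $\Omega_s$, normalised to partial correlations
$-\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}$, measure direct association
between regions. Inverting a sample covariance is noisy whenever $n_s$ is
not much larger than $p$, so practical estimators regularise, usually by
pushing weak entries towards zero. When many subjects are measured, one
can do better than regularising each subject separately: a hierarchical
model shares information across subjects, shrinking each individual's
connection strengths towards a group mean that is itself estimated, and
shrinking the group mean towards zero.

`hierprec` implements such a hierarchy with fully Bayesian block-Gibbs
inference, together with the baseline estimators and simulation designs
used to validate this model class.

## The model

The diagonal entries of each $\Omega_s$ get independent exponential priors
$\mathrm{Exp}(\omega_{ii}; \lambda_s/2)$ with a neutral Gamma hyperprior
$\lambda_s \sim \mathrm{Ga}(1/3, 0)$ (improper, used only through its
conjugate update — there is always ample information about inverse
variances). Each off-diagonal entry, for each subject, gets a spike-and-slab
prior shared across subjects:

$$
\begin{aligned}
\omega_{ij}^{(s)} \mid z_{ij}=1 &\sim N(\mu_{ij}, \sigma_{ij}^2), &
\omega_{ij}^{(s)} \mid z_{ij}=0 &\sim \delta_0,\\
\mu_{ij} &\sim N(0, \chi^2), &
\log \sigma_{ij} &\sim N(\log m_\sigma, s_\sigma^2),\\
\chi &\sim C^+(0, A), &
z_{ij} &\sim \mathrm{Bernoulli}(a), \quad a \sim \mathrm{Beta}(a_\pi, b_\pi).
\end{aligned}
$$

The pieces have clear roles: $\mu_{ij}$ is the group-level strength of the
edge, $\sigma_{ij}$ the between-subject spread of that edge, $\chi$ a global
scale that pools information about how large group strengths tend to be,
and $Z = (z_{ij})$ an explicit shared network: when $z_{ij}=0$ the edge is
absent in *every* subject. The **strong** model uses all of this; the
**weak** model fixes $a = 1$, $z_{ij} = 1$, keeping only continuous
shrinkage (the Cauchy scale still pulls group means towards zero). A
**single-subject** variant replaces the hierarchy by a fixed zero-centred
slab $N(0, 0.7^2)$ and is fitted to the concatenated panel. For
comparison, per-subject **Bayesian graphical lasso** (double-exponential
prior via its exponential scale mixture) and **SSVS** (two-component
normal mixture, $v_0 = 0.05$, $v_1 = 2.5$, $a = 0.5$) column samplers are
included in the same engine.

### Default constants

| constant | default | role |
|---|---|---|
| $m_\sigma$ | 0.5 | centre of the log-normal prior on between-subject scales |
| $s_\sigma$ | 1 | its log-scale sd (allows order-of-magnitude deviations) |
| $A$ | 0.7 | half-Cauchy scale for $\chi$; suited to variance-scaled data where partial correlations rarely exceed 0.7 |
| $a_\pi, b_\pi$ | 6, 6 | Beta prior on sparsity; most mass in (0.3, 0.7) |
| Gamma shape | 1/3 | neutral hyperprior for the diagonal rates |

All are overridable through `default_hyperconstants()` or a YAML/JSON
config (`read_config()`).

## Inference

Partitioning $\Omega_s$ about column $j$ and substituting
$(u_s, \nu_s) = (\omega_{12}^{(s)}, \omega_{22}^{(s)} - \omega_{12}^{(s)\top}
\Omega_{11}^{(s)-1}\omega_{12}^{(s)})$ turns the column conditional into a
Bayesian linear regression: $u_s$ is Gaussian with precision
$\Upsilon_s + D^{-1}$ where $\Upsilon_s = (S_{22} + \lambda_s)
\Omega_{11}^{(s)-1}$ and $D$ holds the slab variances, and $\nu_s$ is
exactly $\mathrm{Gamma}(n_s/2 + 1, (S_{22}+\lambda_s)/2)$. Because
$\nu_s > 0$ almost surely and the reassembled diagonal entry is
$\nu_s + u_s^\top \Omega_{11}^{(s)-1} u_s$, every update keeps every
$\Omega_s$ positive definite by the Schur-complement argument — the test
suite audits 100% of stored draws.

One sweep visits the columns in random order. Within a column, for the
strong model, the edge indicators are updated by collapsed
Metropolis–Hastings: both the subject strengths $u_s$ and the group means
$\mu_{12}$ are Gaussian given the rest, so they integrate out in closed
form, and a single-entry flip is accepted with probability
$\min\{1, e^{\Delta \log \text{evidence}} \cdot a/(1-a)\}$ (or its
inverse for a removal). After the indicator sweep the group means are
drawn from their collapsed conditional $N(M^{-1}m, M^{-1})$ — drawing them
conditional on the *old* strengths would break the balance of the marginal
indicator update — and then strengths and Schur complements are drawn per
subject. Global conjugate updates follow: $\sigma_{ij}$ by random-walk
Metropolis on the log scale (step adapted towards 40% acceptance during
warm-up, then frozen), $\chi$ through the inverse-Gamma scale-mixture
expansion of the half-Cauchy, $a$ by Beta–Bernoulli conjugacy, and
$\lambda_s$ by Gamma conjugacy. Excluded edges keep their $\mu_{ij}$,
$\sigma_{ij}$ refreshed from the prior so the chain lives on the full
parameter space; by the same choice, all $p(p-1)/2$ pairs (included or
not) enter the $\chi$ update.

The engine is compiled (RcppArmadillo) with all randomness drawn from R's
RNG, so a run is reproducible from its single seed. Evidence evaluations
for flip proposals use incremental bordered factorisations
($O(Nk^2)$ per proposal instead of $O(Nk^3)$); during the first sweeps of
every run each incremental value is checked against the full computation
and any disagreement aborts the chain. A pure-R reference implementation
of the sweep (`gibbs_sweep()`) and of every conditional is exported, is
tested against closed forms and quadrature oracles, and is cross-checked
against the compiled engine on toy posteriors.

### Numerical choices

* Positive definiteness is certified by Cholesky with a minimum-pivot
  tolerance of `1e-10`.
* $\Omega_{11}^{-1}$ is refactorised per column per subject (no rank-one
  carry-over), trading a little arithmetic for unconditional stability.
* Initialisation: Tikhonov precisions ($\lambda = 0.01$), indicators from
  thresholding the group-mean $|$partial correlation$|$ at 0.05, $\mu$
  from the group-mean precision, $\sigma = m_\sigma$, $\chi = A$,
  $a = 0.5$, log-$\sigma$ step 0.1.
* Thinning defaults to 10; draws are stored in double precision when the
  archive stays below ~100 MB (`store_draws` overrides).
* Run lengths default to the benchmark protocol (30 000 kept + 10 000
  warm-up for the hierarchical models; 10 000 + 5 000 single-subject;
  3 000 + 1 000 for the per-subject samplers); the tests and the
  reproduction script run 5 000 total sweeps per fit, which these small
  designs mix well within.

## Simulated designs

`sim_preset()` reproduces the standard benchmark designs: circle precisions
($\omega_{ii}=1$, $\omega_{i,i+1}=0.5$, $\omega_{1p}=0.4$; sparsity 0.60
at $p=6$) with 5 or 25 subjects and 18–1000 samples; subject-perturbed
circles (shared random edge signs, per-subject strengths
$N(\pm\text{group}, \text{sd}^2)$ with sd 0.05 or 0.15, repaired to the PD
cone and rescaled to unit variance); a random-edge design whose edges
carry inclusion probabilities drawn from $\{0, 0.5, 1\}$ and toggle
independently at every time point; and G-Wishart-structured groups over an
arbitrary user-supplied graph (the published cat/macaque cortical
adjacencies are external data; any adjacency slots into the same recipe).

Three interpretation points worth knowing:

* The sample count printed for the 30-node perturbed-circle design is
  ambiguous in its published description; the preset defaults to
  `n = 1100` and exposes it as a parameter.
* The PD repair is a spectral clip (Frobenius-nearest matrix with minimum
  eigenvalue $\ge \epsilon$). When random signs make a matrix strongly
  indefinite the repair, followed by the unit-variance rescale, perturbs
  *all* entries — structural zeros are no longer exact and the realised
  between-subject spread exceeds the nominal sd (the inversions mix
  neighbouring edges). This mirrors the large printed variability of
  those designs and is why the recovered networks for them are not
  strictly sparse.
* The random-edge generator realises a new adjacency per time point; each
  realised matrix is PD-repaired (floor 0.01) before its sample is drawn —
  how the original recipe maintained definiteness is unstated.
* G-Wishart draws use the shape parameterisation
  $|\Omega|^{(\mathrm{df}-2)/2}\exp(-\mathrm{tr}(V^{-1}\Omega)/2)$ (block
  Gibbs along columns, conditional on the graph). A complete graph
  reduces to a Wishart with $\mathrm{df}+p-1$ degrees of freedom; the
  group-level default $\mathrm{df} = p-1$ is proper on sparse graphs in
  this convention.

What the simulations do *not* emulate: temporal autocorrelation,
haemodynamics or oscillatory envelopes, measurement leakage between
regions, or missing data. Passing these tests shows correct inference
under the model's own assumptions — i.i.d. Gaussian samples with
subject-level precision heterogeneity — not robustness to real
neuroimaging artefacts.

## Evaluation metrics

`rms_error()` scores estimates on the partial-correlation scale over the
$p(p-1)/2$ unordered pairs (ground truth is normalised without inversion,
so indefinite "truth" matrices from the random-edge design pose no
problem; a precision-space comparison is available via `space =
"precision"` since published descriptions vary between the two).
`normalise_rms()` divides by the naive-inversion error, anchoring that
estimator at exactly 1. `edge_roc_auc()` is the midrank Mann–Whitney
statistic on absolute inferred strengths versus the true graph — used for
all models, with posterior edge probabilities reported separately
(`summarise_posterior()`, `tidy()`).

## Design choices that were genuinely open

* **Collapsed evidence derivation.** The full sampler derivation is not
  published; the Gaussian integral over $(\{u_s\}, \mu_{12})$ was derived
  from scratch and is validated against adaptive quadrature to $10^{-6}$
  on log-evidence differences (the quantity the chain uses).
* **Indicator proposal scheme.** Every entry of a column's indicator
  vector is visited once per sweep with a single-entry flip — the
  simplest reversible scheme consistent with the column-conditional
  structure.
* **$a$ enters the MH ratio as its sampled value** (conjugate and cheap);
  collapsing over the Beta layer would be an optimisation, not a change
  of target.
* **Selection rules for baselines** (Tikhonov/graphical-lasso penalty,
  hierarchical-Wishart $\nu_0$) follow the stated group-coherence and
  split-half criteria, computed on off-diagonal partial correlations —
  the space in which all results are reported.
* **Bayesian-glasso rate** $\lambda$ is a config constant (default 1);
  its published value is not stated. Diagonals keep the framework's
  exponential/neutral-Gamma treatment since the Laplace prior is printed
  for off-diagonals only.

## Known limitations

The shared-graph assumption means no subject can deviate in structure,
only in strength; with abundant data the posterior tends towards the full
graph, so sparse-model edge probabilities are best read as regularisation
devices rather than biological claims. The per-subject samplers
(Bayesian glasso, SSVS) are included as comparison points and do not pool
across subjects. Complex-valued data and within-series missingness are
out of scope.
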