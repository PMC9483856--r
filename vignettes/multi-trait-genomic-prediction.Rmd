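---
title: "Multi-trait genomic prediction across environments: models, kernels and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait genomic prediction across environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Genomic selection trains a statistical model on lines that have both
genome-wide marker data and phenotypes, then predicts the performance of
candidates from their markers alone. In multi-environment trials the same
panel of lines is evaluated in several environments (locations, years,
managed treatments), several correlated traits are scored on each plot, and
the practically relevant question is often extrapolation to a *new*
environment: every line has been genotyped, but nobody has grown the panel
at the new site. `genopred` implements and compares two families of models
for this setting:

* **MT-GBLUP** — a Bayesian multi-trait genomic best linear unbiased
  prediction model, the field's standard benchmark;
* **MT-PLS** — multi-response partial least squares regression on
  kernel-augmented predictors, a fast deterministic alternative that handles
  the strong collinearity of marker-derived inputs by construction.

Both have single-trait ("UT") reductions, obtained by fitting one response
column at a time, so four methods are compared under a common
leave-one-environment-out protocol.

## The mixed model

With $n$ records ordered first by environment and then by line, the
multi-trait model is

$$Y = 1_n\mu^\top + X_E\beta_E + Z_L g + Z_{EL}\,g_E + \epsilon,$$

where $Y$ is $n \times n_T$, $\mu$ holds per-trait intercepts, $X_E$, $Z_L$
and $Z_{EL}$ are 0/1 indicator matrices of environments, lines and
environment-by-line cells, and

* $g \sim MN(0,\, G,\, \Sigma_T)$: line effects with row covariance the
  VanRaden genomic relationship matrix
  $G = WW^\top / (2\sum_k p_k(1-p_k))$ ($W$ the 0/1/2 marker matrix with
  columns centered at $2p_k$), and column covariance the genetic trait
  covariance $\Sigma_T$;
* $g_E \sim MN(0,\, K,\, \Sigma_T)$: interaction effects whose row
  covariance $K$ is the Kronecker kernel combining the environmental
  relationship matrix $H$ and $G$;
* $\epsilon \sim MN(0,\, I_n,\, R)$: residuals with trait covariance $R$.

$H$ is computed from environment-level covariates as the standardized Gram
kernel $W_E W_E^\top / q$ (the direct analogue of the VanRaden kernel on
markers) or set to the identity when no covariates exist. Note the model
deliberately shares one $\Sigma_T$ between $g$ and $g_E$; the interaction's
overall scale is carried by the kernels. This is the model as stated, not a
package simplification, and the Gibbs sampler's covariance update therefore
pools both effect matrices.

### Cell-index convention

Rows are environment-major, so the (environment $i$, line $j$) cell is
column $(i-1)J + j$ of $Z_{EL}$, and the matching interaction covariance is
$H \otimes G$ in that ordering. The literature sometimes writes the product
in the other order while still ordering rows by environment; the two differ
only by a permutation, and this package uses the single environment-major
convention everywhere (designs, kernels, simulation, prediction).

### Gibbs sampler

All full conditionals are standard. Random effects are sampled in the
spectral basis of their kernels: with $G = U D U^\top$ the working variable
is $\alpha = D^{-1/2}U^\top g$, whose prior is $MN(0, I, \Sigma_T)$. This
(i) is well-defined for rank-deficient kernels (a centered GRM always has a
zero eigenvalue; eigenvalues below $10^{-10}$ of the largest are dropped),
and (ii) makes the rows of $\alpha$ conditionally independent whenever
$\tilde Z^\top \tilde Z$ is diagonal — which holds exactly in balanced
layouts — so the update vectorizes. Unbalanced layouts fall back to an
exact row-at-a-time Gibbs scan. Trait pairs are decoupled by simultaneous
diagonalization of $(\Sigma_T^{-1}, R^{-1})$. The Kronecker kernel's
eigenpairs are Kronecker products of the factors' eigenpairs, so the
interaction term never requires an $IJ \times IJ$ decomposition.

Priors: $\Sigma_T, R \sim \mathrm{IW}(\nu = n_T + 2,\, S = cI)$ with
$c = 1$ by default, and flat Gaussians (variance $10^6$) on $\mu$ and
$\beta_E$. The original analyses delegated these choices to an external
library without reporting them; these are conventional weakly-informative
defaults. Chain defaults are 12,000 iterations, 2,000 burn-in, thinning 5;
the test suite uses a reduced 2,000/500/2 profile, which is enough because
every accuracy claim about the sampler is checked against the deterministic
mixed-model-equations solution rather than against chain-internal
diagnostics.

### Identifiability and the held-out environment

The fixed-effect design contains an intercept *and* a full set of
environment dummies. Under flat priors only the sums $\mu + \beta_{E,i}$
are identified; the split between $\mu$ and $\beta_E$ wanders along the
collinear direction with prior variance $10^6$, so the posterior mean of
$\mu$ alone is meaningless at any realistic chain length. Two consequences
are built into the package:

* comparisons between the sampler and the deterministic solver are made on
  identified quantities: $g$, $g_E$ and $\mu + \beta_E$;
* predictions for an environment absent from training default to centering
  on $\mu + \overline{\beta_E}$ (`unseen_env = "mean"`), the identified
  average environment level. The alternative `"zero"` (center on $\mu$
  alone) is selectable but was found to mis-center predictions badly for
  exactly the reason above; it remains useful for the `G+GE` configuration,
  which has no environment dummies, and for algebraic tests.

The genomic part of an unseen environment's prediction is
$Z_L \hat g$ plus the conditional mean of the new environment's interaction
block given the training blocks,
$\big(H_{te,tr}H_{tr,tr}^{-1} \otimes I_J\big)\hat g_E$ — exactly zero under
an identity $H$, and a covariate-weighted borrowing of training interaction
effects under an informative $H$.

## Multi-response partial least squares

PLS regresses $Y$ not on $X$ but on a small number of latent scores
$T = XR$ chosen to maximize covariance with the responses. Per component:
both working matrices are column-centered and scaled once at the start;
$S = E^\top F$ is formed from the current deflated matrices; the leading
singular pair $(w, q)$ of $S$ gives the weight vectors; the score
$t = Ew$ is normalized to unit length; loadings $p = E^\top t$,
$q = F^\top t$ follow; and both matrices are deflated by the rank-one
component contribution. After $a$ components the weights are mapped back to
the original predictor space by $R = W(P^\top W)^{-1}$, the inner
regression is $b = (T^\top T)^{-1}T^\top Y$, and $B = Rb$ gives predictions
$\hat Y_{new} = X_{new}B$ on the standardized scale, which are rescaled to
original response units. Numerical choices:

* scores are normalized to unit Euclidean norm (the typeset $t/t^\top t$
  reads as a scalar division; unit norm is the form under which
  $p = E^\top t$ is the least-squares loading);
* $Y$ columns are scaled as well, and predictions back-transformed, so
  observed and predicted values share a scale (NRMSE needs this);
* the sign of each weight vector is fixed (largest-magnitude entry
  positive) so fits are reproducible across linear-algebra backends;
* $(P^\top W)^{-1}$ uses a dense solve, falling back to a pseudo-inverse
  with a warning when the condition number exceeds $10^{12}$ (near rank
  exhaustion);
* zero-variance predictor columns — e.g. the dummy block of an environment
  absent from a training fold under an identity $H$ — are centered but not
  scaled, and end up with zero weight;
* if the deflated matrices are numerically empty before the requested
  number of components, fitting stops early with a warning.

The $u = Fq$ scores are computed and stored for interpretation but play no
role in prediction.

### Kernel-augmented inputs

PLS accepts one predictor matrix, so the covariance structure that MT-GBLUP
encodes through kernels is injected through the inputs: the concatenation

$$X = \big[\,X_E L_E \;\big|\; Z_L L_g \;\big|\; Z_{EL}(L_E \otimes L_g)\,\big],$$

where $L_g$ and $L_E$ are the symmetric (spectral) square roots of $G$ and
$H$. The Gram matrix of each block then reproduces the corresponding kernel
term of the mixed model — the package asserts
$(Z_L L_g)(Z_L L_g)^\top = Z_L G Z_L^\top$ in its tests. The spectral root
(rather than Cholesky) is used because relationship matrices are routinely
rank-deficient; eigenvalues below $10^{-10}$ of the largest are clipped to
zero. Three predictor configurations are supported: `E+G`, `E+G+GE` and
`G+GE`.

### Choosing the number of components

The number of latent variables is tuned by cross-validated RMSEP on the
training fold: rows are partitioned into `tune_folds` folds (default 5,
matching the nested 80/20 scheme; set 10 for classic 10-fold RMSEP), the
model is fitted at the largest candidate and every smaller model is read
off the same fit (PLS components are nested), and the pooled held-out root
mean squared error on the original response scale is minimized, ties going
to the smaller model. The default grid cap is
$\min(n_{train} - 1, m, 100)$.

## Evaluation protocol

Leave-one-environment-out: each environment in turn is the test set and the
remaining $I-1$ environments train the model. Component tuning happens
*inside* the training fold only. NRMSE $= \mathrm{RMSE}/\bar y$ is computed
per (environment, trait) on the held-out environment; "AcrossTraits" values
are arithmetic means of an environment's per-trait cells and "Global"
values arithmetic means across environments, a declared pooling rule chosen
for being exactly re-derivable from the cells (scale-free NRMSE cells make
the plain mean defensible). Relative efficiency is the ratio of two NRMSE
cells — GBLUP/PLS within each framework and UT/MT within each family — with
values above 1 favoring the denominator method.

For the PLS methods the predictor matrix is built once over all
environments: environment-level inputs ($H$, hence $L_E$) are known for the
test environment (its covariates are measured before harvest), while its
phenotypes never enter fitting or tuning. Under an identity $H$ the test
environment's columns are identically zero in the training rows, so they
receive zero weight — the PLS analogue of "no information transfer".

## The synthetic world

The generator draws markers as unlinked Binomial(2, MAF) loci with MAF
uniform on (0.05, 0.5), environment covariates as independent standard
normals, and phenotypes from the mixed model above with:
$g \sim MN(0, G, (1-f)\Sigma_T)$ and
$g_E \sim MN(0, H \otimes G, f\,\Sigma_T)$ where $f$ is `ge_fraction`
(default 0.2); diagonal residual covariance set per trait so the marginal
heritability $h^2$ (genetic variance over total, on the realized kernel
scale) matches the request (default 0.5); environment main effects with
standard deviation 0.5 genetic SDs; intercepts 10 (traits like yield are
positive-mean, and NRMSE divides by the observed mean). Default shapes
mirror a mid-sized balanced trial: around 300 lines, 4 environments, 4
traits, a few thousand markers. Real trials additionally have linkage
disequilibrium, population structure, spatial field trends and unbalanced
line sets — none of which the generator emulates, so a green test
establishes algorithmic correctness on the stated generative model, not
field performance.

## Known limitations

* The sampler estimates one $\Sigma_T$ shared by main and interaction
  effects because the model is stated that way; richer parametrizations
  (separate interaction covariance, trait-by-environment structures) are
  out of scope.
* Unbalanced layouts are supported but take the slower row-scan sampler
  path.
* REML/point estimation is not provided; the deterministic solver requires
  covariances to be supplied.
* Phenotype records with any missing trait are dropped listwise; markers
  are mean-imputed per locus before GRM construction.
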