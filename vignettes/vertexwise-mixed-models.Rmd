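---
title: "Mixed models for mass-univariate vertexwise association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed models for mass-univariate vertexwise association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Vertexwise analyses regress a phenotype on each of several hundred thousand
gray-matter measurements (cortical thickness and surface area on the
tessellated cortical surface, radial thickness and a surface-area analogue
on subcortical shapes) one at a time. Vertices are strongly correlated: with
their mesh neighbours (the tessellation oversamples smooth anatomy) and at
long range, across hemispheres and measurement types, because subject-level
factors — head size, age, sex, scanner, motion — load on wide swathes of the
brain at once. When a trait is genuinely associated with some vertices, any
null vertex correlated with those vertices inherits part of the signal, and
a per-vertex general linear model (GLM) will happily call it significant.
The result is inflated test statistics on null vertices, false-positive
clusters far from the true associations, and maps that are larger and less
specific than the underlying biology.

`vertexlmm` implements both the standard models and the remedy imported from
omics association studies: linear mixed models (LMMs) that test one vertex
as a fixed effect while conditioning on *all* vertices fitted jointly as a
random effect.

## Models

Let `y` be the standardized phenotype of N subjects, `Z` a covariate matrix
(an intercept is always included) and `x_i` the i-th standardized vertex.

**GLMs** (five covariate sets): `y = Z c + x_i b_i + e`, with covariates
none; age/sex/ICV analogues; 5 or 10 global principal components of the
vertex matrix; or 10 PCs per measurement type (40 in all). Per-vertex OLS
gives `b_i`, its standard error, and the test `(b_i/SE)^2 ~ chi-square(1)`.

**LMMs** (three variants): `y = Z c + x_i b_i + X beta + e` with
`beta ~ N(0, I sigma_b^2)`, so `var(y) = V = p sigma_b^2 B + sigma_e^2 I`
where `B = X X' / p` is the *brain-relatedness matrix* (BRM) — the
subject-by-subject similarity of gray-matter structure. The variants are:
global BRM without covariates, global BRM with age/sex/ICV, and a
four-component model with one BRM per measurement type, letting each type
carry its own effect-size distribution. We parameterize each component
directly as `v_k = p_k sigma_bk^2`, the phenotypic variance captured by that
vertex set; with a single global BRM, `v / (v + v_e)` is the
**morphometricity** of the trait. Columns are standardized with
denominator-N variance so that `mean(diag(B)) = 1` holds exactly and `v_k`
reads as a variance share.

Testing follows the one-pass MOA strategy: variance components are
estimated once per phenotype under the null model (no vertex fixed effect,
and the candidate vertex is *not* removed from the BRM), then every vertex
is tested by generalized least squares, `b = x'Py / x'Px`,
`SE^2 = 1/(x'Px)` with `P` the projected inverse covariance. The scan costs
O(pN^2 + N^3) overall instead of O(pN^3) for per-vertex refits. Keeping the
candidate inside the BRM ("double fitting") slightly deflates its statistic
— the tests are mildly conservative, never anti-conservative; leave-one-out
BRMs would cost a full refit per vertex and are not worth it beyond tiny p.

## REML estimation

Components are estimated by average-information (AI) REML. The update loop
takes one EM step, then AI steps with step-halving; an AI step proposing a
negative component is replaced — as a whole — by an EM step, with the
offending components additionally capped at half their current value (plain
EM approaches a distant boundary only geometrically). A component proposed
negative twice in a row is pinned to zero, but only if fixing it at zero
does not lower the restricted likelihood; this guard matters for weakly
identified fits such as a rank-1 BRM, where the AI quadratic model
persistently overshoots although the optimum is interior. Convergence is
declared when the restricted log-likelihood moves by less than `tol`
(default 1e-8). Standard errors come from the inverse AI matrix, and the
morphometricity SE by the delta method — the SE convention is ours, chosen
because it is the standard output of the AI-REML machinery.

Two numerical paths produce identical results (tested against each other
and against a grid-search/Nelder-Mead maximization of an independently
coded restricted likelihood): a dense Cholesky path for arbitrary numbers
of components, and, for a single BRM, a spectral path that rotates the
problem into the eigenbasis of B once — the decomposition is cached on the
BRM and shared across phenotypes, so each of the hundreds of REML fits in a
simulation study costs O(Nq) per iteration. This is why the package can fit
100 phenotypes x 8 models in minutes on one core.

## The synthetic cohort generator

The generator emulates the two correlation structures the argument rests
on, on lattices rather than real meshes:

* **Geometry.** One 4-neighbour lattice per measurement type and hemisphere
  (8 structures). Default layouts give p = 5,000, 10,000 or 20,000 vertices
  with a 9:1 cortical:subcortical ratio, close to the ~11:1 of FreeSurfer +
  subcortical-shape output.
* **Local correlation.** The per-vertex noise field is smoothed on the
  lattice (default 2 rounds of neighbour averaging with self-weight 1/2,
  rescaled to unit variance). Graph smoothing stands in for a surface
  kernel in millimetres; it reproduces the qualitative effect (rising
  neighbour correlation with rounds) without real geometry.
* **Long-range and cross-type correlation.** K = 6 latent standard-normal
  subject factors with spatially smooth, row-normalized loading maps inject
  a `confounder_share` (default 0.3) of every vertex's variance. Three
  factors are exported as observed covariates (age, sex — dichotomized at
  the median — and an ICV analogue) plus one pure-noise covariate; three
  stay hidden, so covariate-adjusted GLMs remove some but not all
  confounding. The share of 0.3 is a choice — the source data's long-range
  correlation strength is not quantified anywhere — and is stated in every
  result that depends on it.

Replication cohorts reuse the loading maps with fresh subjects and noise,
and an optional mean shift on the observed factors emulates a transfer
cohort. What the generator does **not** emulate: real marginal
distributions, scanner or site effects, true cortical geometry and
curvature-dependent smoothing, or missing data. Passing tests on this
generator therefore demonstrate the statistical mechanics of the models —
calibration under the null, confounder-driven GLM inflation, LMM
parsimony — not performance on any particular real dataset.

## Phenotype simulation

A trait draws `m` causal vertices uniformly (optionally within one
measurement type), effects from N(0,1), forms `g = X_causal w` and adds
noise of variance `var(g) (1 - R2)/R2`. With `exact_rescale` (default) the
noise is orthogonalized against `g` and rescaled so the realized in-sample
variance share equals the target morphometricity exactly; the alternative
draws noise at its theoretical variance for distributional realism. Whether
the reference simulation machinery rescaled to empirical or theoretical
variance is not documented; both are supported and the default is the
reproducible one. The standing scenarios are (i) m = 10, R2 = 0.20,
(ii) m = 100, R2 = 0.50, (iii) m = 1000, R2 = 0.40, each with 100
replicates, plus null traits and per-type restricted variants.

## Evaluation metrics

Significance uses Bonferroni (`0.05 / p`, and `/ n_phenotypes` when several
traits are analysed). Clusters are maximal connected sets of significant
vertices in the mesh graph; they never span structures because edges do
not. A cluster is TP if it contains a causal (hence significant) vertex.
Reported metrics: inflation factor `lambda` (median chi-square over the
chi-square(1) median, 0.4549364, averaged over replicates), nominal FPR
(null vertices with p < 0.05), TPR, vertex and cluster FWER (replicates
with at least one false-positive vertex / cluster), pooled cluster FDR (FP
clusters over all significant clusters pooled across replicates, with the
per-replicate mean as a secondary column — the pooling convention is a
choice), mapping precision (median and max TP-cluster size), and
FWER-calibrated power: the TPR at the largest threshold whose cluster FWER
stays at or below 0.2, found by bisection on log10(alpha) to 0.1 log10
units starting from the Bonferroni threshold.

Two fine points uncovered while testing. First, cluster-level FDR and FWER
are *not* exactly monotone in alpha on alternative-hypothesis data: lowering
the threshold can push the causal vertex itself below significance and
relabel the rest of its cluster as FP. The monotone quantities are the
significant- and FP-vertex counts, and cluster FWER on null traits. Second,
the per-trait `lambda` is noisy and right-skewed at a few thousand vertices
(SD near 0.3 per null trait at p = 5000), so the calibration suite checks
that the replicate mean is consistent with 1 given its between-replicate
standard error, which `replicate_metrics()` reports as `lambda_se`.

## Prediction

Linear predictors use the marginal association weights of either the most
significant vertex per cluster (ties to the lowest id) or every significant
vertex, with the training-sample standardization frozen into the predictor
and applied unchanged to test cohorts — no test-sample statistics, no
leakage, and the convention transfers to shifted cohorts. Accuracy is the
Pearson correlation with a Fisher-z confidence interval, plus a partial
correlation after residualizing on covariates. The trait's morphometricity
bounds attainable accuracy (`r <= sqrt(R2)`, up to noise).

At desk scale, the "one vertex per cluster beats all significant vertices"
ordering holds for the global-BRM LMM — whose few clusters carry distinct
signals — in well over 70% of replicates. For GLMs it reverses: their maps
contain dozens of confounder-driven distal clusters, and averaging many
correlated significant vertices cancels noise. The property is therefore
asserted for the mixed model, which is the model whose parsimony it is
about.

## Study sizes and numerical choices

The standing desk-scale studies are: null calibration at N = 1000,
p = 5000 with 100 null traits and all eight models; morphometricity
recovery at N = 2000, p = 10000 with 20 traits per scenario;
and the GLM-vs-LMM contrast at N = 1000, p = 5000, scenario (ii), 50
replicates. These sizes keep a full run in minutes on one core while
leaving every qualitative contrast visible. One quantitative bound does not
transfer from full-scale data: on a 5000-vertex lattice with two smoothing
rounds, Bonferroni is only mildly conservative (effective tests close to
p), so the vertex FWER under the null sits near 4-5% rather than under the
3% observed with several hundred thousand heavily redundant real vertices.
The calibration suite reports this honestly rather than strengthening the
generator's correlation to force it.

Other numerical conventions: covariance solves use Cholesky factorizations;
vertices whose residual variance after covariate projection falls below
1e-12 are flagged and reported as chi2 = 0, p = 1 rather than aborting a
scan; p-values are floored at the smallest positive double; BRM
eigenvalues are clipped at zero; all randomness flows through explicitly
seeded generators, with replicate r of a study using `base_seed * 1000 + r`
so studies are reproducible and extensible.

## Limitations

Lattice meshes have no geometry, so nothing here speaks to
millimetre-kernel smoothing, random-field theory, or real cluster-extent
inference. The LMMs assume Gaussian, homoscedastic traits; discrete or
skewed phenotypes are out of scope. The one-pass scan is conservative for
vertices that carry a visible share of the BRM (tiny p); at realistic p the
deflation is negligible. Stepwise and Bayesian mixed-model extensions, and
leave-one-vertex-out BRMs, are deliberately not implemented.
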