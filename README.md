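# vertexlmm

Mixed-model and GLM mass-univariate association analysis for vertexwise
gray-matter data.

## The problem

Surface-based morphometry yields hundreds of thousands of per-subject
measurements — cortical thickness and surface area at each vertex of the
tessellated cortex, radial thickness and a surface-area analogue on
subcortical shapes. Mass-univariate analysis regresses a phenotype on each
vertex in turn. But vertices are far from independent: mesh neighbours are
nearly duplicated measurements, and subject-level factors (head size, age,
sex, scanner, motion — some measured, some not) induce correlation across
distant regions, hemispheres and measurement types. A per-vertex GLM then
transfers real signal onto correlated null vertices, producing inflated
test statistics, distal false-positive clusters and anatomically bloated
maps.

The package implements the remedy borrowed from genome- and methylome-wide
association studies: a **linear mixed model** that tests one vertex as a
fixed effect while conditioning on all p vertices fitted jointly as a
random effect,

    y = Z c + x_i b_i + X beta + e,     beta ~ N(0, I sigma_b^2),
    var(y) = V = p sigma_b^2 B + sigma_e^2 I,     B = X X' / p,

where `B` is the **brain-relatedness matrix** (BRM): the subject-by-subject
similarity of gray-matter structure over standardized vertices. The
variance share `p sigma_b^2 / (p sigma_b^2 + sigma_e^2)` is the trait's
**morphometricity**, estimated by average-information REML (with a cached
spectral fast path for a single BRM). Vertices are then tested in one pass
by generalized least squares, `chi2_i = (x_i'Py)^2 / (x_i'Px_i)` against
chi-square(1) — O(pN^2 + N^3) for a whole scan. Eight model configurations
are built in: GLMs with no covariates, age/sex/ICV analogues, 5 or 10
global PCs, or 10 modality-specific PCs per measurement type; and LMMs with
a global BRM (with/without covariates) or four per-type BRMs.

Around the models sit a synthetic-cohort generator (mesh-local smoothing
plus latent-confounder long-range correlation on lattice atlases),
phenotype simulation with exact target morphometricity, Bonferroni
thresholding and mesh-cluster formation, the full evaluation battery
(inflation factor, FPR, TPR, vertex/cluster FWER, pooled cluster FDR,
mapping precision, power calibrated at cluster FWER <= 0.2), and
out-of-sample linear prediction from significant vertices.

## Worked example

Simulate a confounded cohort, a trait with 100 causal vertices capturing
half of the phenotypic variance, and compare a covariate-adjusted GLM with
the global-BRM LMM:

```r
library(vertexlmm)

cfg   <- generator_config(N = 800, p = 5000, confounder_share = 0.3, seed = 42)
gen   <- generate_cohort(cfg)
data  <- standardize_columns(gen$cohort)
trait <- simulate_trait(data, trait_spec(m_causal = 100, target_r2 = 0.5,
                                         seed = 7))

suite <- run_model_suite(trait$y, data, gen$atlas)
suite$vc$lmm_none_global
#> variance_components (eigen AI-REML, converged in 6 iterations)
#>   v[global] = 0.363517 (SE 0.0954)
#>   v[e] = 0.529493
#>   morphometricity = 0.4071 (SE 0.0837), logL = -1014.9362

alpha <- bonferroni_alpha(gen$atlas$p)   # 0.05 / 5000 = 1e-05
for (nm in c("glm_age_sex_icv", "lmm_none_global")) {
  cs   <- threshold_and_cluster(suite$results[[nm]], gen$atlas, alpha,
                                trait$causal_ids)
  labs <- vapply(cs$clusters, `[[`, character(1), "label")
  cat(sprintf("%s: %d clusters (%d TP, %d FP)\n",
              nm, length(labs), sum(labs == "TP"), sum(labs == "FP")))
}
#> glm_age_sex_icv: 218 clusters (37 TP, 181 FP)
#> lmm_none_global: 1 clusters (1 TP, 0 FP)
```

The GLM — despite adjusting for the observed covariates — reports 218
significant clusters of which 181 contain no causal vertex: the hidden
confounders and local smoothness spread the association over the whole
atlas. The LMM, conditioning on all vertices through the BRM, returns a
single true-positive cluster. Its REML fit estimates the morphometricity at
0.41 (SE 0.08) against a simulated 0.50 for this single replicate.

Predictors built from the significant vertices transfer to a matched
replication cohort using frozen training statistics:

```r
res  <- suite$results$lmm_none_global
cs   <- threshold_and_cluster(res, gen$atlas, alpha, trait$causal_ids)
pred <- build_predictor(res, cs, "top_per_cluster", data)
rep_raw <- generate_replication(cfg, gen$latent, seed2 = 900042)
y_rep   <- apply_trait(trait, standardize_columns(rep_raw), seed = 1)
ev <- evaluate_prediction(score_cohort(pred, rep_raw), y_rep$y)
sprintf("out-of-sample r = %.3f [%.3f, %.3f]", ev$r, ev$ci_low, ev$ci_high)
#> "out-of-sample r = 0.276 [0.211, 0.339]"
```

A command-line wrapper over the same functions lives at
`inst/cli/vertexlmm.R` (subcommands `generate`, `simulate`, `reml`,
`assoc`, `metrics`, `predict`, `experiment`).

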