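test_that("GLM scan matches lm() and the explicit normal equations", {
  co <- small_cohort(N = 20, seed = 51, grid = micro_grid())
  set.seed(1)
  y <- rnorm(20)
  res <- run_glm(y, co$std, model_spec("glm", "age_sex_icv"))
  cv <- co$std$covariates
  for (j in c(1, 10, 30)) {
    x <- co$std$values[, j]
    ref <- summary(lm(y ~ cv$age + cv$sex + cv$icv + x))$coefficients["x", ]
    expect_equal(res$tbl$b[j], unname(ref["Estimate"]), tolerance = 1e-8)
    expect_equal(res$tbl$se[j], unname(ref["Std. Error"]), tolerance = 1e-8)
  }
  # explicit normal equations for one vertex, no covariates
  res0 <- run_glm(y, co$std, model_spec("glm", "none"))
  W <- cbind(1, co$std$values[, 7])
  beta <- solve(crossprod(W), crossprod(W, y))
  resid <- y - W %*% beta
  s2 <- sum(resid^2) / (20 - 2)
  se <- sqrt(s2 * solve(crossprod(W))[2, 2])
  expect_equal(res0$tbl$b[7], beta[2], tolerance = 1e-10)
  expect_equal(res0$tbl$se[7], se, tolerance = 1e-10)
  expect_equal(res0$tbl$chi2[7], (beta[2] / se)^2, tolerance = 1e-8)
})

test_that("perfect and null associations behave at the extremes", {
  co <- small_cohort(N = 100, seed = 52)
  x <- co$std$values[, 5]
  res <- run_glm(x, co$std, model_spec("glm", "none"))
  expect_equal(res$tbl$pval[5], .Machine$double.xmin)
  expect_equal(res$tbl$b[5], 1, tolerance = 1e-8)
  # y constructed orthogonal to a vertex
  y <- resid(lm(rnorm(100) ~ x))
  res2 <- run_glm(y, co$std, model_spec("glm", "none"))
  expect_equal(res2$tbl$b[5], 0, tolerance = 1e-10)
  expect_lt(res2$tbl$chi2[5], 1e-16)
  expect_true(all(res2$tbl$chi2 >= 0))
  expect_true(all(res2$tbl$pval > 0 & res2$tbl$pval <= 1))
})

test_that("vertices collinear with covariates are flagged, not fatal", {
  set.seed(3)
  age <- rnorm(50); sex <- rbinom(50, 1, 0.5); icv <- rnorm(50)
  vals <- cbind(age, matrix(rnorm(50 * 9), 50, 9))
  d <- standardize_columns(cohort_matrix(
    vals, covariates = data.frame(age = age, sex = sex, icv = icv)))
  res <- run_glm(rnorm(50), d, model_spec("glm", "age_sex_icv"))
  expect_true(res$tbl$flagged[1])
  expect_equal(res$tbl$chi2[1], 0)
  expect_equal(res$tbl$pval[1], 1)
  expect_false(any(res$tbl$flagged[-1]))
})

test_that("the LMM reduces to the GLM when the variance components vanish", {
  co <- small_cohort(N = 150, seed = 53, grid = micro_grid())
  brm <- compute_brm(co$std)
  vc0 <- fit_reml(simulate_null(150, 1)$y, NULL, brm)
  vc0$v_components[1] <- 0
  vc0$v_e <- 1
  # y orthogonal to every vertex: both engines give chi2 = 0 identically
  set.seed(53)
  y_orth <- resid(lm(rnorm(150) ~ co$std$values))
  y_orth <- (y_orth - mean(y_orth)) / sd(y_orth)
  g0 <- run_glm(y_orth, co$std, model_spec("glm", "none"))
  l0 <- run_lmm(y_orth, co$std, model_spec("lmm", "none", "global"), vc0)
  expect_equal(l0$tbl$chi2, g0$tbl$chi2, tolerance = 1e-8)
  expect_equal(l0$tbl$b, g0$tbl$b, tolerance = 1e-8)
  # arbitrary y: slopes agree exactly; chi2 agrees up to the O(1/N)
  # difference between the per-vertex OLS residual variance and v_e
  y <- simulate_null(150, 2)$y
  g1 <- run_glm(y, co$std, model_spec("glm", "none"))
  l1 <- run_lmm(y, co$std, model_spec("lmm", "none", "global"), vc0)
  expect_equal(l1$tbl$b, g1$tbl$b, tolerance = 1e-8)
  expect_lt(max(abs(l1$tbl$chi2 - g1$tbl$chi2) / (g1$tbl$chi2 + 1)), 0.05)
})

test_that("double fitting deflates the single-vertex chi-square", {
  set.seed(11)
  n <- 200
  x <- rnorm(n); x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  y <- 0.3 * x + rnorm(n)
  y <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  d <- cohort_matrix(cbind(x, deparse.level = 0))
  d$standardized <- TRUE
  d$col_means <- 0; d$col_sds <- 1
  brm <- compute_brm(d)
  vc <- fit_reml(y, NULL, brm)
  glm_chi <- run_glm(y, d, model_spec("glm", "none"))$tbl$chi2[1]
  lmm_chi <- run_lmm(y, d, model_spec("lmm", "none", "global"), vc)$tbl$chi2[1]
  expect_gt(vc$v_components[1], 0)
  expect_lt(lmm_chi, glm_chi)
})

test_that("one-pass LMM agrees with the exact per-vertex REML refit", {
  co <- small_cohort(N = 150, seed = 54)
  # a diffuse trait (100 of 200 vertices causal) keeps any single vertex a
  # small part of the random effect, the regime the one-pass strategy
  # targets; concentrated effects at tiny p make the two testing
  # strategies legitimately diverge
  tr <- simulate_trait(co$std, trait_spec(100, 0.3, seed = 13))
  brm <- compute_brm(co$std)
  vc <- fit_reml(tr$y, NULL, brm)
  one_pass <- run_lmm(tr$y, co$std, model_spec("lmm", "none", "global"), vc)
  top <- order(one_pass$tbl$pval)[1:10]
  joint_gls <- function(x, comps) {
    V <- comps[1] * brm$matrix + comps[2] * diag(150)
    W <- cbind(1, x)
    WVi <- solve(V, W)
    covb <- solve(crossprod(W, WVi))
    bhat <- covb %*% crossprod(WVi, tr$y)
    c(chi2 = bhat[2]^2 / covb[2, 2], b = bhat[2])
  }
  for (j in top) {
    x <- co$std$values[, j]
    # at the null-model covariance the one-pass scan IS the joint GLS fit
    fixed <- joint_gls(x, c(vc$v_components[1], vc$v_e))
    expect_equal(one_pass$tbl$chi2[j], unname(fixed["chi2"]),
                 tolerance = 1e-8)
    expect_equal(one_pass$tbl$b[j], unname(fixed["b"]), tolerance = 1e-8)
    # re-estimating the components with the vertex as a fixed effect
    # shrinks the random-effect share and raises the statistic; the
    # one-pass value tracks it from below (double-fitting deflation)
    refit <- fit_reml(tr$y, cbind(x), brm)
    chi_refit <- unname(joint_gls(x, c(refit$v_components[1],
                                       refit$v_e))["chi2"])
    expect_lte(one_pass$tbl$chi2[j], chi_refit * 1.05)
    expect_equal(one_pass$tbl$chi2[j], chi_refit, tolerance = 0.35)
  }
})

test_that("both engines give uniform p-values under the null hypothesis", {
  cfg <- generator_config(N = 500, p = 5000, confounder_share = 0.3,
                          seed = 55)
  gen <- generate_cohort(cfg)
  data <- standardize_columns(gen$cohort)
  brm <- compute_brm(data)
  pg <- pl <- numeric(0)
  for (r in 1:20) {
    y <- simulate_null(500, seed = 5500 + r)
    pg <- c(pg, run_glm(y$y, data, model_spec("glm", "none"))$tbl$pval)
    vc <- fit_reml(y$y, NULL, brm)
    pl <- c(pl, run_lmm(y$y, data, model_spec("lmm", "none", "global"),
                        vc)$tbl$pval)
  }
  ks <- function(p) max(abs(sort(p) - seq_along(p) / length(p)))
  expect_lt(ks(pg), 0.03)
  expect_lt(ks(pl), 0.03)
})

test_that("association results are invariant to subject permutation", {
  co <- small_cohort(N = 80, seed = 56, grid = micro_grid())
  tr <- simulate_trait(co$std, trait_spec(5, 0.5, seed = 14))
  perm <- sample(80)
  d2 <- cohort_matrix(co$raw$values[perm, ],
                      subject_id = co$raw$subject_id[perm],
                      covariates = co$raw$covariates[perm, ])
  d2 <- standardize_columns(d2)
  g1 <- run_glm(tr$y, co$std, model_spec("glm", "age_sex_icv"))
  g2 <- run_glm(tr$y[perm], d2, model_spec("glm", "age_sex_icv"))
  expect_equal(g1$tbl$chi2, g2$tbl$chi2, tolerance = 1e-8)
  vc1 <- fit_reml(tr$y, NULL, compute_brm(co$std))
  vc2 <- fit_reml(tr$y[perm], NULL, compute_brm(d2))
  l1 <- run_lmm(tr$y, co$std, model_spec("lmm", "none", "global"), vc1)
  l2 <- run_lmm(tr$y[perm], d2, model_spec("lmm", "none", "global"), vc2)
  expect_equal(l1$tbl$chi2, l2$tbl$chi2, tolerance = 1e-6)
})

test_that("the model suite runs all eight configurations on shared subjects", {
  co <- small_cohort(N = 120, seed = 57)
  tr <- simulate_trait(co$std, trait_spec(10, 0.5, seed = 15))
  suite <- run_model_suite(tr$y, co$std, co$atlas)
  expect_length(suite$results, 8)
  expect_setequal(names(suite$results),
                  c("glm_none", "glm_age_sex_icv", "glm_pc5_global",
                    "glm_pc10_global", "glm_pc10_per_type",
                    "lmm_none_global", "lmm_age_sex_icv_global",
                    "lmm_none_per_type_4"))
  expect_true(all(vapply(suite$results, `[[`, numeric(1),
                         "n_subjects") == 120))
  # the modality-specific PC set supplies 10 x 4 covariates
  pcs <- vertexlmm:::spec_covariates(co$std,
                                     model_spec("glm", "pc10_per_type"),
                                     co$atlas)
  expect_equal(ncol(pcs), 40)
  expect_length(suite$vc, 3)
  # on H1 data the LMM suppresses the null-vertex statistics relative to
  # the GLM
  nulls <- setdiff(seq_len(co$atlas$p), tr$causal_ids + 1L)
  expect_lt(mean(suite$results$lmm_none_global$tbl$chi2[nulls]),
            mean(suite$results$glm_none$tbl$chi2[nulls]))
})

test_that("model specs outside the published census are rejected", {
  expect_error(model_spec("glm", "bogus"))
  expect_error(model_spec("lmm", "pc5_global"))
  expect_silent(model_spec("lmm", "age_sex_icv", "per_type_4"))
})
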