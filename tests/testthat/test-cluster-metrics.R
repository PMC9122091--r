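test_that("Bonferroni thresholds reproduce the published values", {
  expect_equal(bonferroni_alpha(652283), 7.6e-8, tolerance = 1e-2)
  expect_equal(bonferroni_alpha(652283) * 652283, 0.05)
  expect_equal(bonferroni_alpha(652283, n_phenotypes = 5), 1.5e-8,
               tolerance = 3e-2)
  expect_equal(bonferroni_alpha(1), 0.05)
  expect_error(bonferroni_alpha(0), "at least 1")
})

test_that("clusters are the connected components of the significant set", {
  atlas <- lattice_atlas_1(3, 3)   # ids 0..8 row-major
  pv <- rep(0.5, 9)
  pv[c(1, 2, 9)] <- 1e-9           # vertices 0, 1 (adjacent) and 8
  res <- fake_result(pv)
  cs <- threshold_and_cluster(res, atlas, 1e-6, truth = 8L)
  expect_length(cs$clusters, 2)
  sizes <- sort(vapply(cs$clusters, `[[`, numeric(1), "size"))
  expect_equal(sizes, c(1, 2))
  labs <- vapply(cs$clusters, `[[`, character(1), "label")
  by_size <- vapply(cs$clusters, `[[`, numeric(1), "size")
  expect_equal(labs[by_size == 1], "TP")   # isolated causal vertex
  expect_equal(labs[by_size == 2], "FP")
  # equal p-values tie-break to the lowest vertex id
  pair <- cs$clusters[[which(by_size == 2)]]
  expect_equal(pair$top_vertex, 0)
  expect_equal(pair$members, c(0, 1))
  # nothing significant -> empty set
  expect_length(threshold_and_cluster(fake_result(rep(0.5, 9)), atlas,
                                      1e-6)$clusters, 0)
})

test_that("every significant vertex lies in exactly one cluster", {
  co <- small_cohort(N = 150, seed = 61)
  tr <- simulate_trait(co$std, trait_spec(10, 0.6, seed = 20))
  res <- run_glm(tr$y, co$std, model_spec("glm", "none"))
  alpha <- 0.01
  cs <- threshold_and_cluster(res, co$atlas, alpha, tr$causal_ids)
  members <- unlist(lapply(cs$clusters, `[[`, "members"))
  expect_equal(sort(members), sort(which(res$tbl$pval < alpha) - 1L))
  expect_false(anyDuplicated(members) > 0)
  expect_equal(sum(vapply(cs$clusters, `[[`, numeric(1), "size")),
               sum(res$tbl$pval < alpha))
  # clusters never span measurement types
  tp <- co$atlas$vertices$meas_type
  for (cl in cs$clusters)
    expect_length(unique(tp[cl$members + 1L]), 1)
})

test_that("the inflation factor scales the median chi-square", {
  expect_equal(inflation_factor(rep(0.4549364, 5)), 1, tolerance = 1e-6)
  expect_equal(inflation_factor(rep(0.9098728, 5)), 2, tolerance = 1e-6)
  set.seed(8)
  expect_equal(inflation_factor(rchisq(1e6, df = 1)), 1, tolerance = 0.01)
  expect_error(inflation_factor(numeric(0)), "empty")
})

test_that("replicate metrics count rates as defined", {
  atlas <- lattice_atlas_1(2, 10)  # 20-vertex path-ish lattice
  # truth 0..9; significant: 7 causal + 1 distant null vertex
  pv <- rep(0.5, 20)
  pv[1:7] <- 1e-9
  pv[19] <- 1e-9
  rep1 <- list(res = fake_result(pv), truth = 0:9)
  m <- replicate_metrics(list(rep1), atlas, alpha = 1e-6, calibrate = FALSE)
  expect_equal(m$tpr, 0.7)
  expect_equal(m$fwer_vertex, 1.0)
  expect_equal(m$fwer_cluster, 1.0)
  expect_equal(m$fdr_cluster, 0.5)      # one TP cluster, one FP cluster
  expect_equal(m$precision_median, 7)
  expect_equal(unname(m$per_type_fwer["ct"]), 1.0)

  # clean replicate: no significant nulls
  pv2 <- rep(0.5, 20); pv2[1:7] <- 1e-9
  rep2 <- list(res = fake_result(pv2), truth = 0:9)
  m2 <- replicate_metrics(list(rep2), atlas, 1e-6, calibrate = FALSE)
  expect_equal(m2$fwer_vertex, 0)
  expect_equal(m2$fdr_cluster, 0)

  # nothing significant at all: cluster FDR undefined
  m3 <- replicate_metrics(list(list(res = fake_result(rep(0.5, 20)),
                                    truth = 0:9)), atlas, 1e-6,
                          calibrate = FALSE)
  expect_true(is.na(m3$fdr_cluster))
  expect_equal(m3$tpr, 0)

  # pooled FDR: 4 replicates with one TP cluster, 6 with one FP cluster
  mk <- function(tp) {
    pv <- rep(0.5, 20)
    if (tp) pv[1] <- 1e-9 else pv[19] <- 1e-9
    list(res = fake_result(pv), truth = if (tp) 0L else integer(0))
  }
  reps <- c(lapply(1:4, function(i) mk(TRUE)),
            lapply(1:6, function(i) mk(FALSE)))
  m4 <- replicate_metrics(reps, atlas, 1e-6, calibrate = FALSE)
  expect_equal(m4$fdr_cluster, 6 / 10)
})

test_that("significance counts and null-replicate cluster FWER are monotone in alpha", {
  # Cluster-level FDR/FWER on alternative-hypothesis data need not be
  # exactly monotone in alpha: lowering the threshold can drop the causal
  # vertex out of a cluster and relabel the remainder FP. What is monotone:
  # the significant and FP vertex counts, and the cluster FWER when no
  # vertex is causal (every cluster FP).
  co <- small_cohort(N = 200, seed = 62)
  tr <- simulate_trait(co$std, trait_spec(10, 0.6, seed = 21))
  res <- run_glm(tr$y, co$std, model_spec("glm", "none"))
  null1 <- setdiff(seq_len(co$atlas$p), tr$causal_ids + 1L)
  alphas <- 10^seq(-2, -8, by = -0.5)
  n_sig <- vapply(alphas, function(a) sum(res$tbl$pval < a), numeric(1))
  n_fp <- vapply(alphas, function(a) sum(res$tbl$pval[null1] < a),
                 numeric(1))
  expect_true(all(diff(n_sig) <= 0))
  expect_true(all(diff(n_fp) <= 0))

  null_reps <- lapply(1:5, function(r) {
    y <- simulate_null(200, seed = 6200 + r)
    list(res = run_glm(y$y, co$std, model_spec("glm", "none")),
         truth = integer(0))
  })
  fwer <- vapply(alphas, function(a)
    replicate_metrics(null_reps, co$atlas, a,
                      calibrate = FALSE)$fwer_cluster, numeric(1))
  expect_true(all(diff(fwer) <= 1e-12))
})

test_that("power calibration lowers alpha until the cluster FWER target holds", {
  atlas <- lattice_atlas_1(2, 10)
  # no FP cluster anywhere: threshold stays at the Bonferroni level
  clean <- lapply(1:10, function(i) {
    pv <- rep(0.5, 20); pv[1] <- 1e-30
    list(res = fake_result(pv), truth = 0L)
  })
  cal <- calibrate_power(clean, atlas, alpha0 = 1e-3)
  expect_equal(cal$alpha, 1e-3)
  expect_equal(cal$power, 1)

  # exactly half the replicates carry one FP cluster at p = 3e-7: reaching
  # cluster FWER <= 0.2 requires alpha below that, hence below 1e-6
  mixed <- lapply(1:10, function(i) {
    pv <- rep(0.5, 20); pv[1] <- 1e-30
    if (i <= 5) pv[19] <- 3e-7
    list(res = fake_result(pv), truth = 0L)
  })
  cal2 <- calibrate_power(mixed, atlas, alpha0 = 1e-3, target_cfwer = 0.2)
  expect_lt(cal2$alpha, 1e-6)
  expect_false(cal2$flagged)
  expect_equal(cal2$power, 1)   # the TP vertex survives any threshold here

  # monotonicity in the target: a looser cluster-FWER target cannot reduce
  # power
  cal_strict <- calibrate_power(mixed, atlas, alpha0 = 1e-3,
                                target_cfwer = 0.05)
  expect_gte(cal2$power, cal_strict$power)
  expect_gte(cal2$alpha, cal_strict$alpha)
})
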