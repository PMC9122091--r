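#' Configuration of a full simulation experiment
#'
#' Bundles a generator configuration, a scenario table (rows as produced by
#' [scenario_grid()]), the models to run, the significance policy, and the
#' output directory for caches and summary tables.
#'
#' @param generator a [generator_config()].
#' @param scenarios data.frame with columns `scenario`, `m_causal`,
#'   `target_r2`, `type_restriction` (one row per scenario; replicates are
#'   expanded internally).
#' @param replicates replicates per scenario (>= 1).
#' @param models list of [model_spec()] (default [default_model_suite()]).
#' @param alpha vertexwise threshold; default `bonferroni_alpha(p)`.
#' @param target_cfwer cluster-FWER level for power calibration.
#' @param output_dir directory for per-replicate caches and summary TSVs.
#' @param base_seed seed base; replicate `r` of scenario block `s` uses
#'   trait seed `base_seed + 10000 * s + r`, the cohort uses `base_seed`,
#'   and the replication cohort `base_seed + 900000`.
#' @param with_prediction also score a matched replication cohort with a
#'   top-per-cluster predictor per model (default TRUE).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(generator, scenarios, replicates,
                              models = default_model_suite(),
                              alpha = NULL, target_cfwer = 0.2,
                              output_dir = tempfile("vlmm_exp_"),
                              base_seed = 1, with_prediction = TRUE) {
  stopifnot(inherits(generator, "generator_config"),
            is.data.frame(scenarios), nrow(scenarios) >= 1,
            replicates >= 1, length(models) >= 1)
  alpha <- alpha %||% bonferroni_alpha(generator$p)
  structure(list(generator = generator, scenarios = scenarios,
                 replicates = as.integer(replicates), models = models,
                 alpha = alpha, target_cfwer = target_cfwer,
                 output_dir = output_dir, base_seed = as.integer(base_seed),
                 with_prediction = isTRUE(with_prediction)),
            class = "experiment_config")
}

# One replicate of one scenario: simulate the trait, run every model,
# cluster at cfg$alpha, optionally score the replication cohort.
run_one_replicate <- function(cfg, data, atlas, row, rep_env) {
  trait <- simulate_from_row(data, row, atlas)
  suite <- run_model_suite(trait$y, data, atlas, cfg$models)
  out <- list(truth = trait$causal_ids, seed = row$seed, models = list())
  for (nm in names(suite$results)) {
    res <- suite$results[[nm]]
    cs <- threshold_and_cluster(res, atlas, cfg$alpha, trait$causal_ids)
    pr <- NA_real_
    if (cfg$with_prediction && !is.null(rep_env) && length(cs$clusters) &&
        length(trait$causal_ids)) {
      pred <- build_predictor(res, cs, "top_per_cluster", data)
      sc <- score_cohort(pred, rep_env$raw)
      y_rep <- apply_trait(trait, rep_env$std, seed = row$seed + 1L)
      pr <- evaluate_prediction(sc, y_rep$y)$r
    }
    out$models[[nm]] <- list(res = res, clusters = cs, pred_r = pr)
  }
  out
}

#' Run a simulation experiment end to end
#'
#' Generates the cohort (and a matched replication cohort for prediction),
#' simulates `replicates` traits per scenario, runs every model, and
#' aggregates one [replicate_metrics()] row per (scenario, model), including
#' mean out-of-sample prediction accuracy. Per-replicate results are cached
#' under `output_dir/cache` as RDS files and reloaded on re-run, making the
#' experiment resumable; a `summary.tsv` and a seed/timing log are written
#' to `output_dir`. Deterministic given `base_seed`.
#'
#' @param cfg an [experiment_config()].
#' @return Invisibly, a list with `summary` (data.frame) and `metrics`
#'   (nested list scenario -> model -> `metrics_report`).
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  dir.create(file.path(cfg$output_dir, "cache"), recursive = TRUE,
             showWarnings = FALSE)
  gen <- generate_cohort(cfg$generator, seed = cfg$base_seed)
  data <- standardize_columns(gen$cohort)
  atlas <- gen$atlas
  rep_env <- NULL
  if (cfg$with_prediction) {
    raw_rep <- generate_replication(cfg$generator, gen$latent,
                                    seed2 = cfg$base_seed + 900000L)
    rep_env <- list(raw = raw_rep, std = standardize_columns(raw_rep))
  }
  log_lines <- character(0)
  metrics <- list()
  summary_rows <- list()
  for (s in seq_len(nrow(cfg$scenarios))) {
    row0 <- cfg$scenarios[s, , drop = FALSE]
    sc_name <- row0$scenario
    reps <- vector("list", cfg$replicates)
    for (r in seq_len(cfg$replicates)) {
      row <- row0
      row$replicate <- r
      row$seed <- cfg$base_seed + 10000L * s + r
      cache_file <- file.path(cfg$output_dir, "cache",
                              sprintf("%s_r%03d.rds", sc_name, r))
      if (file.exists(cache_file)) {
        reps[[r]] <- readRDS(cache_file)
        log_lines <- c(log_lines, sprintf("%s\t%d\t%d\tcached", sc_name, r,
                                          row$seed))
      } else {
        t0 <- proc.time()[["elapsed"]]
        reps[[r]] <- run_one_replicate(cfg, data, atlas, row, rep_env)
        saveRDS(reps[[r]], cache_file)
        log_lines <- c(log_lines,
                       sprintf("%s\t%d\t%d\t%.2fs", sc_name, r, row$seed,
                               proc.time()[["elapsed"]] - t0))
      }
    }
    metrics[[sc_name]] <- list()
    for (nm in names(cfg$models)) {
      model_reps <- lapply(reps, function(z)
        list(res = z$models[[nm]]$res, clusters = z$models[[nm]]$clusters,
             truth = z$truth))
      m <- replicate_metrics(model_reps, atlas, cfg$alpha,
                             target_cfwer = cfg$target_cfwer)
      pred_rs <- vapply(reps, function(z) z$models[[nm]]$pred_r, numeric(1))
      metrics[[sc_name]][[nm]] <- m
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        scenario = sc_name, model = nm, n_replicates = m$n_replicates,
        lambda = m$lambda, fpr_nominal = m$fpr_nominal, tpr = m$tpr,
        fwer_vertex = m$fwer_vertex, fwer_cluster = m$fwer_cluster,
        fdr_cluster = m$fdr_cluster, fdr_cluster_mean = m$fdr_cluster_mean,
        precision_median = m$precision_median,
        precision_max = m$precision_max,
        power_at_cfwer = m$power_at_cfwer,
        calibrated_alpha = m$calibrated_alpha,
        pred_r_mean = if (all(is.na(pred_rs))) NA_real_
                      else mean(pred_rs, na.rm = TRUE))
    }
  }
  summary <- do.call(rbind, summary_rows)
  data.table::fwrite(summary, file.path(cfg$output_dir, "summary.tsv"),
                     sep = "\t", na = "NA")
  writeLines(c("scenario\treplicate\tseed\ttime", log_lines),
             file.path(cfg$output_dir, "log.tsv"))
  invisible(list(summary = summary, metrics = metrics))
}

#' Null-hypothesis calibration suite
#'
#' Restricts [run_experiment()] to null traits: simulates `replicates`
#' phenotypes independent of all vertices, runs every model and returns a
#' [replicate_metrics()] report per model (lambda, nominal FPR, vertex and
#' cluster FWER at the Bonferroni threshold).
#'
#' @param cfg an [experiment_config()] (its `scenarios` are ignored).
#' @return A list of `metrics_report`, one per model.
#' @export
h0_suite <- function(cfg) {
  cfg$scenarios <- data.frame(scenario = "null", m_causal = 0L,
                              target_r2 = 0,
                              type_restriction = NA_character_)
  cfg$with_prediction <- FALSE
  out <- run_experiment(cfg)
  out$metrics$null
}

#' Null-trait calibration study at desk scale
#'
#' Generates one confounded cohort, simulates null traits, runs the model
#' suite and aggregates vertex FWER (at the Bonferroni threshold), nominal
#' FPR and inflation factor per model. This is the standing calibration
#' check: null traits are independent of the data, so every model should be
#' calibrated regardless of the correlation structure.
#'
#' @param seed base seed; the cohort uses `seed`, trait `r` uses
#'   `seed * 1000 + r`.
#' @param N,p cohort size (p must have a lattice preset or use
#'   `grid_dims`).
#' @param confounder_share latent-factor variance share.
#' @param n_traits number of null traits (default 100).
#' @param models models to run (default all eight).
#' @param grid_dims optional explicit lattice sizes.
#' @return A list with `metrics` (per model), `alpha`, `atlas`.
#' @export
h0_calibration_study <- function(seed = 1, N = 1000, p = 5000,
                                 confounder_share = 0.3, n_traits = 100,
                                 models = default_model_suite(),
                                 grid_dims = NULL) {
  cfg <- generator_config(N = N, p = p, grid_dims = grid_dims,
                          confounder_share = confounder_share, seed = seed)
  gen <- generate_cohort(cfg)
  data <- standardize_columns(gen$cohort)
  atlas <- gen$atlas
  alpha <- bonferroni_alpha(atlas$p)
  per_model <- lapply(models, function(m) vector("list", n_traits))
  for (r in seq_len(n_traits)) {
    y <- simulate_null(N, seed = seed * 1000L + r)
    suite <- run_model_suite(y$y, data, atlas, models)
    for (nm in names(suite$results))
      per_model[[nm]][[r]] <- list(res = suite$results[[nm]],
                                   truth = integer(0))
  }
  metrics <- lapply(per_model, function(reps)
    replicate_metrics(reps, atlas, alpha, calibrate = FALSE))
  list(metrics = metrics, alpha = alpha, atlas = atlas)
}

#' GLM-versus-LMM contrast study under correlated associated vertices
#'
#' The headline simulation contrast: traits truly associated with a set of
#' vertices embedded in a correlated (confounded) cohort. GLMs leak the
#' association into correlated null vertices (inflated nominal FPR and many
#' false-positive clusters) while the global-BRM LMM, by conditioning on all
#' vertices, keeps the null-vertex FPR at its nominal level and the cluster
#' FDR low.
#'
#' @param seed base seed; the cohort uses `seed`, trait `r` uses
#'   `seed * 1000 + r`.
#' @param N,p,confounder_share,grid_dims cohort settings.
#' @param m_causal,target_r2 trait scenario (default scenario (ii): 100
#'   causal vertices, morphometricity 0.50).
#' @param n_traits number of replicates (default 50).
#' @param models models to contrast; defaults to the no-covariate GLM, the
#'   age/sex/ICV GLM and the global-BRM LMM.
#' @param calibrate run power calibration within [replicate_metrics()].
#' @return A list with `metrics` (per model), `alpha`, `atlas`.
#' @export
glm_lmm_contrast_study <- function(seed = 3, N = 1000, p = 5000,
                                   confounder_share = 0.3, m_causal = 100,
                                   target_r2 = 0.5, n_traits = 50,
                                   models = NULL, grid_dims = NULL,
                                   calibrate = FALSE) {
  if (is.null(models)) {
    models <- list(model_spec("glm", "none"),
                   model_spec("glm", "age_sex_icv"),
                   model_spec("lmm", "none", "global"))
    names(models) <- vapply(models, `[[`, character(1), "name")
  }
  cfg <- generator_config(N = N, p = p, grid_dims = grid_dims,
                          confounder_share = confounder_share, seed = seed)
  gen <- generate_cohort(cfg)
  data <- standardize_columns(gen$cohort)
  atlas <- gen$atlas
  alpha <- bonferroni_alpha(atlas$p)
  per_model <- lapply(models, function(m) vector("list", n_traits))
  for (r in seq_len(n_traits)) {
    trait <- simulate_trait(data, trait_spec(m_causal, target_r2,
                                             seed = seed * 1000L + r))
    suite <- run_model_suite(trait$y, data, atlas, models)
    for (nm in names(suite$results))
      per_model[[nm]][[r]] <- list(res = suite$results[[nm]],
                                   truth = trait$causal_ids)
  }
  metrics <- lapply(per_model, function(reps)
    replicate_metrics(reps, atlas, alpha, calibrate = calibrate))
  list(metrics = metrics, alpha = alpha, atlas = atlas)
}

#' Morphometricity recovery study
#'
#' Simulates traits at a known morphometricity from a confounded cohort and
#' re-estimates it with a single-global-BRM REML fit per trait; reports the
#' per-trait estimates and their mean. Because the BRM eigendecomposition is
#' shared across traits, each fit is cheap.
#'
#' @param seed base seed; the cohort uses `seed`, trait `r` of scenario `s`
#'   uses `seed * 1000 + 10000 * s + r`.
#' @param N,p,confounder_share,grid_dims cohort settings.
#' @param scenarios data.frame with columns `scenario`, `m_causal`,
#'   `target_r2`; defaults to scenarios (i) and (ii).
#' @param n_traits traits per scenario (default 20).
#' @return A list with `estimates` (scenario -> numeric vector) and
#'   `means` (named numeric).
#' @export
morphometricity_recovery_study <- function(seed = 2, N = 2000, p = 10000,
                                           confounder_share = 0.3,
                                           scenarios = NULL, n_traits = 20,
                                           grid_dims = NULL) {
  if (is.null(scenarios))
    scenarios <- data.frame(scenario = c("i", "ii"),
                            m_causal = c(10L, 100L),
                            target_r2 = c(0.20, 0.50))
  cfg <- generator_config(N = N, p = p, grid_dims = grid_dims,
                          confounder_share = confounder_share, seed = seed)
  gen <- generate_cohort(cfg)
  data <- standardize_columns(gen$cohort)
  brm <- cohort_brms(data, "global")[[1L]]
  estimates <- list()
  for (s in seq_len(nrow(scenarios))) {
    est <- numeric(n_traits)
    for (r in seq_len(n_traits)) {
      trait <- simulate_trait(data,
                              trait_spec(scenarios$m_causal[s],
                                         scenarios$target_r2[s],
                                         seed = seed * 1000L +
                                           10000L * s + r))
      est[r] <- fit_reml(trait$y, NULL, brm)$morphometricity
    }
    estimates[[scenarios$scenario[s]]] <- est
  }
  list(estimates = estimates,
       means = vapply(estimates, mean, numeric(1)))
}
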