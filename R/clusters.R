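#' Bonferroni-corrected significance threshold
#'
#' `base / (n_tests * n_phenotypes)`; with the full vertex census of 652,283
#' measurements this gives the brain-wide threshold 7.7e-8 (0.05/652,283),
#' and 1.5e-8 when further correcting for five phenotypes.
#'
#' @param n_tests number of vertexwise tests (>= 1).
#' @param base familywise error target (default 0.05).
#' @param n_phenotypes number of phenotypes analysed (default 1).
#' @return The per-test significance threshold.
#' @export
bonferroni_alpha <- function(n_tests, base = 0.05, n_phenotypes = 1) {
  if (n_tests < 1) stop("n_tests must be at least 1")
  base / (n_tests * n_phenotypes)
}

#' Threshold an association scan and form mesh clusters
#'
#' Significant vertices (`p < alpha`) are grouped into maximal connected
#' components of the atlas adjacency; since edges never cross measurement
#' types, hemispheres or structures, neither do clusters. A cluster is
#' labelled `TP` if it contains a truly causal vertex (which, being a
#' member, is significant) and `FP` otherwise. Singleton clusters are
#' allowed. Ties for the top (most significant) vertex break to the lowest
#' vertex id.
#'
#' @param res an `assoc_result`.
#' @param atlas the matching [vertex_atlas()].
#' @param alpha significance threshold.
#' @param truth integer vector of causal vertex ids (0-based); empty under
#'   the null.
#' @return An object of class `cluster_set`: a list with `clusters` (list of
#'   `members`, `meas_type`, `hemisphere`, `top_vertex`, `size`, `label`)
#'   and `alpha_used`.
#' @export
threshold_and_cluster <- function(res, atlas, alpha,
                                  truth = integer(0)) {
  stopifnot(inherits(res, "assoc_result"))
  if (nrow(res$tbl) != atlas$p) stop("result/atlas length mismatch")
  sig <- which(res$tbl$pval < alpha)            # 1-based indices
  clusters <- list()
  if (length(sig)) {
    g <- atlas_graph(atlas)
    sub <- igraph::induced_subgraph(g, sig)
    comp <- igraph::components(sub)
    truth1 <- truth + 1L
    for (ci in seq_len(comp$no)) {
      members1 <- sig[comp$membership == ci]
      pvals <- res$tbl$pval[members1]
      top1 <- members1[order(pvals, members1)[1L]]
      clusters[[ci]] <- list(
        members = sort(members1) - 1L,
        meas_type = atlas$vertices$meas_type[members1[1L]],
        hemisphere = atlas$vertices$hemisphere[members1[1L]],
        top_vertex = top1 - 1L,
        size = length(members1),
        label = if (any(members1 %in% truth1)) "TP" else "FP")
    }
  }
  structure(list(clusters = clusters, alpha_used = alpha),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  labs <- vapply(x$clusters, `[[`, character(1), "label")
  cat("cluster_set:", length(x$clusters), "clusters (",
      sum(labs == "TP"), "TP,", sum(labs == "FP"), "FP ) at alpha =",
      format(x$alpha_used, digits = 4), "\n")
  invisible(x)
}

#' Inflation factor of association statistics
#'
#' Ratio of the empirical median chi-square over the theoretical
#' chi-square(1) median (0.4549364); 1 for calibrated tests, above 1 under
#' inflation.
#'
#' @param chi2 chi-square statistics of null (non-associated) vertices.
#' @return The inflation factor lambda.
#' @export
inflation_factor <- function(chi2) {
  if (!length(chi2)) stop("empty chi-square vector")
  stats::median(chi2) / CHISQ1_MEDIAN
}

# Internal: per-replicate significance bookkeeping reused by the metric
# aggregators. Each replicate is a list(res=assoc_result, truth=integer ids).
replicate_flags <- function(rep, atlas, alpha) {
  p <- nrow(rep$res$tbl)
  truth1 <- rep$truth + 1L
  null1 <- setdiff(seq_len(p), truth1)
  sig <- rep$res$tbl$pval < alpha
  list(null1 = null1, truth1 = truth1, sig = sig)
}

#' Aggregate evaluation metrics over simulation replicates
#'
#' Computes, over a set of replicates of one model: the mean inflation
#' factor on null vertices (with its between-replicate standard error);
#' the nominal FPR (null vertices with p < 0.05);
#' the TPR at `alpha`; the vertex-level FWER (replicates with at least one
#' significant null vertex); the cluster FWER (replicates with at least one
#' FP cluster); the pooled cluster FDR (FP clusters / significant clusters,
#' pooled over replicates, NA when nothing is significant) along with the
#' mean of per-replicate FDRs; the median and max TP-cluster size (mapping
#' precision); the FWER-calibrated power at `target_cfwer`; and the
#' per-measurement-type vertex FWER.
#'
#' @param replicates list of replicates, each `list(res = assoc_result,
#'   truth = integer causal ids)`.
#' @param atlas the matching [vertex_atlas()].
#' @param alpha vertexwise significance threshold (e.g.
#'   [bonferroni_alpha()]).
#' @param target_cfwer cluster-FWER level for power calibration
#'   (default 0.2); set `calibrate = FALSE` to skip.
#' @param calibrate run [calibrate_power()].
#' @return An object of class `metrics_report`.
#' @export
replicate_metrics <- function(replicates, atlas, alpha,
                              target_cfwer = 0.2, calibrate = TRUE) {
  stopifnot(length(replicates) >= 1)
  R <- length(replicates)
  lam <- fpr <- tpr <- fw_v <- fw_c <- fdr_r <- rep(NA_real_, R)
  tp_sizes <- integer(0)
  n_fp_cluster <- n_cluster <- 0L
  types <- MEAS_TYPES
  per_type_hit <- matrix(FALSE, R, length(types),
                         dimnames = list(NULL, types))
  vtype <- atlas$vertices$meas_type
  for (r in seq_len(R)) {
    rep_ <- replicates[[r]]
    fl <- replicate_flags(rep_, atlas, alpha)
    chi2_null <- rep_$res$tbl$chi2[fl$null1]
    lam[r] <- inflation_factor(chi2_null)
    fpr[r] <- mean(rep_$res$tbl$pval[fl$null1] < 0.05)
    if (length(fl$truth1))
      tpr[r] <- mean(fl$sig[fl$truth1])
    fw_v[r] <- any(fl$sig[fl$null1])
    for (tp in types)
      per_type_hit[r, tp] <- any(fl$sig[fl$null1][vtype[fl$null1] == tp])
    cs <- rep_$clusters %||%
      threshold_and_cluster(rep_$res, atlas, alpha, rep_$truth)
    labs <- vapply(cs$clusters, `[[`, character(1), "label")
    sizes <- vapply(cs$clusters, `[[`, numeric(1), "size")
    n_cluster <- n_cluster + length(labs)
    n_fp_cluster <- n_fp_cluster + sum(labs == "FP")
    fw_c[r] <- any(labs == "FP")
    fdr_r[r] <- if (length(labs)) mean(labs == "FP") else NA_real_
    tp_sizes <- c(tp_sizes, sizes[labs == "TP"])
  }
  cal <- list(alpha = NA_real_, power = NA_real_, flagged = FALSE)
  if (calibrate && any(vapply(replicates, function(z) length(z$truth) > 0,
                              logical(1))))
    cal <- calibrate_power(replicates, atlas, alpha,
                           target_cfwer = target_cfwer)
  structure(list(
    lambda = mean(lam),
    lambda_se = if (R > 1) stats::sd(lam) / sqrt(R) else NA_real_,
    fpr_nominal = mean(fpr),
    tpr = if (all(is.na(tpr))) NA_real_ else mean(tpr, na.rm = TRUE),
    fwer_vertex = mean(fw_v), fwer_cluster = mean(fw_c),
    fdr_cluster = if (n_cluster) n_fp_cluster / n_cluster else NA_real_,
    fdr_cluster_mean = if (all(is.na(fdr_r))) NA_real_
                       else mean(fdr_r, na.rm = TRUE),
    precision_median = if (length(tp_sizes)) stats::median(tp_sizes)
                       else NA_real_,
    precision_max = if (length(tp_sizes)) max(tp_sizes) else NA_real_,
    power_at_cfwer = cal$power, calibrated_alpha = cal$alpha,
    calibration_flagged = cal$flagged,
    per_type_fwer = colMeans(per_type_hit),
    alpha_used = alpha, n_replicates = R), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    paste0("metrics_report (%d replicates, alpha %.3g):\n",
           "  lambda %.3f  FPR %.4f  TPR %s\n",
           "  vertex FWER %.3f  cluster FWER %.3f  cluster FDR %s\n",
           "  TP-cluster size median %s max %s  power@cFWER %s\n"),
    x$n_replicates, x$alpha_used, x$lambda, x$fpr_nominal,
    format(x$tpr, digits = 3), x$fwer_vertex, x$fwer_cluster,
    format(x$fdr_cluster, digits = 3),
    format(x$precision_median, digits = 3),
    format(x$precision_max, digits = 3),
    format(x$power_at_cfwer, digits = 3)))
  invisible(x)
}

# Cluster FWER of a replicate set at a given alpha.
cluster_fwer_at <- function(replicates, atlas, alpha) {
  hits <- vapply(replicates, function(rep_) {
    cs <- threshold_and_cluster(rep_$res, atlas, alpha, rep_$truth)
    any(vapply(cs$clusters, `[[`, character(1), "label") == "FP")
  }, logical(1))
  mean(hits)
}

tpr_at <- function(replicates, alpha) {
  mean(vapply(replicates, function(rep_) {
    if (!length(rep_$truth)) return(NA_real_)
    mean(rep_$res$tbl$pval[rep_$truth + 1L] < alpha)
  }, numeric(1)), na.rm = TRUE)
}

#' Calibrate the significance threshold to a target cluster FWER
#'
#' Starting from the Bonferroni threshold, iteratively lowers alpha
#' (bisection on log10 alpha, bracketed to 0.1 log10 units) until the
#' cluster FWER across replicates is at or below `target_cfwer`; the
#' calibrated power is the TPR at the resulting threshold. If even the
#' smallest representable threshold cannot reach the target, power is 0 and
#' the result is flagged.
#'
#' @param replicates as in [replicate_metrics()].
#' @param atlas the matching [vertex_atlas()].
#' @param alpha0 starting (Bonferroni) threshold.
#' @param target_cfwer cluster-FWER target (default 0.2).
#' @return A list `alpha` (calibrated threshold), `power`, `flagged`.
#' @export
calibrate_power <- function(replicates, atlas, alpha0, target_cfwer = 0.2) {
  if (cluster_fwer_at(replicates, atlas, alpha0) <= target_cfwer)
    return(list(alpha = alpha0, power = tpr_at(replicates, alpha0),
                flagged = FALSE))
  lhi <- log10(alpha0)            # failing (too liberal)
  llo <- lhi
  repeat {
    llo <- llo - 1
    if (llo < -280)
      return(list(alpha = 10^llo, power = 0, flagged = TRUE))
    if (cluster_fwer_at(replicates, atlas, 10^llo) <= target_cfwer) break
  }
  while (lhi - llo > 0.1) {
    mid <- (lhi + llo) / 2
    if (cluster_fwer_at(replicates, atlas, 10^mid) <= target_cfwer)
      llo <- mid
    else lhi <- mid
  }
  alpha_star <- 10^llo
  list(alpha = alpha_star, power = tpr_at(replicates, alpha_star),
       flagged = FALSE)
}
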