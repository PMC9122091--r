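#' Build a linear predictor from significant vertices
#'
#' Selects either the most significant vertex of each cluster
#' (`"top_per_cluster"`, ties to the lowest vertex id) or every cluster
#' member (`"all_significant"`), and freezes the marginal association
#' weights together with the training-cohort standardization statistics of
#' the selected vertices, so the predictor can be applied to raw test data
#' without any test-sample leakage.
#'
#' @param res the `assoc_result` the clusters were derived from.
#' @param clusters a [threshold_and_cluster()] result.
#' @param mode `"top_per_cluster"` or `"all_significant"`.
#' @param data the training [cohort_matrix()] (standardized; supplies
#'   `col_means`/`col_sds`).
#' @return An object of class `vertex_predictor` with `vertex_ids`
#'   (0-based), `weights`, `train_means`, `train_sds`, `mode`,
#'   `source_model`.
#' @export
build_predictor <- function(res, clusters,
                            mode = c("top_per_cluster", "all_significant"),
                            data = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(res, "assoc_result"), inherits(clusters, "cluster_set"))
  if (!length(clusters$clusters))
    stop("no predictor available: no significant clusters")
  ids <- if (mode == "top_per_cluster")
    vapply(clusters$clusters, `[[`, numeric(1), "top_vertex")
  else
    unlist(lapply(clusters$clusters, `[[`, "members"))
  ids <- sort(unique(as.integer(ids)))
  w <- res$tbl$b[ids + 1L]
  mu <- sds <- NULL
  if (!is.null(data)) {
    if (is.null(data$col_means))
      stop("training cohort has no standardization statistics recorded")
    mu <- data$col_means[ids + 1L]
    sds <- data$col_sds[ids + 1L]
  } else {
    mu <- rep(0, length(ids))
    sds <- rep(1, length(ids))
  }
  structure(list(vertex_ids = ids, weights = w, train_means = mu,
                 train_sds = sds, mode = mode, source_model = res$model),
            class = "vertex_predictor")
}

#' @export
print.vertex_predictor <- function(x, ...) {
  cat("vertex_predictor (", x$mode, ", model ", x$source_model$name, "): ",
      length(x$vertex_ids), " vertices\n", sep = "")
  invisible(x)
}

#' Score a cohort with a linear predictor
#'
#' `score_j = sum_i w_i * (x_ji - train_mean_i) / train_sd_i`: the training
#' standardization is applied to the test data; test-sample statistics are
#' never used. Accepts a raw cohort (recommended) or one standardized on its
#' own sample, in which case the raw values are reconstructed from its
#' recorded statistics first.
#'
#' @param pred a [build_predictor()] object.
#' @param data a [cohort_matrix()] containing the selected vertices.
#' @return Numeric score vector, one per subject.
#' @export
score_cohort <- function(pred, data) {
  stopifnot(inherits(pred, "vertex_predictor"))
  stop_if_not_cohort(data)
  idx <- pred$vertex_ids + 1L
  if (any(idx > ncol(data$values)))
    stop("test cohort is missing predictor vertices")
  X <- data$values[, idx, drop = FALSE]
  if (isTRUE(data$standardized)) {
    # undo the test-sample standardization to recover raw values
    X <- sweep(sweep(X, 2L, data$col_sds[idx], "*"), 2L,
               data$col_means[idx], "+")
  }
  Xs <- sweep(sweep(X, 2L, pred$train_means, "-"), 2L, pred$train_sds, "/")
  as.vector(Xs %*% pred$weights)
}

#' Evaluate out-of-sample prediction accuracy
#'
#' Pearson correlation between scores and phenotype with a Fisher-z 95%
#' confidence interval, plus the partial correlation after residualizing
#' both scores and phenotype on covariates by OLS.
#'
#' @param scores predictor scores.
#' @param y observed phenotype.
#' @param covariates optional numeric matrix/data.frame of covariates.
#' @return A list `r`, `ci_low`, `ci_high`, `r_partial` (`r` is `NA` for
#'   zero-variance scores).
#' @export
evaluate_prediction <- function(scores, y, covariates = NULL) {
  stopifnot(length(scores) == length(y), length(y) >= 10)
  if (stats::sd(scores) == 0)
    return(list(r = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                r_partial = NA_real_))
  r <- stats::cor(scores, y)
  n <- length(y)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  hw <- stats::qnorm(0.975) / sqrt(n - 3)
  r_partial <- NA_real_
  if (!is.null(covariates)) {
    W <- cbind(1, as.matrix(covariates))
    rs <- stats::lm.fit(W, scores)$residuals
    ry <- stats::lm.fit(W, y)$residuals
    # covariates explaining either side completely leave nothing to
    # correlate: the partial correlation is 0 by convention
    r_partial <- if (stats::sd(rs) < 1e-10 * stats::sd(scores) ||
                     stats::sd(ry) < 1e-10 * stats::sd(y)) 0
                 else stats::cor(rs, ry)
  }
  list(r = r, ci_low = tanh(z - hw), ci_high = tanh(z + hw),
       r_partial = r_partial)
}

#' Read / write a predictor as a JSON text file
#'
#' Serializes vertex ids, weights, training means/SDs, mode and the source
#' model name.
#'
#' @param pred a [build_predictor()] object.
#' @param file path.
#' @export
write_predictor <- function(pred, file) {
  jsonlite::write_json(
    list(vertex_ids = pred$vertex_ids, weights = pred$weights,
         train_means = pred$train_means, train_sds = pred$train_sds,
         mode = pred$mode, source_model = pred$source_model$name),
    file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_predictor
#' @export
read_predictor <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  structure(list(vertex_ids = as.integer(j$vertex_ids),
                 weights = as.numeric(j$weights),
                 train_means = as.numeric(j$train_means),
                 train_sds = as.numeric(j$train_sds),
                 mode = j$mode,
                 source_model = list(name = j$source_model)),
            class = "vertex_predictor")
}
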