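#' Construct a cohort matrix
#'
#' The central data container: an N x p matrix of per-subject vertexwise
#' values, a covariate table, and the standardization state. Column `j` of
#' `values` corresponds to vertex id `j - 1` of the matching atlas.
#'
#' @param values numeric N x p matrix, no missing values.
#' @param subject_id character vector of length N, unique.
#' @param covariates optional data.frame with N rows (e.g. age/sex/ICV
#'   analogues); numeric columns only.
#' @param standardized logical; `TRUE` only when every column has mean 0 and
#'   denominator-N variance 1.
#' @param col_means,col_sds standardization statistics recorded when
#'   [standardize_columns()] was applied (needed to apply training-scale
#'   standardization to new cohorts).
#' @return An object of class `cohort_matrix`.
#' @export
cohort_matrix <- function(values, subject_id = NULL, covariates = NULL,
                          standardized = FALSE, col_means = NULL,
                          col_sds = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("cohort values must not contain missing values")
  n <- nrow(values)
  if (is.null(subject_id)) subject_id <- sprintf("S%05d", seq_len(n))
  subject_id <- as.character(subject_id)
  if (length(subject_id) != n) stop("subject_id length mismatch")
  if (anyDuplicated(subject_id)) stop("subject ids must be unique")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariate table row mismatch")
    if (anyNA(covariates)) stop("covariates must not contain missing values")
  }
  structure(list(values = values, subject_id = subject_id,
                 covariates = covariates,
                 standardized = isTRUE(standardized),
                 col_means = col_means, col_sds = col_sds,
                 cache = new.env(parent = emptyenv())),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat("cohort_matrix:", nrow(x$values), "subjects x", ncol(x$values),
      "vertices;", if (x$standardized) "standardized" else "raw", "\n")
  if (!is.null(x$covariates))
    cat("covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.cohort_matrix <- function(x) dim(x$values)

#' Standardize vertex columns to mean 0, variance 1
#'
#' Each column is centred and scaled to unit variance with denominator N
#' (population variance), the convention under which the brain-relatedness
#' matrix B = XX'/p has mean diagonal exactly 1 and the per-BRM variance
#' component is directly the variance share captured by those vertices.
#' Column means and SDs are recorded for later out-of-sample reuse.
#'
#' @param data a raw [cohort_matrix()].
#' @return A standardized `cohort_matrix`.
#' @export
standardize_columns <- function(data) {
  stop_if_not_cohort(data)
  if (isTRUE(data$standardized)) stop("cohort is already standardized")
  X <- data$values
  n <- nrow(X)
  mu <- colMeans(X)
  X <- sweep(X, 2L, mu, "-")
  sd_n <- sqrt(colMeans(X^2))
  bad <- which(sd_n <= 0 | !is.finite(sd_n))
  if (length(bad))
    stop("constant vertex column(s), vertex id(s): ",
         paste(utils::head(bad - 1L, 5L), collapse = ", "))
  X <- sweep(X, 2L, sd_n, "/")
  out <- data
  out$values <- X
  out$standardized <- TRUE
  out$col_means <- mu
  out$col_sds <- sd_n
  out$cache <- new.env(parent = emptyenv())
  out
}

#' Compute a brain-relatedness matrix (BRM)
#'
#' The BRM of a set of standardized vertices is B = X X' / p, the
#' subject-by-subject similarity of gray-matter structure over those
#' vertices. With denominator-N standardization, `mean(diag(B)) == 1`.
#'
#' @param data a standardized [cohort_matrix()].
#' @param subset either `NULL` (all vertices), a vector of 0-based vertex
#'   ids, or one of [MEAS_TYPES] (requires `atlas`).
#' @param atlas atlas used to resolve a measurement-type subset.
#' @param component_label label stored on the BRM (defaults to `"global"` or
#'   the type name).
#' @return An object of class `brm` with fields `matrix` (N x N), `p_used`
#'   and `component_label`.
#' @export
compute_brm <- function(data, subset = NULL, atlas = NULL,
                        component_label = NULL) {
  stop_if_not_cohort(data)
  if (!isTRUE(data$standardized)) stop("standardize the cohort first")
  if (is.character(subset) && length(subset) == 1L &&
      subset %in% MEAS_TYPES) {
    if (is.null(atlas)) stop("an atlas is required for a type subset")
    component_label <- component_label %||% subset
    subset <- atlas_type_ids(atlas, subset)
  }
  if (is.null(subset)) {
    Xs <- data$values
    component_label <- component_label %||% "global"
  } else {
    subset <- as.integer(subset)
    if (!length(subset)) stop("empty vertex subset")
    if (any(subset < 0L) || any(subset >= ncol(data$values)))
      stop("vertex subset out of range")
    Xs <- data$values[, subset + 1L, drop = FALSE]
    component_label <- component_label %||% "subset"
  }
  p_used <- ncol(Xs)
  B <- tcrossprod(Xs) / p_used
  structure(list(matrix = B, p_used = p_used,
                 component_label = component_label,
                 cache = new.env(parent = emptyenv())),
            class = "brm")
}

#' @export
print.brm <- function(x, ...) {
  cat("brm (", x$component_label, "): ", nrow(x$matrix), " subjects, built",
      " from ", x$p_used, " vertices\n", sep = "")
  invisible(x)
}

# Eigendecomposition of a BRM, cached. Used by the spectral REML path and by
# principal-component extraction; eigenvalues are clipped at 0 (B is PSD up
# to roundoff).
brm_eigen <- function(brm) {
  e <- brm$cache$eigen
  if (is.null(e)) {
    e <- eigen(brm$matrix, symmetric = TRUE)
    e$values <- pmax(e$values, 0)
    brm$cache$eigen <- e
  }
  e
}

# Cached global / per-type BRMs of a cohort.
cohort_brms <- function(data, structure = c("global", "per_type_4"),
                        atlas = NULL) {
  structure <- match.arg(structure)
  key <- paste0("brms_", structure)
  b <- data$cache[[key]]
  if (is.null(b)) {
    if (structure == "global") {
      b <- list(global = compute_brm(data))
    } else {
      if (is.null(atlas)) stop("atlas needed for per-type BRMs")
      b <- lapply(MEAS_TYPES, function(tp) compute_brm(data, tp, atlas))
      names(b) <- MEAS_TYPES
    }
    data$cache[[key]] <- b
  }
  b
}

#' Principal components of gray-matter variation
#'
#' Top-k left singular components of the standardized matrix (equivalently,
#' eigenvectors of N*B). Scores are the projections U_k d_k used as GLM
#' covariates; `variance_explained` is each component's share of the total
#' variance of the (sub)matrix. With `scope = "per_type"`, k components are
#' extracted per measurement type and concatenated (the "modality-specific
#' PCs" covariate set uses k = 10 per type).
#'
#' @param data a standardized [cohort_matrix()].
#' @param k number of components (per type when `scope = "per_type"`);
#'   must satisfy `0 < k <= min(N - 1, p)`.
#' @param scope `"global"` or `"per_type"`.
#' @param atlas required for `scope = "per_type"`.
#' @return An object of class `pc_set` with `scores`, `loadings`,
#'   `variance_explained` and `scope`.
#' @export
compute_pcs <- function(data, k, scope = c("global", "per_type"),
                        atlas = NULL) {
  stop_if_not_cohort(data)
  if (!isTRUE(data$standardized)) stop("standardize the cohort first")
  scope <- match.arg(scope)
  if (k <= 0) stop("k must be positive")
  n <- nrow(data$values)
  one_block <- function(ids, label) {
    Xs <- data$values[, ids + 1L, drop = FALSE]
    if (k > min(n - 1L, ncol(Xs)))
      stop("k exceeds min(N - 1, p) for block ", label)
    ee <- eigen(tcrossprod(Xs), symmetric = TRUE)
    ev <- pmax(ee$values, 0)
    d <- sqrt(ev[seq_len(k)])
    U <- ee$vectors[, seq_len(k), drop = FALSE]
    scores <- U %*% diag(d, k)
    colnames(scores) <- paste0("pc", seq_len(k), "_", label)
    loadings <- crossprod(Xs, U) %*% diag(ifelse(d > 0, 1 / d, 0), k)
    list(scores = scores, loadings = loadings,
         ve = ev[seq_len(k)] / sum(ev))
  }
  if (scope == "global") {
    bl <- one_block(0:(ncol(data$values) - 1L), "global")
    out <- list(scores = bl$scores, loadings = bl$loadings,
                variance_explained = bl$ve, scope = scope)
  } else {
    if (is.null(atlas)) stop("atlas needed for per-type PCs")
    blocks <- lapply(MEAS_TYPES, function(tp)
      one_block(atlas_type_ids(atlas, tp), tp))
    out <- list(scores = do.call(cbind, lapply(blocks, `[[`, "scores")),
                loadings = lapply(blocks, `[[`, "loadings"),
                variance_explained = unlist(lapply(blocks, `[[`, "ve")),
                scope = scope)
  }
  class(out) <- "pc_set"
  out
}

#' Read / write a cohort as TSV
#'
#' The matrix file is a TSV with a `subject_id` column followed by one column
#' per vertex, named `v0 ... v<p-1>`; covariates travel in a second TSV with
#' a matching `subject_id` column.
#'
#' @param data a [cohort_matrix()].
#' @param matrix_file,covar_file file paths (`covar_file` optional).
#' @return `read_cohort` returns a `cohort_matrix` (raw; standardization
#'   state is not serialized).
#' @export
write_cohort <- function(data, matrix_file, covar_file = NULL) {
  stop_if_not_cohort(data)
  dt <- data.table::data.table(subject_id = data$subject_id)
  vals <- data.table::as.data.table(data$values)
  data.table::setnames(vals, paste0("v", seq_len(ncol(data$values)) - 1L))
  data.table::fwrite(cbind(dt, vals), matrix_file, sep = "\t")
  if (!is.null(covar_file) && !is.null(data$covariates))
    data.table::fwrite(cbind(dt, data$covariates), covar_file, sep = "\t")
  invisible(matrix_file)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(matrix_file, covar_file = NULL) {
  dt <- as.data.frame(data.table::fread(matrix_file, sep = "\t"))
  sid <- as.character(dt$subject_id)
  X <- as.matrix(dt[, -1L, drop = FALSE])
  cov <- NULL
  if (!is.null(covar_file)) {
    cv <- as.data.frame(data.table::fread(covar_file, sep = "\t"))
    if (!identical(as.character(cv$subject_id), sid))
      stop("covariate file subject ids do not match the matrix file")
    cov <- cv[, setdiff(names(cv), "subject_id"), drop = FALSE]
  }
  cohort_matrix(X, sid, covariates = cov)
}

#' Read / write phenotypes in the GCTA/OSCA 3-column dialect
#'
#' Whitespace-separated columns: family id, subject id, value; missing coded
#' `NA`. `read_phenotype` returns values aligned to `subject_id` order when
#' given, dropping missing values.
#'
#' @param y numeric phenotype vector.
#' @param subject_id subject ids (family id is reused as subject id on write).
#' @param file path.
#' @export
write_phenotype <- function(y, subject_id, file) {
  data.table::fwrite(data.table::data.table(fid = subject_id,
                                            iid = subject_id, value = y),
                     file, sep = " ", col.names = FALSE, na = "NA")
  invisible(file)
}

#' @rdname write_phenotype
#' @export
read_phenotype <- function(file, subject_id = NULL) {
  dt <- as.data.frame(data.table::fread(file, header = FALSE,
                                        col.names = c("fid", "iid",
                                                      "value")))
  if (!is.null(subject_id)) {
    idx <- match(subject_id, dt$iid)
    if (anyNA(idx)) stop("phenotype file is missing some subjects")
    dt <- dt[idx, ]
  }
  y <- dt$value
  names(y) <- dt$iid
  y[!is.na(y)]
}
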