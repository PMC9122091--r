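#' Model specification for a vertexwise association scan
#'
#' Exactly eight configurations are expressible: five GLMs (Eq.-(1)-style
#' per-vertex OLS) differing by covariate set — none; age/sex/ICV; 5 global
#' PCs; 10 global PCs; 10 PCs per measurement type — and three LMMs that
#' additionally fit all vertices as random effects through BRMs — global BRM
#' without and with age/sex/ICV covariates, and a four-component model with
#' one BRM per measurement type.
#'
#' @param family `"glm"` or `"lmm"`.
#' @param covariate_set one of `"none"`, `"age_sex_icv"`, `"pc5_global"`,
#'   `"pc10_global"`, `"pc10_per_type"` (GLM) or `"none"`, `"age_sex_icv"`
#'   (LMM).
#' @param brm_structure `"global"` or `"per_type_4"` (LMM only).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("glm", "lmm"),
                       covariate_set = "none",
                       brm_structure = c("global", "per_type_4")) {
  family <- match.arg(family)
  glm_sets <- c("none", "age_sex_icv", "pc5_global", "pc10_global",
                "pc10_per_type")
  lmm_sets <- c("none", "age_sex_icv")
  covariate_set <- match.arg(covariate_set,
                             if (family == "glm") glm_sets else lmm_sets)
  brm_structure <- if (family == "lmm") match.arg(brm_structure) else NA
  name <- if (family == "glm") paste0("glm_", covariate_set)
          else paste0("lmm_", covariate_set, "_", brm_structure)
  structure(list(family = family, covariate_set = covariate_set,
                 brm_structure = brm_structure, name = name),
            class = "model_spec")
}

#' The eight standard model configurations
#'
#' @return Named list of [model_spec()] objects: five GLMs and three LMMs.
#' @export
default_model_suite <- function() {
  specs <- list(
    model_spec("glm", "none"),
    model_spec("glm", "age_sex_icv"),
    model_spec("glm", "pc5_global"),
    model_spec("glm", "pc10_global"),
    model_spec("glm", "pc10_per_type"),
    model_spec("lmm", "none", "global"),
    model_spec("lmm", "age_sex_icv", "global"),
    model_spec("lmm", "none", "per_type_4"))
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

# Assemble the covariate matrix (without intercept) of a model spec.
# PC covariate sets draw on compute_pcs(), cached on the cohort.
spec_covariates <- function(data, spec, atlas = NULL, pcs = NULL) {
  cs <- spec$covariate_set
  if (cs == "none") return(NULL)
  if (cs == "age_sex_icv") {
    cv <- data$covariates
    need <- c("age", "sex", "icv")
    if (is.null(cv) || !all(need %in% names(cv)))
      stop("cohort covariates must contain age, sex, icv")
    return(as.matrix(cv[, need]))
  }
  k <- switch(cs, pc5_global = 5L, pc10_global = 10L, pc10_per_type = 10L)
  scope <- if (cs == "pc10_per_type") "per_type" else "global"
  if (is.null(pcs)) {
    key <- paste0("pcs_", scope, "_", k)
    pcs <- data$cache[[key]]
    if (is.null(pcs)) {
      pcs <- compute_pcs(data, k, scope = scope, atlas = atlas)
      data$cache[[key]] <- pcs
    }
  }
  pcs$scores
}

# Trait-independent part of a GLM scan for one covariate set: the thin-Q
# factor of the design [1, Z] and the residual sum of squares of every
# vertex column after projecting out the design. Cached on the cohort.
glm_design <- function(data, spec, atlas = NULL, pcs = NULL) {
  key <- paste0("glmdesign_", spec$covariate_set)
  des <- data$cache[[key]]
  if (!is.null(des)) return(des)
  Z <- spec_covariates(data, spec, atlas, pcs)
  Zf <- build_design(Z, nrow(data$values))
  Q <- qr.Q(qr(Zf))
  X <- data$values
  QtX <- crossprod(Q, X)
  xtx_resid <- colSums(X^2) - colSums(QtX^2)
  des <- list(Q = Q, xtx_resid = xtx_resid, q = ncol(Zf))
  data$cache[[key]] <- des
  des
}

assoc_result <- function(b, se, chi2, pval, flagged, model, n) {
  structure(list(tbl = data.frame(vertex_id = seq_along(b) - 1L,
                                  b = b, se = se, chi2 = chi2, pval = pval,
                                  flagged = flagged),
                 model = model, n_subjects = n),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("assoc_result:", x$model$name, "-", nrow(x$tbl), "vertices,",
      x$n_subjects, "subjects\n")
  cat("  min p =", format(min(x$tbl$pval), digits = 4),
      " median chi2 =", format(stats::median(x$tbl$chi2), digits = 4), "\n")
  invisible(x)
}

#' Per-vertex GLM association scan
#'
#' For every vertex, ordinary least squares of `y` on `[1, Z, x_i]` with the
#' covariate set named by the model spec; effect and standard error from the
#' usual OLS formulas (via the Frisch-Waugh projection, vectorized over
#' vertices), chi-square statistic `(b/SE)^2` referred to chi-square(1).
#' Vertices collinear with the covariates (residual variance below 1e-12)
#' are flagged and reported as `chi2 = 0`, `p = 1` rather than erroring
#' mid-scan.
#'
#' @param y phenotype vector.
#' @param data a standardized [cohort_matrix()].
#' @param spec a GLM [model_spec()].
#' @param pcs optional precomputed [compute_pcs()] set matching the spec.
#' @param atlas needed to compute per-type PCs when not supplied.
#' @return An `assoc_result` with per-vertex `b`, `se`, `chi2`, `pval`.
#' @export
run_glm <- function(y, data, spec = model_spec("glm", "none"), pcs = NULL,
                    atlas = NULL) {
  stop_if_not_cohort(data)
  if (!isTRUE(data$standardized)) stop("standardize the cohort first")
  stopifnot(spec$family == "glm")
  y <- as.numeric(y)
  n <- nrow(data$values)
  stopifnot(length(y) == n)
  des <- glm_design(data, spec, atlas, pcs)
  yr <- y - des$Q %*% crossprod(des$Q, y)
  yr <- as.vector(yr)
  ytyr <- sum(yr^2)
  xty <- as.vector(crossprod(data$values, yr))
  xtx <- des$xtx_resid
  df <- n - des$q - 1L
  ok <- xtx / n > 1e-12
  b <- ifelse(ok, xty / xtx, 0)
  rss <- pmax(ytyr - b * xty, 0)
  sigma2 <- rss / df
  se <- ifelse(ok, sqrt(sigma2 / xtx), NA_real_)
  # a numerically perfect fit (zero residual variance with b != 0) is an
  # infinitely significant association, not a degenerate vertex
  chi2 <- ifelse(ok, ifelse(se > 0, (b / se)^2,
                            ifelse(abs(b) > 0, Inf, 0)), 0)
  pval <- pmax(stats::pchisq(chi2, 1, lower.tail = FALSE),
               .Machine$double.xmin)
  pval[!ok] <- 1
  assoc_result(b, se, chi2, pval, !ok, spec, n)
}

#' Per-vertex LMM association scan (one-pass MOA strategy)
#'
#' Variance components are estimated once under the null model (no vertex
#' fixed effect, the candidate vertex not excluded from the BRM), then every
#' vertex is tested by generalized least squares against the fitted
#' covariance: with `P = V^-1 - V^-1 Z (Z'V^-1 Z)^-1 Z'V^-1`,
#' `b = x'Py / x'Px`, `SE^2 = 1 / x'Px`, `chi2 = (b/SE)^2`. The cost is
#' O(pN^2 + N^3) for the whole scan rather than O(pN^3) for per-vertex
#' restricted-likelihood refits. With a single global BRM the scan runs in
#' the eigenbasis of B (rotation of X cached on the BRM), costing O(pNq)
#' per trait after the one-off rotation.
#'
#' @param y phenotype vector (the same `y` the components were fitted on).
#' @param data a standardized [cohort_matrix()].
#' @param spec an LMM [model_spec()].
#' @param vc [fit_reml()] result for the matching null model.
#' @param atlas needed for `brm_structure = "per_type_4"`.
#' @return An `assoc_result`.
#' @export
run_lmm <- function(y, data, spec, vc, atlas = NULL) {
  stop_if_not_cohort(data)
  if (!isTRUE(data$standardized)) stop("standardize the cohort first")
  stopifnot(spec$family == "lmm", inherits(vc, "variance_components"))
  if (!vc$converged)
    warning("variance components did not converge; proceeding with the ",
            "final estimates")
  y <- as.numeric(y)
  n <- nrow(data$values)
  stopifnot(length(y) == n)
  brms <- cohort_brms(data, spec$brm_structure, atlas)
  if (!identical(unname(vapply(brms, `[[`, character(1), "component_label")),
                 unname(vc$brm_labels)))
    stop("variance components do not match the BRM structure of the spec")
  Z <- spec_covariates(data, spec, atlas)
  Zf <- build_design(Z, n)
  X <- data$values

  if (length(brms) == 1L) {
    brm <- brms[[1L]]
    e <- brm_eigen(brm)
    Xt <- brm$cache$rotX
    if (is.null(Xt)) {
      Xt <- crossprod(e$vectors, X)
      brm$cache$rotX <- Xt
    }
    lam <- vc$v_components[1L] * e$values + vc$v_e
    a <- 1 / lam
    yt <- as.vector(crossprod(e$vectors, y))
    Zt <- crossprod(e$vectors, Zf)
    Zl <- Zt * a
    Minv <- chol2inv(chol(crossprod(Zt, Zl)))
    Py <- as.vector(yt * a - Zl %*% (Minv %*% crossprod(Zl, yt)))
    xPy <- as.vector(crossprod(Xt, Py))
    G <- crossprod(Xt, Zl)                       # p x q
    xPx <- colSums(Xt^2 * a) - rowSums((G %*% Minv) * G)
  } else {
    V <- diag(vc$v_e, n)
    for (k in seq_along(brms))
      V <- V + vc$v_components[k] * brms[[k]]$matrix
    ch <- chol(V)
    Vinv <- chol2inv(ch)
    VZ <- Vinv %*% Zf
    Minv <- chol2inv(chol(crossprod(Zf, VZ)))
    Py <- as.vector(Vinv %*% y - VZ %*% (Minv %*% crossprod(VZ, y)))
    W <- Vinv %*% X - VZ %*% (Minv %*% crossprod(VZ, X))   # P X
    xPy <- as.vector(crossprod(X, Py))
    xPx <- colSums(X * W)
  }
  ok <- xPx > 1e-12
  b <- ifelse(ok, xPy / xPx, 0)
  se <- ifelse(ok, sqrt(1 / xPx), NA_real_)
  chi2 <- ifelse(ok, xPy^2 / xPx, 0)
  pval <- pmax(stats::pchisq(chi2, 1, lower.tail = FALSE),
               .Machine$double.xmin)
  pval[!ok] <- 1
  assoc_result(b, se, chi2, pval, !ok, spec, n)
}

#' Run the full eight-model suite on one phenotype
#'
#' Runs the five GLMs and three LMMs on the same subjects; LMM variance
#' components are fitted once per (covariate set, BRM structure) combination
#' and the fits are returned alongside the scans.
#'
#' @param y phenotype vector.
#' @param data a standardized [cohort_matrix()].
#' @param atlas the matching [vertex_atlas()].
#' @param models list of [model_spec()] (default [default_model_suite()]).
#' @param reml_opts options passed to [fit_reml()].
#' @return A list with `results` (named list of `assoc_result`) and
#'   `vc` (named list of variance-component fits keyed by LMM model name).
#' @export
run_model_suite <- function(y, data, atlas,
                            models = default_model_suite(),
                            reml_opts = reml_options()) {
  results <- list()
  vcs <- list()
  for (spec in models) {
    if (spec$family == "glm") {
      results[[spec$name]] <- run_glm(y, data, spec, atlas = atlas)
    } else {
      brms <- cohort_brms(data, spec$brm_structure, atlas)
      Z <- spec_covariates(data, spec, atlas)
      vc <- fit_reml(y, Z, brms, reml_opts)
      vcs[[spec$name]] <- vc
      results[[spec$name]] <- run_lmm(y, data, spec, vc, atlas)
    }
  }
  list(results = results, vc = vcs)
}
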