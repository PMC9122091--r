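#' Options controlling the REML fit
#'
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood (default 1e-8).
#' @param max_iter maximum number of iterations (default 100).
#' @param constraint what to do with a variance component whose update is
#'   negative twice in a row: `"truncate_to_zero"` pins it at 0 (default),
#'   `"error"` aborts.
#' @param em_fallback replace an average-information step that proposes a
#'   negative component by an expectation-maximization step (default TRUE).
#' @param verbose print per-iteration log-likelihoods.
#' @return An object of class `reml_options`.
#' @export
reml_options <- function(tol = 1e-8, max_iter = 100,
                         constraint = c("truncate_to_zero", "error"),
                         em_fallback = TRUE, verbose = FALSE) {
  stopifnot(tol > 0, max_iter >= 1)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 constraint = match.arg(constraint),
                 em_fallback = isTRUE(em_fallback),
                 verbose = isTRUE(verbose)),
            class = "reml_options")
}

# Fixed-effect design: intercept always included, plus optional covariates.
build_design <- function(Z, n) {
  if (is.null(Z)) Zf <- matrix(1, n, 1L)
  else {
    Z <- as.matrix(Z)
    storage.mode(Z) <- "double"
    Zf <- cbind(1, Z)
  }
  if (qr(Zf)$rank < ncol(Zf)) stop("covariate matrix is rank deficient")
  Zf
}

# Per-iteration REML quantities for the dense (Cholesky) path.
# theta = c(v_1, ..., v_K, v_e); Gs = list of K BRM matrices.
reml_stats_dense <- function(theta, y, Zf, Gs) {
  n <- length(y)
  K <- length(Gs)
  V <- diag(theta[K + 1L], n)
  for (k in seq_len(K)) V <- V + theta[k] * Gs[[k]]
  ch <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix not positive definite at components (",
         paste(signif(theta, 4), collapse = ", "), ")", call. = FALSE))
  logdetV <- 2 * sum(log(diag(ch)))
  Vinv <- chol2inv(ch)
  VZ <- Vinv %*% Zf
  M <- crossprod(Zf, VZ)
  Mch <- chol(M)
  Minv <- chol2inv(Mch)
  Vy <- Vinv %*% y
  Py <- Vy - VZ %*% (Minv %*% crossprod(VZ, y))
  yPy <- sum(y * Py)
  loglik <- -0.5 * (logdetV + 2 * sum(log(diag(Mch))) + yPy) -
    0.5 * (n - ncol(Zf)) * log(2 * pi)
  nc <- K + 1L
  u <- vector("list", nc)
  yPBPy <- trPB <- numeric(nc)
  for (k in seq_len(nc)) {
    if (k <= K) {
      u[[k]] <- as.vector(Gs[[k]] %*% Py)
      BVZ <- Gs[[k]] %*% VZ
      trPB[k] <- sum(Vinv * Gs[[k]]) - sum(Minv * crossprod(VZ, BVZ))
    } else {
      u[[k]] <- as.vector(Py)
      trPB[k] <- sum(diag(Vinv)) - sum(Minv * crossprod(VZ))
    }
    yPBPy[k] <- sum(Py * u[[k]])
  }
  Pu <- lapply(u, function(uk)
    as.vector(Vinv %*% uk - VZ %*% (Minv %*% crossprod(VZ, uk))))
  AI <- matrix(0, nc, nc)
  for (k in seq_len(nc)) for (l in k:nc)
    AI[k, l] <- AI[l, k] <- 0.5 * sum(u[[k]] * Pu[[l]])
  list(loglik = loglik, yPBPy = yPBPy, trPB = trPB, AI = AI)
}

# Per-iteration quantities for the spectral path (single BRM): with
# B = U diag(d) U' the rotated covariance is diagonal, lam = v_b*d + v_e,
# and every quantity costs O(N q) instead of O(N^3).
reml_stats_eigen <- function(theta, yt, Zt, d) {
  n <- length(yt)
  lam <- theta[1L] * d + theta[2L]
  if (any(lam <= 0))
    stop("covariance matrix not positive definite at components (",
         paste(signif(theta, 4), collapse = ", "), ")", call. = FALSE)
  a <- 1 / lam
  Zl <- Zt * a
  M <- crossprod(Zt, Zl)
  Mch <- chol(M)
  Minv <- chol2inv(Mch)
  Py <- yt * a - Zl %*% (Minv %*% crossprod(Zl, yt))
  Py <- as.vector(Py)
  yPy <- sum(yt * Py)
  loglik <- -0.5 * (sum(log(lam)) + 2 * sum(log(diag(Mch))) + yPy) -
    0.5 * (n - ncol(Zt)) * log(2 * pi)
  u <- list(d * Py, Py)
  yPBPy <- c(sum(Py * u[[1L]]), sum(Py * u[[2L]]))
  trPB <- c(sum(d * a) - sum(Minv * crossprod(Zl, d * Zl)),
            sum(a) - sum(Minv * crossprod(Zl, Zl)))
  Pu <- lapply(u, function(uk)
    as.vector(uk * a - Zl %*% (Minv %*% crossprod(Zl, uk))))
  AI <- matrix(0, 2L, 2L)
  for (k in 1:2) for (l in k:2)
    AI[k, l] <- AI[l, k] <- 0.5 * sum(u[[k]] * Pu[[l]])
  list(loglik = loglik, yPBPy = yPBPy, trPB = trPB, AI = AI)
}

#' Restricted log-likelihood of a variance-component model
#'
#' Evaluates the REML objective of `var(y) = sum_k v_k B_k + v_e I` with
#' fixed effects `[1, Z]` at the given components, including the constant
#' `-(N - q)/2 * log(2*pi)` term.
#'
#' @param y numeric phenotype vector.
#' @param Z optional covariate matrix (an intercept is always added).
#' @param brms a single [compute_brm()] object or a list of them.
#' @param components numeric vector `c(v_1, ..., v_K, v_e)`, all `>= 0`
#'   with positive total.
#' @return The restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(y, Z = NULL, brms, components) {
  if (inherits(brms, "brm")) brms <- list(brms)
  K <- length(brms)
  stopifnot(length(components) == K + 1L, all(components >= 0))
  Zf <- build_design(Z, length(y))
  Gs <- lapply(brms, `[[`, "matrix")
  reml_stats_dense(components, y, Zf, Gs)$loglik
}

#' Fit variance components by average-information REML
#'
#' Estimates `var(y) = sum_k v_k B_k + v_e I`, where each `B_k` is a
#' brain-relatedness matrix with mean diagonal 1 so that `v_k` is directly
#' the phenotypic variance captured by that vertex set (for a single global
#' BRM, the morphometricity). The fit starts from an equal split of
#' `var(y)`, takes one EM step and then AI (quasi-Newton) steps with
#' step-halving; an AI step proposing a negative component falls back to EM,
#' and a component whose update is negative twice in a row is pinned to zero
#' (`truncate_to_zero`). For a single BRM the model is solved in the
#' eigenbasis of B, which makes each iteration O(Nq) after a one-off
#' decomposition that is cached on the BRM and shared across traits.
#'
#' Standard errors come from the inverse AI matrix at convergence; the SE of
#' the morphometricity `sum_k v_k / (sum_k v_k + v_e)` is obtained by the
#' delta method.
#'
#' @param y numeric phenotype vector (standardized recommended).
#' @param Z optional covariate matrix (intercept always added).
#' @param brms a [compute_brm()] object or list of them (all N x N).
#' @param opts a [reml_options()].
#' @return An object of class `variance_components` with fields
#'   `v_components` (named), `v_e`, `morphometricity`, `se_morph`,
#'   `se_components`, `loglik`, `converged`, `n_iter`, `pinned`.
#' @export
fit_reml <- function(y, Z = NULL, brms, opts = reml_options()) {
  if (inherits(brms, "brm")) brms <- list(brms)
  stopifnot(length(brms) >= 1, all(vapply(brms, inherits, logical(1), "brm")))
  y <- as.numeric(y)
  n <- length(y)
  if (!all(vapply(brms, function(b) nrow(b$matrix) == n, logical(1))))
    stop("BRMs and phenotype disagree on the number of subjects")
  Zf <- build_design(Z, n)
  K <- length(brms)
  labels <- vapply(brms, `[[`, character(1), "component_label")
  use_eigen <- (K == 1L)
  if (use_eigen) {
    e <- brm_eigen(brms[[1L]])
    yt <- as.vector(crossprod(e$vectors, y))
    Zt <- crossprod(e$vectors, Zf)
    stats_fun <- function(theta) reml_stats_eigen(theta, yt, Zt, e$values)
  } else {
    Gs <- lapply(brms, `[[`, "matrix")
    stats_fun <- function(theta) reml_stats_dense(theta, y, Zf, Gs)
  }

  vary <- var_n(y)
  nc <- K + 1L
  theta <- rep(vary / nc, nc)
  floor_v <- 1e-8 * vary
  pinned <- rep(FALSE, nc)
  neg_streak <- rep(0L, nc)
  st <- stats_fun(theta)
  converged <- FALSE
  iter <- 0L
  final_st <- st
  repeat {
    iter <- iter + 1L
    free <- which(!pinned)
    score <- -0.5 * (st$trPB[free] - st$yPBPy[free])
    em_step <- theta[free] + theta[free]^2 *
      (st$yPBPy[free] - st$trPB[free]) / n
    if (iter == 1L) {
      raw_prop <- em_step
    } else {
      AIf <- st$AI[free, free, drop = FALSE]
      delta <- tryCatch(solve(AIf, score), error = function(e) NULL)
      raw_prop <- if (is.null(delta)) em_step else theta[free] + delta
    }
    # streak counted on the raw (pre-fallback) proposal, so a component the
    # quasi-Newton step keeps driving negative is pinned rather than left to
    # decay geometrically under EM
    new_streak <- neg_streak
    new_streak[free] <- ifelse(raw_prop < 0, neg_streak[free] + 1L, 0L)
    prop_free <- raw_prop
    if (opts$em_fallback && any(raw_prop < 0)) {
      # replace the WHOLE step by EM: keeping the other components' AI
      # moves while clamping the negative one breaks the joint direction.
      # EM is uphill but can stall when the AI step wants a component far
      # below its current value, so those components are at least halved
      neg <- raw_prop < 0
      prop_free <- em_step
      prop_free[neg] <- pmin(em_step[neg], theta[free][neg] / 2)
    }
    to_pin <- !pinned & new_streak >= 2L & seq_len(nc) <= K
    if (any(to_pin) && opts$constraint == "error")
      stop("variance component pinned at the zero boundary: ",
           paste(labels[which(to_pin)], collapse = ", "))
    theta_new <- theta
    theta_new[free] <- pmax(prop_free, floor_v)
    theta_new[to_pin] <- 0
    # keep the residual variance away from an exact zero
    theta_new[nc] <- max(theta_new[nc], floor_v)
    st_new <- stats_fun(theta_new)
    # pin only when the zero boundary is actually supported: if fixing the
    # component at 0 lowers the restricted likelihood, the quasi-Newton step
    # was merely overshooting (weakly identified component) and the
    # component stays free at its EM value
    if (any(to_pin) && st_new$loglik < st$loglik - 1e-8) {
      theta_new[to_pin] <- pmax(em_step[match(which(to_pin), free)], floor_v)
      new_streak[to_pin] <- 0L
      to_pin[] <- FALSE
      st_new <- stats_fun(theta_new)
    }
    pinned <- pinned | to_pin
    neg_streak <- new_streak
    neg_streak[to_pin] <- 0L
    # step-halving if the likelihood went down
    halvings <- 0L
    while (st_new$loglik < st$loglik - 1e-10 && halvings < 8L) {
      theta_new[!pinned] <- 0.5 * (theta_new[!pinned] + theta[!pinned])
      st_new <- stats_fun(theta_new)
      halvings <- halvings + 1L
    }
    if (opts$verbose)
      message(sprintf("iter %d logL %.8f theta %s", iter, st_new$loglik,
                      paste(signif(theta_new, 5), collapse = " ")))
    done <- abs(st_new$loglik - st$loglik) < opts$tol ||
      max(abs(theta_new - theta)) < opts$tol * max(vary, 1)
    theta <- theta_new
    st <- st_new
    final_st <- st
    if (done) { converged <- TRUE; break }
    if (iter >= opts$max_iter) break
  }

  v_comp <- theta[seq_len(K)]
  names(v_comp) <- labels
  v_e <- theta[nc]
  tot <- sum(v_comp) + v_e
  morph <- sum(v_comp) / tot
  free <- which(!pinned)
  se_comp <- rep(NA_real_, nc)
  se_morph <- NA_real_
  if (length(free)) {
    AIf <- final_st$AI[free, free, drop = FALSE]
    covf <- tryCatch(solve(AIf), error = function(e) NULL)
    if (!is.null(covf)) {
      se_comp[free] <- sqrt(pmax(diag(covf), 0))
      # delta method on m = s / (s + v_e), s = sum of BRM components
      g_full <- c(rep(v_e / tot^2, K), -sum(v_comp) / tot^2)
      g <- g_full[free]
      se_morph <- sqrt(max(0, as.numeric(t(g) %*% covf %*% g)))
    }
  }
  structure(list(v_components = v_comp, v_e = v_e,
                 morphometricity = morph, se_morph = se_morph,
                 se_components = stats::setNames(se_comp, c(labels, "e")),
                 loglik = final_st$loglik, converged = converged,
                 n_iter = iter, pinned = pinned, n = n, q = ncol(Zf),
                 brm_labels = labels,
                 method = if (use_eigen) "eigen" else "dense"),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("variance_components (", x$method, " AI-REML, ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$n_iter, " iterations)\n", sep = "")
  for (k in seq_along(x$v_components))
    cat(sprintf("  v[%s] = %.6f (SE %.4f)%s\n", names(x$v_components)[k],
                x$v_components[k], x$se_components[k],
                if (x$pinned[k]) " [pinned at 0]" else ""))
  cat(sprintf("  v[e] = %.6f\n", x$v_e))
  cat(sprintf("  morphometricity = %.4f (SE %.4f), logL = %.4f\n",
              x$morphometricity, x$se_morph, x$loglik))
  invisible(x)
}
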