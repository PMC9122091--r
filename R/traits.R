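#' Specification of a simulated trait
#'
#' A trait is a linear combination of `m_causal` randomly chosen standardized
#' vertex columns with iid standard-normal effects, plus Gaussian noise scaled
#' so the vertices capture a target share `target_r2` of the phenotypic
#' variance (the trait's morphometricity).
#'
#' @param m_causal number of causal vertices.
#' @param target_r2 target morphometricity in `[0, 1]`.
#' @param type_restriction optional measurement type the causal vertices are
#'   restricted to (one of [MEAS_TYPES]), or `NULL`.
#' @param seed RNG seed.
#' @param exact_rescale if `TRUE` (default) the noise is orthogonalized
#'   against the vertex part and rescaled so the realized variance share
#'   equals `target_r2` exactly in-sample; if `FALSE` the noise is drawn at
#'   its theoretical variance for distributional realism.
#' @return An object of class `trait_spec`.
#' @export
trait_spec <- function(m_causal, target_r2, type_restriction = NULL,
                       seed = 1, exact_rescale = TRUE) {
  stopifnot(m_causal >= 0, target_r2 >= 0, target_r2 <= 1)
  if (!is.null(type_restriction))
    type_restriction <- match.arg(type_restriction, MEAS_TYPES)
  structure(list(m_causal = as.integer(m_causal), target_r2 = target_r2,
                 type_restriction = type_restriction,
                 seed = as.integer(seed),
                 exact_rescale = isTRUE(exact_rescale)),
            class = "trait_spec")
}

#' Simulate a phenotype from vertexwise data
#'
#' Draws the causal set uniformly without replacement from the eligible
#' vertices, effects from N(0, 1), forms `g = X_causal %*% effects` and adds
#' noise with variance `var(g) * (1 - R2) / R2`. The returned phenotype is
#' standardized (mean 0, denominator-N variance 1), which leaves the variance
#' share unchanged.
#'
#' @param data a standardized [cohort_matrix()].
#' @param spec a [trait_spec()].
#' @param atlas required when `spec$type_restriction` is set.
#' @return An object of class `sim_trait` with fields `y`, `causal_ids`
#'   (0-based), `effects`, `realized_r2`, `target_r2`.
#' @export
simulate_trait <- function(data, spec, atlas = NULL) {
  stop_if_not_cohort(data)
  if (!isTRUE(data$standardized)) stop("standardize the cohort first")
  stopifnot(inherits(spec, "trait_spec"))
  p <- ncol(data$values)
  eligible <- if (is.null(spec$type_restriction)) 0:(p - 1L)
              else {
                if (is.null(atlas)) stop("atlas needed for a type restriction")
                atlas_type_ids(atlas, spec$type_restriction)
              }
  if (spec$m_causal > length(eligible))
    stop("m_causal exceeds the number of eligible vertices")
  if (spec$target_r2 == 0 && spec$m_causal > 0)
    stop("target_r2 = 0 with causal vertices; use simulate_null()")
  with_seed(spec$seed, {
    causal <- sort(sample(eligible, spec$m_causal))
    effects <- stats::rnorm(spec$m_causal)
    g <- as.vector(data$values[, causal + 1L, drop = FALSE] %*% effects)
    vg <- var_n(g)
    if (spec$target_r2 >= 1) {
      y <- g
      realized <- 1
    } else {
      ve_target <- vg * (1 - spec$target_r2) / spec$target_r2
      e <- stats::rnorm(length(g), sd = sqrt(ve_target))
      if (spec$exact_rescale) {
        # orthogonalize against [1, g] and rescale so the in-sample
        # variance share of g is exactly the target
        e <- stats::lm.fit(cbind(1, g), e)$residuals
        e <- e * sqrt(ve_target / var_n(e))
      }
      y <- g + e
      realized <- vg / var_n(y)
    }
    y <- (y - mean(y)) / sqrt(var_n(y))
    structure(list(y = y, causal_ids = causal, effects = effects,
                   realized_r2 = realized, target_r2 = spec$target_r2,
                   spec = spec),
              class = "sim_trait")
  })
}

#' Simulate a null trait
#'
#' A standard-normal phenotype independent of every vertex, standardized to
#' mean 0 and denominator-N variance 1; used to check test calibration under
#' the null hypothesis.
#'
#' @param N number of subjects.
#' @param seed RNG seed.
#' @return A `sim_trait` with empty `causal_ids` and `realized_r2 = 0`.
#' @export
simulate_null <- function(N, seed = 1) {
  stopifnot(N >= 2)
  with_seed(seed, {
    y <- stats::rnorm(N)
    y <- (y - mean(y)) / sqrt(var_n(y))
    structure(list(y = y, causal_ids = integer(0), effects = numeric(0),
                   realized_r2 = 0, target_r2 = 0, spec = NULL),
              class = "sim_trait")
  })
}

#' The simulation scenario grid
#'
#' The three alternative-hypothesis scenarios — (i) 10 causal vertices with
#' morphometricity 0.20, (ii) 100 with 0.50, (iii) 1000 with 0.40 — each
#' replicated `n_replicates` times, plus `n_replicates` null traits, plus the
#' per-type restricted variants of every H1 scenario.
#'
#' @param n_replicates replicates per scenario (default 100).
#' @param base_seed seed base; replicate `r` of scenario block `s` uses seed
#'   `base_seed + 10000 * s + r`.
#' @param per_type include the per-measurement-type restricted variants.
#' @return A data.frame with columns `scenario`, `m_causal`, `target_r2`,
#'   `type_restriction`, `replicate`, `seed`; H0 rows have `m_causal = 0`.
#' @export
scenario_grid <- function(n_replicates = 100, base_seed = 1,
                          per_type = TRUE) {
  base <- data.frame(scenario = c("i", "ii", "iii"),
                     m_causal = c(10L, 100L, 1000L),
                     target_r2 = c(0.20, 0.50, 0.40),
                     type_restriction = NA_character_)
  rows <- base
  if (per_type) {
    for (tp in MEAS_TYPES) {
      v <- base
      v$scenario <- paste0(v$scenario, "_", tp)
      v$type_restriction <- tp
      rows <- rbind(rows, v)
    }
  }
  rows <- rbind(rows, data.frame(scenario = "null", m_causal = 0L,
                                 target_r2 = 0, type_restriction = NA))
  out <- rows[rep(seq_len(nrow(rows)), each = n_replicates), ]
  out$replicate <- rep(seq_len(n_replicates), times = nrow(rows))
  out$seed <- base_seed + 10000L *
    rep(seq_len(nrow(rows)), each = n_replicates) + out$replicate
  rownames(out) <- NULL
  out
}

# Materialize one scenario_grid row as a trait on a cohort.
simulate_from_row <- function(data, row, atlas = NULL) {
  if (row$m_causal == 0)
    simulate_null(nrow(data$values), seed = row$seed)
  else
    simulate_trait(data,
                   trait_spec(row$m_causal, row$target_r2,
                              if (is.na(row$type_restriction)) NULL
                              else row$type_restriction,
                              seed = row$seed),
                   atlas = atlas)
}

#' Re-apply a simulated trait to a new cohort
#'
#' Reuses the causal set and effects of a training trait on an independent
#' cohort (same vertex set), drawing fresh noise at the same morphometricity;
#' used to evaluate out-of-sample prediction against a phenotype with the
#' same generative definition.
#'
#' @param trait a `sim_trait` from [simulate_trait()].
#' @param data a standardized [cohort_matrix()] (e.g. a replication cohort).
#' @param seed RNG seed for the fresh noise.
#' @return A `sim_trait` on the new cohort.
#' @export
apply_trait <- function(trait, data, seed = 1) {
  stopifnot(inherits(trait, "sim_trait"), length(trait$causal_ids) > 0)
  stop_if_not_cohort(data)
  if (!isTRUE(data$standardized)) stop("standardize the cohort first")
  r2 <- trait$target_r2
  with_seed(seed, {
    g <- as.vector(data$values[, trait$causal_ids + 1L, drop = FALSE] %*%
                     trait$effects)
    vg <- var_n(g)
    if (r2 >= 1) y <- g
    else y <- g + stats::rnorm(length(g),
                               sd = sqrt(vg * (1 - r2) / r2))
    realized <- vg / var_n(y)
    y <- (y - mean(y)) / sqrt(var_n(y))
    structure(list(y = y, causal_ids = trait$causal_ids,
                   effects = trait$effects,
                   realized_r2 = realized, target_r2 = r2,
                   spec = trait$spec),
              class = "sim_trait")
  })
}
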