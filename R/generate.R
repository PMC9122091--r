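#' Configuration of the synthetic-cohort generator
#'
#' The generator emulates standardized vertexwise gray-matter data with the
#' two correlation structures that drive false positives in mass-univariate
#' analyses: (a) strong local spatial correlation within each mesh, obtained
#' by graph-smoothing the per-vertex noise, and (b) long-range and cross-type
#' correlation induced by latent subject-level factors (confounders), some of
#' which are exported as observed covariates (age/sex/ICV analogues) while
#' the rest stay hidden. Meshes are 4-neighbour lattices, one per
#' measurement type and hemisphere, with a 9:1 cortical:subcortical vertex
#' ratio approximating real data.
#'
#' @param N number of subjects.
#' @param p total vertex count; presets exist for 5000, 10000 and 20000
#'   (the default); any other value requires explicit `grid_dims`.
#' @param grid_dims named list `list(ct=, ca=, st=, sa=)` of `c(rows, cols)`
#'   lattice sizes used for each hemisphere of each type; overrides `p`.
#' @param K_confounders number of latent factors (default 6).
#' @param confounder_share fraction of each vertex's variance explained by
#'   the latent factors, in `[0, 1)` (default 0.3).
#' @param n_observed how many factors are exported as covariates (default 3,
#'   labelled `age`, `sex`, `icv`; `sex` is dichotomized at its median).
#' @param smooth_rounds neighbour-averaging rounds applied to the noise
#'   field (default 2).
#' @param loading_smooth_rounds smoothing rounds applied to each factor's
#'   loading map so confounders act regionally rather than per-vertex
#'   (default 4).
#' @param seed base RNG seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(N = 1000, p = 20000, grid_dims = NULL,
                             K_confounders = 6, confounder_share = 0.3,
                             n_observed = 3, smooth_rounds = 2,
                             loading_smooth_rounds = 4, seed = 1) {
  if (is.null(grid_dims)) grid_dims <- default_grid_dims(p)
  stopifnot(setequal(names(grid_dims), MEAS_TYPES))
  dims_ok <- vapply(grid_dims, function(d)
    length(d) == 2L && all(d >= 2), logical(1))
  if (!all(dims_ok)) stop("each lattice must be at least 2 x 2")
  if (confounder_share < 0 || confounder_share >= 1)
    stop("confounder_share must be in [0, 1)")
  stopifnot(N >= 2, K_confounders >= 1, n_observed >= 0,
            n_observed <= K_confounders, smooth_rounds >= 0)
  p_total <- sum(vapply(grid_dims, prod, numeric(1))) * 2L
  structure(list(N = as.integer(N), p = as.integer(p_total),
                 grid_dims = grid_dims,
                 K_confounders = as.integer(K_confounders),
                 confounder_share = confounder_share,
                 n_observed = as.integer(n_observed),
                 smooth_rounds = as.integer(smooth_rounds),
                 loading_smooth_rounds = as.integer(loading_smooth_rounds),
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Preset lattice sizes keeping the cortical:subcortical ratio at 9:1, split
# equally between thickness and area and between hemispheres.
default_grid_dims <- function(p) {
  presets <- list(
    `5000`  = list(ct = c(25, 45), ca = c(25, 45), st = c(5, 25), sa = c(5, 25)),
    `10000` = list(ct = c(45, 50), ca = c(45, 50), st = c(10, 25), sa = c(10, 25)),
    `20000` = list(ct = c(60, 75), ca = c(60, 75), st = c(20, 25), sa = c(20, 25)))
  key <- as.character(p)
  if (is.null(presets[[key]]))
    stop("no lattice preset for p = ", p, "; supply grid_dims explicitly")
  presets[[key]]
}

#' Build the lattice atlas of a generator configuration
#'
#' One 4-neighbour lattice per measurement type and hemisphere (8 structures
#' in all), vertices numbered consecutively in type order ct, ca, st, sa and
#' hemisphere order L, R, row-major within each lattice. Deterministic given
#' the configuration.
#'
#' @param config a [generator_config()].
#' @return A [vertex_atlas()].
#' @export
build_atlas <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  vert_list <- list()
  edge_list <- list()
  offset <- 0L
  struct <- 0L
  for (tp in MEAS_TYPES) {
    d <- config$grid_dims[[tp]]
    nr <- d[1]; nc <- d[2]; nb <- nr * nc
    for (hemi in c("L", "R")) {
      struct <- struct + 1L
      vert_list[[length(vert_list) + 1L]] <- data.frame(
        vertex_id = offset + 0:(nb - 1L), meas_type = tp,
        hemisphere = hemi, structure_id = struct)
      # row-major id of cell (i, j): offset + (i-1)*nc + (j-1)
      idx <- matrix(offset + 0:(nb - 1L), nrow = nr, ncol = nc, byrow = TRUE)
      horiz <- cbind(as.vector(idx[, -nc]), as.vector(idx[, -1L]))
      vert <- cbind(as.vector(idx[-nr, ]), as.vector(idx[-1L, ]))
      edge_list[[length(edge_list) + 1L]] <- rbind(horiz, vert)
      offset <- offset + nb
    }
  }
  vertex_atlas(do.call(rbind, vert_list), do.call(rbind, edge_list))
}

# p x K factor-loading matrix: per-factor white noise smoothed on the
# lattices, then row-normalized so the factor part of each vertex has unit
# variance. Rows with (numerically) zero norm are given a flat loading.
make_loadings <- function(atlas, K, rounds) {
  p <- atlas$p
  L <- matrix(stats::rnorm(p * K), p, K)
  if (rounds > 0) {
    St <- Matrix::t(smoothing_operator(atlas))
    for (r in seq_len(rounds)) L <- as.matrix(Matrix::crossprod(St, L))
  }
  nrm <- sqrt(rowSums(L^2))
  nrm[nrm < 1e-12] <- 1
  L / nrm
}

#' Generate a synthetic vertexwise cohort
#'
#' Raw values are `sqrt(share) * F L' + sqrt(1 - share) * E`, where `F` is an
#' N x K matrix of iid standard-normal latent factors, `L` the row-normalized
#' smooth loading map, and `E` unit-variance noise smoothed `smooth_rounds`
#' times on the mesh (then rescaled to unit variance per vertex, so every raw
#' vertex has variance ~1). The covariate table contains the observed factors
#' (the `sex` analogue dichotomized at its median) plus one pure-noise
#' covariate.
#'
#' @param config a [generator_config()].
#' @param latent optional latent record from a previous call whose loadings
#'   (and atlas) are reused, e.g. for a matched replication cohort.
#' @param seed RNG seed (defaults to `config$seed`).
#' @param subject_prefix prefix for generated subject ids.
#' @param covariate_shift optional named numeric vector of mean offsets added
#'   to observed factors (emulates a transfer cohort with shifted
#'   demographics).
#' @return A list with elements `cohort` (raw [cohort_matrix()]), `latent`
#'   (class `latent_record`: `factor_values`, `loadings`, `observed_mask`)
#'   and `atlas`.
#' @export
generate_cohort <- function(config, latent = NULL, seed = config$seed,
                            subject_prefix = "S", covariate_shift = NULL) {
  stopifnot(inherits(config, "generator_config"))
  atlas <- if (is.null(latent)) build_atlas(config) else latent$atlas
  p <- atlas$p
  N <- config$N
  K <- config$K_confounders
  share <- config$confounder_share
  with_seed(seed, {
    L <- if (is.null(latent)) make_loadings(atlas, K,
                                            config$loading_smooth_rounds)
         else latent$loadings
    Fm <- matrix(stats::rnorm(N * K), N, K)
    obs <- seq_len(config$n_observed)
    if (!is.null(covariate_shift)) {
      for (nm in seq_along(covariate_shift))
        Fm[, obs[nm]] <- Fm[, obs[nm]] + covariate_shift[nm]
    }
    E <- matrix(stats::rnorm(N * p), N, p)
    if (config$smooth_rounds > 0) {
      St <- Matrix::t(smoothing_operator(atlas))
      for (r in seq_len(config$smooth_rounds)) E <- as.matrix(E %*% St)
      # iid noise smoothed by S has per-vertex variance diag(S S'); rescale
      # back to 1 so `share` keeps its meaning
      sm_sd <- sqrt(Matrix::rowSums(smoothing_operator(atlas)^2))
      E <- sweep(E, 2L, pmax(sm_sd, 1e-12), "/")
    }
    V <- sqrt(share) * tcrossprod(Fm, L) + sqrt(1 - share) * E
    covs <- data.frame(row.names = seq_len(N))
    labels <- c("age", "sex", "icv")
    for (j in obs) {
      nm <- if (j <= length(labels)) labels[j] else paste0("factor", j)
      v <- Fm[, j]
      if (nm == "sex") v <- as.numeric(v > stats::median(v))
      covs[[nm]] <- v
    }
    covs$noise1 <- stats::rnorm(N)
    cohort <- cohort_matrix(V, sprintf("%s%05d", subject_prefix, seq_len(N)),
                            covariates = covs)
    lat <- structure(list(factor_values = Fm, loadings = L,
                          observed_mask = seq_len(K) %in% obs,
                          atlas = atlas),
                     class = "latent_record")
    list(cohort = cohort, latent = lat, atlas = atlas)
  })
}

#' Generate a matched replication cohort
#'
#' New subjects drawn from the same generative structure (identical factor
#' loadings); standardization statistics are never shared with the training
#' cohort. An optional `covariate_shift` emulates a transfer cohort whose
#' observed demographics have different means.
#'
#' @param config a [generator_config()] (its `N` sets the replication size).
#' @param latent the `latent_record` returned by [generate_cohort()].
#' @param seed2 RNG seed for the replication draw.
#' @param covariate_shift optional named numeric vector of observed-factor
#'   mean offsets.
#' @return A raw [cohort_matrix()] with subject ids prefixed `"R"`.
#' @export
generate_replication <- function(config, latent, seed2,
                                 covariate_shift = NULL) {
  stopifnot(inherits(latent, "latent_record"))
  generate_cohort(config, latent = latent, seed = seed2,
                  subject_prefix = "R",
                  covariate_shift = covariate_shift)$cohort
}
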