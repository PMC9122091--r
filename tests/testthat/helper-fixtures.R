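# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

# ~200-vertex lattice layout with all four measurement types
tiny_grid <- function() {
  list(ct = c(4, 10), ca = c(4, 10), st = c(2, 5), sa = c(2, 5))
}

# even smaller layout (p = 56) for per-vertex refit oracles
micro_grid <- function() {
  list(ct = c(2, 5), ca = c(2, 5), st = c(2, 2), sa = c(2, 2))
}

small_cohort <- function(N = 200, seed = 1, confounder_share = 0.3,
                         smooth_rounds = 2, grid = tiny_grid()) {
  cfg <- generator_config(N = N, grid_dims = grid,
                          confounder_share = confounder_share,
                          smooth_rounds = smooth_rounds, seed = seed)
  gen <- generate_cohort(cfg)
  list(cfg = cfg, atlas = gen$atlas, latent = gen$latent,
       raw = gen$cohort, std = standardize_columns(gen$cohort))
}

# assoc_result stand-in with prescribed p-values (for cluster tests)
fake_result <- function(pvals, model_name = "fake") {
  p <- length(pvals)
  chi2 <- stats::qchisq(pvals, 1, lower.tail = FALSE)
  structure(list(tbl = data.frame(vertex_id = seq_len(p) - 1L,
                                  b = rep(0, p), se = rep(1, p),
                                  chi2 = chi2, pval = pvals,
                                  flagged = rep(FALSE, p)),
                 model = list(name = model_name), n_subjects = 100L),
            class = "assoc_result")
}

# single-structure r x c lattice atlas (cortical thickness, left hemisphere)
lattice_atlas_1 <- function(nr, nc) {
  nb <- nr * nc
  idx <- matrix(0:(nb - 1L), nrow = nr, ncol = nc, byrow = TRUE)
  edges <- rbind(cbind(as.vector(idx[, -nc]), as.vector(idx[, -1L])),
                 cbind(as.vector(idx[-nr, ]), as.vector(idx[-1L, ])))
  vertex_atlas(data.frame(vertex_id = 0:(nb - 1L), meas_type = "ct",
                          hemisphere = "L", structure_id = 1L), edges)
}
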