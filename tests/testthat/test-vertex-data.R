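test_that("column standardization uses the population variance", {
  d <- cohort_matrix(cbind(c(1, 2, 3), c(5, 1, 0)))
  s <- standardize_columns(d)
  expect_equal(s$values[, 1], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-6)
  expect_equal(colMeans(s$values), c(0, 0), tolerance = 1e-12)
  expect_equal(colMeans(s$values^2), c(1, 1), tolerance = 1e-12)
  expect_equal(s$col_means, c(2, 2))
  expect_true(s$standardized)

  # a column that is already centred with unit population variance passes
  # through unchanged
  x <- c(-1, 0, 1) * sqrt(3 / 2)
  d2 <- cohort_matrix(cbind(x, c(0, 1, 5)))
  s2 <- standardize_columns(d2)
  expect_equal(s2$values[, 1], x, tolerance = 1e-12)
})

test_that("constant columns abort with the offending vertex id", {
  d <- cohort_matrix(cbind(c(1, 2, 3), c(5, 5, 5)))
  expect_error(standardize_columns(d), "constant vertex.*1")
  expect_error(standardize_columns(standardize_columns(
    cohort_matrix(cbind(c(1, 2, 3))))), "already standardized")
})

test_that("BRM matches the hand-computed product and diag-mean identity", {
  # X = [[1,-1],[-1,1],[0,0]] column-standardized has both columns equal to
  # +-sqrt(3/2)*(1,-1,0); B = (x1 x1' + x2 x2')/2 worked out by hand:
  d <- standardize_columns(cohort_matrix(cbind(c(1, -1, 0), c(-1, 1, 0))))
  B <- compute_brm(d)
  expected <- matrix(c(1.5, -1.5, 0, -1.5, 1.5, 0, 0, 0, 0), 3, 3)
  expect_equal(B$matrix, expected, tolerance = 1e-12)
  expect_equal(B$p_used, 2L)
  expect_equal(mean(diag(B$matrix)), 1, tolerance = 1e-12)

  # p = 1: B = x x'
  b1 <- compute_brm(d, subset = 0L)
  expect_equal(b1$matrix, tcrossprod(d$values[, 1]), tolerance = 1e-12)

  # generated cohort: diag mean 1, PSD
  co <- small_cohort(N = 60, seed = 3)
  Bg <- compute_brm(co$std)
  expect_equal(mean(diag(Bg$matrix)), 1, tolerance = 1e-10)
  expect_gte(min(eigen(Bg$matrix, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)
  expect_error(compute_brm(co$std, subset = integer(0)), "empty")
})

test_that("global BRM is the p-weighted mean of the per-type BRMs", {
  co <- small_cohort(N = 50, seed = 4)
  Bg <- compute_brm(co$std)
  parts <- lapply(MEAS_TYPES, function(tp) compute_brm(co$std, tp, co$atlas))
  wsum <- Reduce(`+`, lapply(parts, function(b)
    b$matrix * b$p_used / Bg$p_used))
  expect_equal(Bg$matrix, wsum, tolerance = 1e-10)
  expect_equal(sum(vapply(parts, `[[`, numeric(1), "p_used")), Bg$p_used)
})

test_that("standardize -> BRM pipeline is invariant to column order", {
  co <- small_cohort(N = 40, seed = 5, grid = micro_grid())
  perm <- sample(ncol(co$raw$values))
  d2 <- cohort_matrix(co$raw$values[, perm])
  B1 <- compute_brm(standardize_columns(co$raw))
  B2 <- compute_brm(standardize_columns(d2))
  expect_equal(B1$matrix, B2$matrix, tolerance = 1e-10)
})

test_that("principal components reproduce the SVD of the data matrix", {
  co <- small_cohort(N = 50, seed = 6)
  pcs <- compute_pcs(co$std, k = 5)
  sv <- svd(co$std$values, nu = 5, nv = 0)
  for (k in 1:5) {
    s <- sign(sum(pcs$scores[, k] * sv$u[, k]))
    expect_equal(pcs$scores[, k], s * sv$u[, k] * sv$d[k], tolerance = 1e-6)
  }
  expect_equal(pcs$variance_explained,
               sv$d[1:5]^2 / sum(svd(co$std$values)$d^2), tolerance = 1e-8)
  expect_true(all(diff(pcs$variance_explained) <= 1e-12))
  # score columns mutually orthogonal
  cp <- crossprod(pcs$scores)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-6 * max(diag(cp)))

  # rank-1 matrix: first component carries all the variance
  u <- rnorm(30); v <- rnorm(10)
  d1 <- cohort_matrix(outer(u, v))
  d1$standardized <- TRUE   # bypass scaling to keep exact rank 1
  p1 <- compute_pcs(d1, 1)
  expect_equal(p1$variance_explained[1], 1, tolerance = 1e-10)

  expect_error(compute_pcs(co$std, k = 0), "positive")
  expect_error(compute_pcs(co$std, k = nrow(co$std$values)), "exceeds")
})

test_that("per-type PCs concatenate k components per measurement type", {
  co <- small_cohort(N = 40, seed = 7)
  pcs <- compute_pcs(co$std, k = 3, scope = "per_type", atlas = co$atlas)
  expect_equal(ncol(pcs$scores), 3L * 4L)
  expect_equal(length(pcs$variance_explained), 12L)
})

test_that("graph smoothing is the identity at 0 rounds and preserves constants", {
  co <- small_cohort(N = 20, seed = 8, smooth_rounds = 0)
  expect_identical(smooth_graph(co$raw, co$atlas, 0)$values, co$raw$values)
  # spatially constant field (rows of ones scaled per subject): the kernel
  # rows sum to 1, so any number of rounds leaves it unchanged
  V <- outer(rnorm(20), rep(1, co$atlas$p))
  d <- cohort_matrix(V)
  sm <- smooth_graph(d, co$atlas, 3)
  expect_equal(sm$values, V, tolerance = 1e-12)
  expect_error(smooth_graph(co$std, co$atlas, 1), "raw")
})

test_that("smoothing increases neighbour correlation", {
  co <- small_cohort(N = 150, seed = 9, confounder_share = 0,
                     smooth_rounds = 0)
  edge_cor <- function(d) {
    e <- co$atlas$edges + 1L
    mean(abs(vapply(seq_len(nrow(e)), function(i)
      cor(d$values[, e[i, 1]], d$values[, e[i, 2]]), numeric(1))))
  }
  r0 <- edge_cor(co$raw)
  r3 <- edge_cor(smooth_graph(co$raw, co$atlas, 3))
  expect_gt(r3, r0)
})

test_that("atlas, cohort and phenotype files round-trip through TSV", {
  co <- small_cohort(N = 15, seed = 10, grid = micro_grid())
  td <- withr::local_tempdir()
  write_atlas(co$atlas, file.path(td, "anno.tsv"), file.path(td, "edges.tsv"))
  a2 <- read_atlas(file.path(td, "anno.tsv"), file.path(td, "edges.tsv"))
  expect_equal(a2$vertices$meas_type, co$atlas$vertices$meas_type)
  expect_equal(a2$edges, co$atlas$edges)

  write_cohort(co$raw, file.path(td, "mat.tsv"), file.path(td, "cov.tsv"))
  c2 <- read_cohort(file.path(td, "mat.tsv"), file.path(td, "cov.tsv"))
  expect_equal(c2$values, co$raw$values, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(c2$covariates, co$raw$covariates, tolerance = 1e-12)

  y <- rnorm(15)
  write_phenotype(y, co$raw$subject_id, file.path(td, "phen.txt"))
  y2 <- read_phenotype(file.path(td, "phen.txt"), co$raw$subject_id)
  expect_equal(unname(y2), y, tolerance = 1e-12)
})

test_that("atlas validation rejects malformed graphs", {
  vert <- data.frame(vertex_id = 0:3, meas_type = c("ct", "ct", "st", "st"),
                     hemisphere = "L", structure_id = c(1, 1, 2, 2))
  expect_silent(vertex_atlas(vert, rbind(c(0, 1), c(2, 3))))
  expect_error(vertex_atlas(vert, rbind(c(1, 2))), "within one")
  expect_error(vertex_atlas(vert, rbind(c(1, 1))), "self-loop")
  expect_error(vertex_atlas(vert, rbind(c(0, 1), c(1, 0))), "duplicate")
})
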