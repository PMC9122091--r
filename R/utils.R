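# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All user-facing randomness goes
# through this so that seeds recorded in configs/specs are reproducible
# without clobbering the session RNG.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Population (denominator-N) variance; the standardization convention used
# throughout so that mean(diag(B)) == 1 holds exactly.
var_n <- function(x) {
  mean((x - mean(x))^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_cohort <- function(data) {
  if (!inherits(data, "cohort_matrix"))
    stop("`data` must be a cohort_matrix", call. = FALSE)
}

# Median of the chi-square(1) distribution, the reference for the inflation
# factor lambda. qchisq(0.5, 1) = 0.4549364...
CHISQ1_MEDIAN <- stats::qchisq(0.5, df = 1)
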