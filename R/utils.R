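# Internal utilities shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#'
#' All synthetic-data generators and the multi-start optimiser route their
#' randomness through this helper so that every stochastic routine is a pure
#' function of (parameters, seed) and never perturbs the session RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = env, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

assert_number <- function(x, name, finite = TRUE, positive = FALSE,
                          nonneg = FALSE) {
  if (!is.numeric(x) || length(x) == 0L)
    stop(sprintf("`%s` must be numeric", name), call. = FALSE)
  if (finite && any(!is.finite(x)))
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  if (positive && any(x <= 0))
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && any(x < 0))
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Avogadro constant, 1/mol (2019 SI exact value).
AVOGADRO <- 6.02214076e23

`%||%` <- function(a, b) if (is.null(a)) b else a
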