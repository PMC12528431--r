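`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. `expr` may be a function (called with no
# arguments) or an expression.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  if (is.function(expr)) expr() else expr
}

# Deterministic 31-bit seed derived from a master seed and a string key, so
# any single pipeline cell can be re-run in isolation and match the full run.
derive_seed <- function(seed, key) {
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 131 + code) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' @useDynLib seasonccm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL
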