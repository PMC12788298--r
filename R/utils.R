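#' @keywords internal
#' @useDynLib parkfuse, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic sub-seed derivation; keeps results < 2^31.
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  s <- 0
  for (k in ks) s <- (s * 69069 + as.numeric(k) + 1) %% 2147483647
  as.integer(s)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable log(1 + exp(x)).
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)
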