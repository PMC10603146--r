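# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# With seed = NULL the expression runs on the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic derived seed, kept well below 2^31.
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483629)
}

# Center columns and scale to unit (population) standard deviation, the
# glmnet convention.  Constant columns get scale 1 so they pass through.
standardize_design <- function(X) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr, "-")
  scl <- sqrt(colMeans(Xc^2))
  scl[scl < .Machine$double.eps] <- 1
  list(X = sweep(Xc, 2L, scl, "/"), center = ctr, scale = scl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vmessage <- function(verbose, ...) {
  if (isTRUE(verbose))
    message(format(Sys.time(), "%H:%M:%S"), " | ", ...)
}
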