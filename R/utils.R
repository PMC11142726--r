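# Internal helpers: seeded substreams, numerics.

# Deterministic substream seed derived from a master seed, a purpose label and
# an index. Keeps results < 2^31 so set.seed() always accepts them.
derive_seed <- function(seed, purpose, index = 0L) {
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  s <- abs(as.numeric(seed)) %% 2147483647
  v <- (s * 48271) %% 2147483647
  v <- (v + h * 1009 + abs(as.numeric(index))) %% 2147483647
  as.integer(v)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

sigmoid <- function(x) 1 / (1 + exp(-x))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Glorot-uniform initial weights, seeded.
glorot <- function(fan_in, fan_out, seed, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  with_seed(seed, array(stats::runif(prod(dims), -lim, lim), dims))
}
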