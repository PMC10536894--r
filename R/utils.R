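# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  seed = NULL runs in the ambient RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Polynomial rolling hash (mod 2^32, exact in doubles) of a serialized R
# object, as a hex string.  Used for manifest fingerprints; stable across
# sessions for plain data (version 2 serialization, header stripped).
object_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  bytes <- bytes[-seq_len(14L)]  # drop header bytes that encode R version
  h <- 2166136261
  for (chunk in split(bytes, ceiling(seq_along(bytes) / 8192))) {
    # Horner update h = h*257 + b, carried exactly in doubles via %% 2^32
    for (b in chunk) h <- (h * 257 + b) %% 4294967296
  }
  sprintf("%04x%04x%06x", as.integer(h %/% 65536), as.integer(h %% 65536),
          as.integer(length(bytes) %% 16777216))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)
is_scalar <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
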