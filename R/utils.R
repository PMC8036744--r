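# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream.  All stochastic operations in the package route their `seed`
# argument through here.
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", globalenv(), mode = "integer")))
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  else
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation; keeps results in 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) + 1009 * as.double(k)) %% 2147483646 + 1)
}

geometric_mean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable hash of an R object for provenance stamps (md5 of canonical JSON).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
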