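# Internal bit/seed helpers. Basis-index arithmetic is done in doubles (exact
# below 2^53); bitwXor/bitwAnd require values below 2^31, which holds for all
# register widths this package simulates.

.isPow2 <- function(x) x >= 1 && abs(x - 2^round(log2(x))) < .Machine$double.eps * x * 4

.log2int <- function(x) {
  n <- as.integer(round(log2(x)))
  if (2^n != x) stop("value is not a power of two: ", x)
  n
}

.intToBits <- function(x, nBits) {
  if (nBits == 0L) return(integer(0))
  as.integer(floor(x / 2^((nBits - 1):0)) %% 2)
}

.bitsToInt <- function(bits) {
  if (!length(bits)) return(0)
  sum(bits * 2^((length(bits) - 1):0))
}

.bitStringToVec <- function(s) {
  v <- as.integer(strsplit(s, "", fixed = TRUE)[[1]])
  if (anyNA(v) || any(v > 1L)) stop("malformed bit string: ", s)
  v
}

.vecToBitString <- function(b) paste(b, collapse = "")

#' Derive a sub-seed from a base seed
#'
#' Emulated cores and repeated runs each draw randomness from their own
#' stream; this maps a base seed and an index to a deterministic 31-bit
#' sub-seed so that multi-core runs are reproducible from one configuration
#' seed.
#'
#' @param seed integer base seed.
#' @param index non-negative integer (core index, run index, ...).
#' @return an integer seed in [0, 2^31).
#' @export
deriveSeed <- function(seed, index = 0L) {
  as.integer((abs(as.double(seed)) * 48271 + 95279 * as.double(index) + 11213) %%
               2147483629)
}

# Evaluate an expression with a local seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
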