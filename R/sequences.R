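#' The default two-bit DNA alphabet
#'
#' Encodes A as 00, T as 01, C as 10 and G as 11, so each nucleotide takes
#' \code{log2(4) = 2} bits and an M-symbol substring takes 2M bits.
#'
#' @return an [Alphabet-class].
#' @examples
#' dnaAlphabet()
#' @export
dnaAlphabet <- function() {
  codes <- c(A = "00", T = "01", C = "10", G = "11")
  new("Alphabet", symbols = names(codes), bitsPerSymbol = 2L, codes = codes)
}

#' Construct an alphabet from explicit symbol codes
#'
#' Only power-of-two alphabet sizes are supported: every possible bit pattern
#' of the symbol width is then a valid symbol, and masking (not a sentinel
#' code) keeps padded text positions out of match sets.
#'
#' @param symbols character vector of single-character symbols.
#' @return an [Alphabet-class] assigning codes in symbol order.
#' @export
makeAlphabet <- function(symbols) {
  k <- length(symbols)
  if (k < 2 || bitwAnd(k, k - 1L) != 0L)
    stop("alphabet size must be a power of two >= 2 (got ", k, ")")
  w0 <- as.integer(round(log2(k)))
  codes <- vapply(seq_len(k) - 1L,
                  function(i) .vecToBitString(.intToBits(i, w0)), "")
  names(codes) <- symbols
  new("Alphabet", symbols = symbols, bitsPerSymbol = w0, codes = codes)
}

.splitChars <- function(x) {
  if (length(x) == 1L) strsplit(x, "", fixed = TRUE)[[1]] else x
}

#' Encode a text sequence for quantum-memory addressing
#'
#' Uppercases the input, checks it against the alphabet and pads it up to the
#' next power of two \code{N = 2^n} (repeating the first alphabet symbol).
#' Substring words at padded or overhanging start indices are defined by
#' cyclic wrap so that the memory's truth table is total, but such indices
#' are excluded from every match set via [validLimit()].
#'
#' @param raw a character string, character vector of single symbols, or a
#'   \code{Biostrings::DNAString}.
#' @param alphabet an [Alphabet-class]; default [dnaAlphabet()].
#' @return an [EncodedText-class].
#' @examples
#' txt <- encodeText("ATCG")
#' wordAt(txt, 0, 1)  # "00"
#' @export
encodeText <- function(raw, alphabet = dnaAlphabet()) {
  if (methods::is(raw, "XString") || methods::is(raw, "XStringSet"))
    raw <- as.character(raw)
  syms <- toupper(.splitChars(raw))
  if (!length(syms)) stop("text must be nonempty")
  bad <- which(!(syms %in% alphabet@symbols))
  if (length(bad))
    stop("unknown symbol '", syms[bad[1]], "' at position ", bad[1] - 1L,
         " (0-based)")
  origLength <- length(syms)
  n <- as.integer(ceiling(log2(max(origLength, 1L))))
  N <- as.integer(2^n)
  if (N > origLength) syms <- c(syms, rep(alphabet@symbols[1L], N - origLength))
  new("EncodedText", symbols = syms, origLength = as.integer(origLength),
      N = N, n = n, alphabet = alphabet)
}

#' Construct a query pattern
#'
#' @param x pattern as a character string or vector of symbols.
#' @param id label used in reports; defaults to the pattern string.
#' @param alphabet an [Alphabet-class].
#' @return a [Pattern-class].
#' @examples
#' dnaPattern("TAG")
#' @export
dnaPattern <- function(x, id = NULL, alphabet = dnaAlphabet()) {
  syms <- toupper(.splitChars(x))
  bad <- which(!(syms %in% alphabet@symbols))
  if (length(bad))
    stop("unknown symbol '", syms[bad[1]], "' at position ", bad[1] - 1L,
         " (0-based)")
  bits <- paste(alphabet@codes[syms], collapse = "")
  if (is.null(id)) id <- paste(syms, collapse = "")
  new("Pattern", id = id, symbols = syms, M = length(syms), bits = bits)
}

#' Substring word served by the quantum memory at a given address
#'
#' Returns the concatenated bit codes of \code{M} consecutive symbols
#' starting at 0-based index \code{i}, leftmost symbol first, wrapping
#' cyclically past the end of the padded text (wrap keeps the memory's truth
#' table total; wrapped addresses never enter match sets).
#'
#' @param text an [EncodedText-class].
#' @param i 0-based start index in \code{[0, N)}.
#' @param M substring length in symbols.
#' @return a bit string of width \code{M * bitsPerSymbol}.
#' @export
wordAt <- function(text, i, M) {
  if (i < 0 || i >= text@N) stop("address out of range: ", i)
  idx <- (i + seq_len(M) - 1L) %% text@N
  paste(text@alphabet@codes[text@symbols[idx + 1L]], collapse = "")
}

#' Symbols of a text window (no wrap)
#' @param text an [EncodedText-class].
#' @param i 0-based start; @param M window length.
#' @return character vector of M symbols.
#' @keywords internal
.windowSymbols <- function(text, i, M) text@symbols[(i + 1L):(i + M)]

#' Largest valid start index for a pattern of length M
#'
#' Occurrences live in the inclusive 0-based start range
#' \code{[0, origLength - M]}; padded and overhanging windows never match.
#'
#' @param text an [EncodedText-class].
#' @param M pattern length in symbols.
#' @return integer, \code{origLength - M}.
#' @export
validLimit <- function(text, M) {
  if (M > text@origLength)
    stop("pattern length ", M, " exceeds text length ", text@origLength)
  text@origLength - as.integer(M)
}

#' Decode a word back to symbols
#'
#' @param bits a bit string whose width is a multiple of the symbol width.
#' @param alphabet an [Alphabet-class].
#' @return character vector of symbols.
#' @export
decodeWord <- function(bits, alphabet = dnaAlphabet()) {
  w0 <- alphabet@bitsPerSymbol
  if (nchar(bits) %% w0 != 0L) stop("bit string width is not a symbol multiple")
  starts <- seq(1L, nchar(bits), by = w0)
  chunks <- substring(bits, starts, starts + w0 - 1L)
  out <- names(alphabet@codes)[match(chunks, alphabet@codes)]
  if (anyNA(out)) stop("unknown code in bit string")
  out
}

#' Classical ground-truth pattern matcher
#'
#' Exhaustive scan returning every 0-based start index with symbol-wise
#' equality, overlaps included. This is the classical oracle every quantum
#' path is verified against.
#'
#' @param text an [EncodedText-class].
#' @param pattern a [Pattern-class] (or a string, converted).
#' @return strictly increasing integer vector of start indices in
#'   \code{[0, validLimit(text, M)]}.
#' @examples
#' bruteForceMatches(encodeText("TAATAA"), dnaPattern("TAA"))  # 0 3
#' @export
bruteForceMatches <- function(text, pattern) {
  if (is.character(pattern)) pattern <- dnaPattern(pattern, alphabet = text@alphabet)
  lim <- validLimit(text, pattern@M)
  if (lim < 0L) return(integer(0))
  hits <- vapply(0:lim, function(i)
    all(.windowSymbols(text, i, pattern@M) == pattern@symbols), logical(1))
  which(hits) - 1L
}

#' Symbol-level Hamming distance
#'
#' Counts positions at which two equal-length symbol sequences differ. The
#' unit is one symbol (one substitution), not one bit, matching the
#' replacement-at-unit-cost error model of approximate filtering.
#'
#' @param a,b character strings or symbol vectors of equal length.
#' @return non-negative integer.
#' @examples
#' hammingDistance("TAA", "TAG")  # 1
#' @export
hammingDistance <- function(a, b) {
  a <- .splitChars(a); b <- .splitChars(b)
  if (length(a) != length(b))
    stop("length mismatch: ", length(a), " vs ", length(b))
  sum(a != b)
}
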