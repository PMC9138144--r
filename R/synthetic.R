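#' Generate a synthetic DNA text with planted pattern occurrences
#'
#' Builds a random background sequence of the requested length and overwrites
#' it with each planted pattern at each requested 0-based start index.
#' Overlapping plants are allowed only when symbol-consistent; a conflict is
#' an error. Every planted occurrence is verified present by
#' [bruteForceMatches()] before the text is returned, and the same seed
#' always yields the same text.
#'
#' The defaults emulate the study conditions this package evaluates under:
#' power-of-two text lengths (128/256/512), a uniform nucleotide background,
#' and a handful of short planted patterns with small occurrence counts.
#'
#' @param length target text length (pre-padding); a power of two leaves the
#'   text unpadded.
#' @param planted named list: pattern string -> integer vector of 0-based
#'   start indices.
#' @param seed integer seed; required for reproducibility.
#' @param background named numeric of symbol probabilities; default uniform
#'   over the alphabet.
#' @param alphabet an [Alphabet-class].
#' @return an [EncodedText-class].
#' @examples
#' txt <- generateSyntheticText(128, list(TAA = c(5L, 50L)), seed = 1)
#' all(c(5L, 50L) %in% bruteForceMatches(txt, "TAA"))
#' @export
generateSyntheticText <- function(length, planted = list(), seed,
                                  background = NULL,
                                  alphabet = dnaAlphabet()) {
  stopifnot(length >= 1)
  if (missing(seed)) stop("a seed is required for reproducible generation")
  if (is.null(background))
    background <- stats::setNames(rep(1 / base::length(alphabet@symbols),
                                      base::length(alphabet@symbols)),
                                  alphabet@symbols)
  fixed <- rep(NA_character_, length)
  for (pat in names(planted)) {
    syms <- .splitChars(toupper(pat))
    for (start in planted[[pat]]) {
      if (start < 0 || start + base::length(syms) > length)
        stop("planted occurrence of '", pat, "' at ", start,
             " does not fit in length ", length)
      pos <- start + seq_along(syms)
      clash <- !is.na(fixed[pos]) & fixed[pos] != syms
      if (any(clash))
        stop("conflicting overlap planting '", pat, "' at index ", start)
      fixed[pos] <- syms
    }
  }
  syms <- .withSeed(seed, {
    bg <- sample(names(background), length, replace = TRUE, prob = background)
    ifelse(is.na(fixed), bg, fixed)
  })
  txt <- encodeText(syms, alphabet)
  for (pat in names(planted)) {
    hits <- bruteForceMatches(txt, dnaPattern(pat, alphabet = alphabet))
    if (!all(planted[[pat]] %in% hits))
      stop("internal error: planted occurrence of '", pat, "' not found")
  }
  txt
}
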