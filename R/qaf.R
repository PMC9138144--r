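# Quantum approximate filtering: mark candidate pattern start positions from
# the first offsets of the pattern's distinct symbols, then keep candidates
# within a Hamming-distance threshold. Every exact occurrence survives any
# threshold >= 0, so filtering is complete; it only prunes the search space.

#' First offset of each distinct pattern symbol
#'
#' @param pattern a [Pattern-class] or string.
#' @return named integer vector: symbol -> smallest 0-based offset.
#' @examples
#' distinctSymbolOffsets("TAA")  # T=0, A=1
#' @export
distinctSymbolOffsets <- function(pattern) {
  if (is.character(pattern)) pattern <- dnaPattern(pattern)
  syms <- pattern@symbols
  first <- !duplicated(syms)
  stats::setNames(which(first) - 1L, syms[first])
}

#' Candidate start positions from distinct-symbol marking
#'
#' Every text position i holding a symbol s with first pattern offset j marks
#' candidate start \code{i - j}; candidates outside \code{[0, validLimit]}
#' are discarded. The set contains every exact occurrence start (the symbol
#' at offset j of an occurrence marks its own start).
#'
#' @param text an [EncodedText-class].
#' @param pattern a [Pattern-class] or string.
#' @param SL optional precomputed [distinctSymbolOffsets()] mapping.
#' @return sorted integer vector of candidate starts.
#' @export
candidateStarts <- function(text, pattern, SL = NULL) {
  if (is.character(pattern)) pattern <- dnaPattern(pattern, alphabet = text@alphabet)
  if (is.null(SL)) SL <- distinctSymbolOffsets(pattern)
  lim <- validLimit(text, pattern@M)
  cand <- integer(0)
  for (k in seq_along(SL)) {
    s <- names(SL)[k]; j <- SL[[k]]
    pos <- which(text@symbols[seq_len(text@origLength)] == s) - 1L
    cand <- c(cand, pos - j)
  }
  sort(unique(cand[cand >= 0L & cand <= lim]))
}

#' Approximate filtering to a location array
#'
#' Keeps the candidate starts whose text window is within \code{threshold}
#' symbol substitutions of the pattern, producing the location array LA
#' (stored classically, sorted ascending) with \code{t = |LA|} and
#' \code{tq = ceiling(log2(max(t, 1)))} location qubits. The quantum
#' collection loop is simulated: candidates are drawn by repeated measurement
#' of the merged auxiliary register until \code{maxRounds} consecutive rounds
#' add nothing; the returned LA is the closed-form set above, which the
#' collection must reproduce - a shortfall raises a warning and sets the
#' \code{partial} flag. The final set is independent of the random stream;
#' randomness affects collection order only.
#'
#' @param text an [EncodedText-class].
#' @param pattern a [Pattern-class] or string.
#' @param threshold Hamming-distance threshold; default
#'   \code{ceiling(M / 4)}. Any value >= 0 retains all exact occurrences.
#' @param seed integer seed for the collection loop.
#' @param maxRounds consecutive empty measurement rounds before the
#'   collection stops; default \code{8 * t + 32}.
#' @return a [FilterResult-class].
#' @examples
#' qafFilter(encodeText("ATAGC"), "TAG", threshold = 0)@LA  # 1
#' @export
qafFilter <- function(text, pattern, threshold = NULL, seed = NULL,
                      maxRounds = NULL) {
  if (is.character(pattern)) pattern <- dnaPattern(pattern, alphabet = text@alphabet)
  if (is.null(threshold)) threshold <- ceiling(pattern@M / 4)
  if (threshold < 0) stop("threshold must be >= 0")
  SL <- distinctSymbolOffsets(pattern)
  cand <- candidateStarts(text, pattern, SL)
  keep <- vapply(cand, function(i)
    hammingDistance(.windowSymbols(text, i, pattern@M), pattern@symbols) <=
      threshold, logical(1))
  LA <- cand[keep]
  t <- length(LA)
  tq <- if (t <= 1L) 0L else as.integer(ceiling(log2(t)))
  partial <- FALSE
  if (t > 0L) {
    if (is.null(maxRounds)) maxRounds <- 16L * t + 64L
    collected <- .withSeed(seed, {
      # auxiliary-register measurements, drawn in one batch; collection stops
      # at the first run of maxRounds consecutive already-seen draws
      cap <- maxRounds + ceiling(t * (log(max(t, 2)) + 2))
      draws <- sample.int(t, cap, replace = TRUE)
      newPos <- which(!duplicated(draws))
      gaps <- diff(c(0L, newPos))
      stopAt <- if (any(gaps > maxRounds))
        newPos[min(which(gaps > maxRounds))] - 1L else cap
      got <- logical(t)
      got[unique(draws[seq_len(stopAt)])] <- TRUE
      got
    })
    if (!all(collected)) {
      warning("collection loop stopped with ", sum(!collected),
              " candidate(s) uncollected; result flagged partial")
      partial <- TRUE
    }
  }
  new("FilterResult", LA = as.integer(LA), t = as.integer(t), tq = tq,
      threshold = as.integer(threshold),
      SL = stats::setNames(as.integer(SL), names(SL)), partial = partial)
}

#' Write a location array as plain text
#'
#' One candidate start index per line (the classically stored LA).
#'
#' @param filter a [FilterResult-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeLocationArray <- function(filter, path) {
  writeLines(as.character(filter@LA), path)
  invisible(path)
}
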