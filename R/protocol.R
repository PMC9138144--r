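# Measurement-accuracy evaluation protocol: repeated independent
# single-search-and-measure trials, each measurement classified as a
# correctly identified pattern index (CIP) or an incorrectly identified one
# (IIP); true indices never measured over the whole protocol count as
# incorrectly missed patterns (IMP).

#' Error percentage from CIP/IIP tallies
#'
#' \code{100 * IIP / (CIP + IIP)}; \code{NA} when no measurements were made.
#'
#' @param CIP,IIP non-negative integer tallies.
#' @return numeric percentage (full precision; reports print one decimal).
#' @examples
#' errorPercent(923, 77)  # 7.7
#' @export
errorPercent <- function(CIP, IIP) {
  if (CIP + IIP == 0) return(NA_real_)
  100 * IIP / (CIP + IIP)
}

#' Tally measurement outcomes against the true occurrence set
#'
#' @param measured integer vector of measured start indices, one per trial.
#' @param trueSet integer vector of true occurrence start indices.
#' @return an [ErrorStats-class].
#' @export
errorStats <- function(measured, trueSet) {
  CIP <- sum(measured %in% trueSet)
  IIP <- length(measured) - CIP
  IMP <- length(setdiff(trueSet, measured))
  pct <- errorPercent(CIP, IIP)
  new("ErrorStats", CIP = as.integer(CIP), IIP = as.integer(IIP),
      IMP = as.integer(IMP), errorPct = pct, defined = !is.na(pct))
}

#' Repeated-measurement evaluation protocol
#'
#' Performs \code{R} repetitions of \code{I} independent
#' single-search-and-measure trials (default 10 x 100, reported as one pooled
#' 1000-trial tally). The solution count is first obtained once from the
#' requested counting method; every trial then prepares the uniform state,
#' applies the scheduled number of Grover iterations and measures. Each
#' measurement is classified CIP (a true occurrence index) or IIP; IMP
#' counts true indices never measured across the whole protocol.
#' Deterministic given the seed.
#'
#' For the filtered algorithm the trial measures the location register and
#' dereferences the (sentinel-padded) location array; sentinel readings are
#' IIP. A pattern with a single filtered location (tq = 0) has a
#' deterministic measurement.
#'
#' @param text an [EncodedText-class].
#' @param pattern a [Pattern-class] or string.
#' @param algorithm "enqpbea" (full address space) or "enqbcea" (filtered).
#' @param tSource "known", "exact", "approx" or "brute".
#' @param tKnown known count for \code{tSource = "known"}.
#' @param rApprox precision qubits for \code{tSource = "approx"}; default
#'   \code{n - 2} (full space) or \code{tq - 1} (filtered), floored at 1.
#' @param R repetitions; @param I trials per repetition.
#' @param threshold filtering threshold (enqbcea), default
#'   \code{ceiling(M/4)}.
#' @param seed integer seed.
#' @return an [ErrorStats-class]; the assumed count and the per-trial
#'   success probability are attached as attributes \code{tAssumed} and
#'   \code{successProb}.
#' @export
runExperimentProtocol <- function(text, pattern,
                                  algorithm = c("enqpbea", "enqbcea"),
                                  tSource = "exact", tKnown = NULL,
                                  rApprox = NULL, R = 10L, I = 100L,
                                  threshold = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (is.character(pattern)) pattern <- dnaPattern(pattern, alphabet = text@alphabet)
  trueSet <- bruteForceMatches(text, pattern)
  nTrials <- R * I
  .withSeed(seed, {
    if (algorithm == "enqpbea") {
      marked <- qemMatchSet(text, pattern, mode = "mask")
      NSearch <- text@N
      regWidth <- text@n
      deref <- function(v) v
    } else {
      fr <- qafFilter(text, pattern, threshold = threshold,
                      seed = deriveSeed(seed, 7L))
      sentinel <- text@N
      LApad <- c(fr@LA, rep(sentinel, 2^fr@tq - fr@t))
      marked <- which(vapply(LApad, function(a) a != sentinel &&
        a <= validLimit(text, pattern@M) &&
        wordAt(text, a, pattern@M) == pattern@bits, logical(1))) - 1L
      NSearch <- 2^fr@tq
      regWidth <- fr@tq
      deref <- function(v) LApad[v + 1L]
    }
    tTrue <- length(marked)
    tAssumed <- switch(tSource,
      known = { if (is.null(tKnown)) stop("tSource='known' needs tKnown"); as.integer(tKnown) },
      exact = exactCount(NSearch = max(NSearch, 2), t = tTrue)@tHat,
      approx = {
        nBits <- .log2int(max(NSearch, 2))
        if (is.null(rApprox)) rApprox <- max(1L, nBits - 2L)
        approxCount(NSearch = max(NSearch, 2), t = tTrue, r = rApprox)@tHat
      },
      brute = tTrue)
    if (regWidth == 0L) {
      outcomes <- rep(0L, nTrials)
      successProb <- as.numeric(tTrue >= 1L)
    } else {
      sched <- groverIterations(NSearch, max(min(tAssumed, NSearch), 0L))
      st <- initUniform(quantumState(c(QL = regWidth)), "QL")
      if (sched@rG > 0) for (r in seq_len(sched@rG)) {
        st <- phaseFlipMask(st, "QL", marked)
        st <- applyDiffusion(st, "QL")
      }
      p <- Mod(st@amplitudes)^2
      successProb <- sum(p[marked + 1L])
      outcomes <- sample.int(NSearch, nTrials, replace = TRUE, prob = p) - 1L
    }
    measured <- deref(outcomes)
    es <- errorStats(measured, trueSet)
    attr(es, "tAssumed") <- tAssumed
    attr(es, "successProb") <- successProb
    es
  })
}
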