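# Quantum exact-match oracle and Grover amplitude amplification.

#' Grover iteration schedule
#'
#' For a search space of size \code{NSearch} with \code{t} assumed solutions,
#' the rotation angle is \code{theta = asin(sqrt(t/NSearch))} and the
#' iteration count is \code{floor(pi/4 * sqrt(NSearch/t))} (at least 1 when
#' \code{0 < t <= NSearch/2}). With \code{t = 0} the search still runs
#' \code{floor(pi/4 * sqrt(NSearch))} iterations and measures a uniform
#' outcome. When more than half the space is marked no iterations are
#' scheduled: a direct measurement of the uniform state already succeeds
#' with probability \code{t/NSearch > 1/2}, whereas a forced iteration can
#' overshoot all the way to zero success (at \code{t = 3N/4} one round lands
#' exactly on \code{sin^2(3 theta) = 0}). After r iterations from the
#' uniform state, a marked outcome is measured with probability
#' \code{sin^2((2r+1) theta)}.
#'
#' @param NSearch search-space size, a power of two.
#' @param t assumed number of solutions, \code{0 <= t <= NSearch}.
#' @return an [IterationSchedule-class].
#' @examples
#' groverIterations(128, 1)@rG  # 8
#' @export
groverIterations <- function(NSearch, t) {
  if (!.isPow2(NSearch)) stop("NSearch must be a power of two")
  if (t < 0 || t > NSearch) stop("t must lie in [0, NSearch]")
  if (t == 0) {
    theta <- 0
    rG <- max(1L, as.integer(floor(pi / 4 * sqrt(NSearch))))
  } else if (t > NSearch / 2) {
    theta <- asin(sqrt(t / NSearch))
    rG <- 0L
  } else {
    theta <- asin(sqrt(t / NSearch))
    rG <- max(1L, as.integer(floor(pi / 4 * sqrt(NSearch / t))))
  }
  new("IterationSchedule", NSearch = as.numeric(NSearch), t = as.numeric(t),
      theta = theta, rG = rG)
}

#' Closed-form single-shot success probability
#'
#' Probability that measuring after \code{r} Grover iterations (default the
#' schedule's \code{rG}) yields a marked state, for \code{t} marked among
#' \code{NSearch} from the uniform start: \code{sin^2((2r+1) theta)}.
#'
#' @param schedule an [IterationSchedule-class].
#' @param r iteration count override.
#' @return probability in [0, 1].
#' @export
groverSuccessProbability <- function(schedule, r = schedule@rG) {
  if (schedule@t == 0) return(0)
  sin((2 * r + 1) * schedule@theta)^2
}

#' Exact-match marked set
#'
#' The set of addresses whose M-symbol word equals the pattern, intersected
#' with the validity mask \code{i <= validLimit} (so padded or wrapped
#' windows never match). In \code{"mask"} mode the set is computed by direct
#' word comparison; in \code{"dense"} mode it is extracted from a simulated
#' comparator circuit: the memory is loaded by [qmemLoad()], X gates map the
#' data register so that a match reads all-ones, and the marked addresses are
#' those components whose data register is all-ones. Both modes must agree.
#'
#' @param text an [EncodedText-class].
#' @param pattern a [Pattern-class] or string.
#' @param mode "mask" (classical evaluation of the oracle predicate) or
#'   "dense" (data register physically simulated).
#' @return sorted integer vector of marked addresses.
#' @export
qemMatchSet <- function(text, pattern, mode = c("mask", "dense")) {
  mode <- match.arg(mode)
  if (is.character(pattern)) pattern <- dnaPattern(pattern, alphabet = text@alphabet)
  lim <- validLimit(text, pattern@M)
  if (mode == "mask") {
    hits <- vapply(0:(text@N - 1L), function(i)
      i <= lim && wordAt(text, i, pattern@M) == pattern@bits, logical(1))
    return(which(hits) - 1L)
  }
  w <- pattern@M * text@alphabet@bitsPerSymbol
  if (text@n + w > 24L)
    stop("dense mode needs ", text@n + w, " qubits; use mode = 'mask'")
  anf <- anfSynthesize(truthTableFromText(text, pattern@M))
  st <- quantumState(c(QA = text@n, QD = w))
  st <- initUniform(st, "QA")
  st <- qmemLoad(st, anf)
  pbits <- .bitStringToVec(pattern@bits)
  qd <- .regSpan(st, "QD")
  for (k in seq_len(w)) if (pbits[k] == 0L) st <- applyGate(st, "X", qd[k])
  dv <- .regValues(st, "QD")
  av <- .regValues(st, "QA")
  marked <- sort(unique(av[Mod(st@amplitudes) > 1e-12 & dv == 2^w - 1]))
  as.integer(marked[marked <= lim])
}

#' One Grover search: amplify, then measure
#'
#' Starts from (or is given) a uniform superposition over the search
#' register, applies \code{rG} rounds of phase-flip on the marked set
#' followed by diffusion, and measures the register. The pre-measurement
#' marked-set probability equals \code{sin^2((2 rG + 1) theta)} exactly when
#' the initial state is uniform. With an empty marked set the outcome is
#' uniform over the whole register.
#'
#' @param schedule an [IterationSchedule-class].
#' @param marked integer vector of marked register values.
#' @param state optional prepared [QuantumState-class]; default a fresh
#'   uniform register of width \code{log2(NSearch)}.
#' @param register register name to search on.
#' @param oracle optional function \code{state -> state} applying the phase
#'   oracle (used by dense-mode searches); default [phaseFlipMask()] with
#'   \code{marked}.
#' @return list with \code{index} (measured value), \code{state} (collapsed),
#'   \code{successProb} (pre-measurement marked probability) and \code{rG}.
#' @export
groverSearchOnce <- function(schedule, marked, state = NULL, register = "QA",
                             oracle = NULL) {
  k <- .log2int(schedule@NSearch)
  if (length(marked) && any(marked < 0 | marked >= schedule@NSearch))
    stop("marked set indices out of range")
  if (is.null(state)) {
    state <- quantumState(stats::setNames(k, register))
    state <- initUniform(state, register)
  }
  if (is.null(oracle))
    oracle <- function(s) phaseFlipMask(s, register, marked)
  if (schedule@rG > 0) for (r in seq_len(schedule@rG)) {
    state <- oracle(state)
    state <- applyDiffusion(state, register)
  }
  v <- .regValues(state, register)
  successProb <- sum(Mod(state@amplitudes[v %in% marked])^2)
  m <- measureRegister(state, register)
  list(index = m$value, state = m$state, successProb = successProb,
       rG = schedule@rG)
}

#' Enumerate all occurrences by repeated Grover search
#'
#' Repeats schedule -> search -> classical verification until the assumed
#' number of solutions has been found or a retry budget of
#' \code{3 t + 10} unverified measurements is exhausted. After each verified
#' hit the index is removed from the marked set and the schedule recomputed
#' with the remaining count, so the expected number of productive rounds is
#' t rather than coupon-collector. Verification failures are counted, never
#' raised; a budget exhaustion with marked states remaining is flagged
#' \code{aborted}.
#'
#' @param text an [EncodedText-class].
#' @param pattern a [Pattern-class] or string.
#' @param tSource how the solution count is obtained: "known" (supply
#'   \code{tKnown}), "exact" / "approx" (quantum counting), or "brute"
#'   (classical count).
#' @param tKnown integer, required when \code{tSource = "known"}.
#' @param rApprox precision qubits for \code{tSource = "approx"}.
#' @param mode "mask" or "dense" oracle realization (see [qemMatchSet()]);
#'   "auto" picks dense for \code{N <= 64}, mask above.
#' @param seed integer seed for the measurement stream.
#' @return a [MatchReport-class].
#' @export
searchAllOccurrences <- function(text, pattern,
                                 tSource = c("known", "exact", "approx", "brute"),
                                 tKnown = NULL, rApprox = NULL,
                                 mode = c("auto", "mask", "dense"),
                                 seed = NULL) {
  tSource <- match.arg(tSource)
  mode <- match.arg(mode)
  if (mode == "auto") mode <- if (text@N <= 64L) "dense" else "mask"
  if (is.character(pattern)) pattern <- dnaPattern(pattern, alphabet = text@alphabet)
  marked0 <- qemMatchSet(text, pattern, mode = mode)
  NSearch <- text@N
  .withSeed(seed, {
    tAssumed <- switch(tSource,
      known = { if (is.null(tKnown)) stop("tSource='known' needs tKnown"); as.integer(tKnown) },
      exact = exactCount(NSearch = NSearch, t = length(marked0))@tHat,
      approx = {
        if (is.null(rApprox)) rApprox <- max(1L, text@n - 2L)
        approxCount(NSearch = NSearch, t = length(marked0), r = rApprox)@tHat
      },
      brute = length(marked0))
    found <- integer(0)
    marked <- marked0
    attempts <- 0L
    budget <- 3L * tAssumed + 10L
    apps <- 0L
    st <- quantumState(c(QA = text@n))
    tRem <- tAssumed
    while (TRUE) {
      if (tRem <= 0L && length(found) > 0L) break
      if (attempts >= budget) break
      sched <- groverIterations(NSearch, max(tRem, 0L))
      res <- groverSearchOnce(sched, marked, state = initUniform(
        quantumState(c(QA = text@n)), "QA"))
      # accumulate the per-pattern gate log across rounds
      for (fam in names(gateCounts(res$state)))
        st@gateLog$counts[[fam]] <- st@gateLog$counts[[fam]] +
          gateCounts(res$state)[[fam]]
      apps <- apps + res$rG
      i <- res$index
      verified <- i <= validLimit(text, pattern@M) &&
        wordAt(text, i, pattern@M) == pattern@bits
      if (verified && !(i %in% found)) {
        found <- c(found, i)
        marked <- setdiff(marked, i)
        tRem <- tRem - 1L
      } else {
        attempts <- attempts + 1L
      }
      if (tRem <= 0L && tAssumed > 0L) break
    }
    # incomplete enumeration (whatever the cause: exhausted retries or an
    # under-assumed t) is always flagged, never a silent short answer
    new("MatchReport", patternId = pattern@id, found = sort(as.integer(found)),
        tAssumed = as.integer(tAssumed), groverApplications = as.integer(apps),
        attempts = attempts, aborted = length(marked) > 0L,
        balanced = FALSE, core = 1L, wave = 1L,
        gateCounts = gateCounts(st), filter = NULL)
  })
}
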