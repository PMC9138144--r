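# End-to-end multiple-pattern matching: the plain-addressing algorithm
# (search over all 2^n start indices, "enqpbea") and the filter-then-search
# algorithm (search over the 2^tq filtered location register, "enqbcea"),
# with round-robin scheduling over emulated quantum cores. Cores are
# independent simulator instances with disjoint registers and derived seeds;
# parallelism is a scheduling/reporting semantic, not threading.

#' Round-robin assignment of patterns to emulated cores
#'
#' Pattern k goes to core \code{((k - 1) mod C) + 1} in wave
#' \code{ceiling(k / C)}; with m patterns on C cores there are
#' \code{ceiling(m / C)} sequential waves and idle cores are allowed.
#'
#' @param patterns character vector or list of [Pattern-class] objects.
#' @param C number of emulated cores.
#' @return a [CoreAssignment-class].
#' @export
schedulePatterns <- function(patterns, C) {
  if (C < 1L) stop("C must be >= 1")
  ids <- vapply(patterns, function(p) if (is.character(p)) p else p@id, "")
  m <- length(ids)
  if (m < 1L) stop("at least one pattern is required")
  assignment <- lapply(seq_len(C), function(c)
    if (c > m) character(0) else ids[seq(c, m, by = C)])
  # "C = " must not be passed to new(): it would partially match new()'s
  # Class parameter; fill the slot after construction instead.
  ca <- new("CoreAssignment", assignment = assignment,
            waves = as.integer(ceiling(m / C)))
  ca@C <- as.integer(C)
  validObject(ca)
  ca
}

#' Qubit accounting for the two search algorithms
#'
#' The plain-addressing search uses \code{n + M * w0 + 2 + 2} qubits: n
#' address qubits, \code{M * w0} data qubits holding the substring in
#' superposition, 2 workspace qubits storing the parallel match result and 2
#' ancillae supporting the Grover operator. The filtered search uses
#' \code{2n + tq}: 2n filtering qubits plus \code{tq = ceiling(log2(t))}
#' location qubits over the t filtered indices.
#'
#' @param algorithm "enqpbea" or "enqbcea".
#' @param n address qubits (\code{log2 N}).
#' @param M pattern length in symbols (enqpbea).
#' @param w0 bits per symbol (default 2, DNA).
#' @param t filtered index count (enqbcea).
#' @return list with \code{total} qubits and a named \code{breakdown}.
#' @examples
#' qubitsRequired("enqpbea", n = 7, M = 3)$total  # 17
#' qubitsRequired("enqbcea", n = 7, t = 23)$total # 19 (14 + 5)
#' @export
qubitsRequired <- function(algorithm = c("enqpbea", "enqbcea"), n, M = NULL,
                           w0 = 2L, t = NULL) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "enqpbea") {
    if (is.null(M)) stop("enqpbea accounting needs M")
    breakdown <- c(address = as.integer(n), data = as.integer(M * w0),
                   workspace = 2L, ancilla = 2L)
  } else {
    if (is.null(t)) stop("enqbcea accounting needs t")
    tq <- if (t <= 1L) 0L else as.integer(ceiling(log2(t)))
    breakdown <- c(filtering = as.integer(2L * n), location = tq)
  }
  list(total = as.integer(sum(breakdown)), breakdown = breakdown)
}

.asPatterns <- function(patterns, alphabet) {
  lapply(patterns, function(p)
    if (is.character(p)) dnaPattern(p, alphabet = alphabet) else p)
}

.coreWave <- function(k, C) c(core = as.integer((k - 1L) %% C) + 1L,
                              wave = as.integer((k - 1L) %/% C) + 1L)

.parallelCost <- function(reports, C) {
  if (!length(reports)) return(0)
  waves <- vapply(reports, function(r) r@wave, integer(1))
  cost <- 0
  for (wv in sort(unique(waves))) {
    inWave <- reports[waves == wv]
    cost <- cost + max(vapply(inWave, function(r)
      as.numeric(r@groverApplications), numeric(1)))
  }
  cost
}

#' Plain-addressing multiple-pattern search
#'
#' Each pattern is searched over the full \code{2^n} address space on its
#' assigned core (an independent simulator instance with a derived seed) by
#' repeated Grover search with verification; see [searchAllOccurrences()].
#'
#' @param text an [EncodedText-class].
#' @param patterns character vector or list of [Pattern-class].
#' @param C number of emulated cores.
#' @param tSource "known", "exact", "approx" or "brute" (see
#'   [searchAllOccurrences()]).
#' @param tKnown named integer vector of known counts per pattern id (for
#'   \code{tSource = "known"}).
#' @param mode oracle realization, "auto"/"mask"/"dense".
#' @param seed integer configuration seed; each core-pattern run derives its
#'   own stream.
#' @return an [MPMResult-class].
#' @export
runEnqpbea <- function(text, patterns, C = 1L, tSource = "exact",
                       tKnown = NULL, mode = "auto", seed = 1L) {
  pats <- .asPatterns(patterns, text@alphabet)
  assignment <- schedulePatterns(pats, C)
  reports <- vector("list", length(pats))
  for (k in seq_along(pats)) {
    p <- pats[[k]]
    cw <- .coreWave(k, C)
    tk <- if (!is.null(tKnown)) {
      if (!is.null(names(tKnown))) unname(tKnown[p@id]) else tKnown[k]
    } else NULL
    rep <- searchAllOccurrences(text, p, tSource = tSource, tKnown = tk,
                                mode = mode, seed = deriveSeed(seed, k))
    rep@core <- cw[["core"]]; rep@wave <- cw[["wave"]]
    reports[[k]] <- rep
  }
  new("MPMResult", algorithm = "enqpbea", reports = reports,
      assignment = assignment, parallelCost = .parallelCost(reports, C))
}

# Search over the filtered location register: the oracle dereferences the
# (sentinel-padded) location array and conjoins the exact-match predicate on
# the original text. Returns a MatchReport in text coordinates.
.searchFiltered <- function(text, pattern, filter, tSource, tKnown, seed) {
  n <- text@n
  sentinel <- text@N                       # an address outside the text
  tq <- filter@tq
  NSearch <- 2^tq
  LApad <- c(filter@LA, rep(sentinel, NSearch - filter@t))
  isMatch <- function(addr) addr != sentinel &&
    addr <= validLimit(text, pattern@M) &&
    wordAt(text, addr, pattern@M) == pattern@bits
  markedLoc <- which(vapply(LApad, isMatch, logical(1))) - 1L
  tPrime <- length(markedLoc)
  balanced <- NSearch > 1 && abs(tPrime / NSearch - 0.5) <= 0.25
  .withSeed(seed, {
    tAssumed <- switch(tSource,
      known = { if (is.null(tKnown)) stop("tSource='known' needs tKnown"); as.integer(tKnown) },
      exact = exactCount(NSearch = max(NSearch, 2), t = tPrime)@tHat,
      approx = approxCount(NSearch = max(NSearch, 2), t = tPrime,
                           r = max(1L, tq - 1L))@tHat,
      brute = tPrime)
    found <- integer(0)
    apps <- 0L; attempts <- 0L
    budget <- 3L * tAssumed + 10L
    gl <- .newGateLog()
    if (tq == 0L) {
      # single filtered location: measurement is deterministic
      if (filter@t >= 1L && isMatch(LApad[1]) && tAssumed > 0L)
        found <- LApad[1]
    } else {
      marked <- markedLoc
      tRem <- tAssumed
      while (TRUE) {
        if (tRem <= 0L && length(found) > 0L) break
        if (attempts >= budget) break
        sched <- groverIterations(NSearch, max(min(tRem, NSearch), 0L))
        st <- initUniform(quantumState(c(QL = tq)), "QL")
        res <- groverSearchOnce(sched, marked, state = st, register = "QL")
        for (fam in names(gateCounts(res$state)))
          gl$counts[[fam]] <- gl$counts[[fam]] + gateCounts(res$state)[[fam]]
        apps <- apps + res$rG
        addr <- LApad[res$index + 1L]
        if (isMatch(addr) && !(addr %in% found)) {
          found <- c(found, addr)
          marked <- setdiff(marked, res$index)
          tRem <- tRem - 1L
        } else attempts <- attempts + 1L
        if (tRem <= 0L && tAssumed > 0L) break
      }
    }
    new("MatchReport", patternId = pattern@id, found = sort(as.integer(found)),
        tAssumed = as.integer(tAssumed), groverApplications = as.integer(apps),
        attempts = as.integer(attempts),
        aborted = tPrime > length(found),
        balanced = balanced, core = 1L, wave = 1L, gateCounts = gl$counts,
        filter = filter)
  })
}

#' Filter-then-search multiple-pattern matching
#'
#' Per pattern: approximate filtering ([qafFilter()]) produces the location
#' array LA, padded with a sentinel address to \code{2^tq}; Grover search
#' then runs over the tq-qubit location register, the oracle dereferencing
#' LA and conjoining the exact-match predicate on the original text. With
#' \code{threshold = M} the filter passes every candidate and the found sets
#' coincide with [runEnqpbea()]. An empty filter result yields an empty
#' report with no search; a near-balanced filtered space (marked fraction
#' within 1/4 of one half) is flagged \code{balanced} in the report.
#'
#' @inheritParams runEnqpbea
#' @param threshold Hamming-distance threshold; default \code{ceiling(M/4)}.
#' @return an [MPMResult-class] whose reports carry their
#'   [FilterResult-class].
#' @export
runEnqbcea <- function(text, patterns, C = 1L, threshold = NULL,
                       tSource = "exact", tKnown = NULL, seed = 1L) {
  pats <- .asPatterns(patterns, text@alphabet)
  assignment <- schedulePatterns(pats, C)
  reports <- vector("list", length(pats))
  for (k in seq_along(pats)) {
    p <- pats[[k]]
    cw <- .coreWave(k, C)
    fr <- qafFilter(text, p, threshold = threshold,
                    seed = deriveSeed(seed, 1000L + k))
    tk <- if (!is.null(tKnown)) {
      if (!is.null(names(tKnown))) unname(tKnown[p@id]) else tKnown[k]
    } else NULL
    rep <- if (fr@t == 0L) {
      new("MatchReport", patternId = p@id, found = integer(0), tAssumed = 0L,
          groverApplications = 0L, attempts = 0L, aborted = FALSE,
          balanced = FALSE, core = 1L, wave = 1L,
          gateCounts = .newGateLog()$counts, filter = fr)
    } else {
      .searchFiltered(text, p, fr, tSource, tk, deriveSeed(seed, k))
    }
    rep@core <- cw[["core"]]; rep@wave <- cw[["wave"]]
    reports[[k]] <- rep
  }
  new("MPMResult", algorithm = "enqbcea", reports = reports,
      assignment = assignment, parallelCost = .parallelCost(reports, C))
}
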