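#' @import methods
NULL

#' Alphabet: a fixed-width binary encoding of a symbol set
#'
#' An \code{Alphabet} maps each symbol of a power-of-two sized symbol set to a
#' distinct bit string of width \code{log2(|symbols|)}. The default DNA
#' alphabet encodes A, T, C, G as 00, 01, 10, 11 (in that order), so every
#' nucleotide occupies exactly two bits and an M-symbol substring occupies
#' 2M bits.
#'
#' @slot symbols character vector of single-character symbols, in code order.
#' @slot bitsPerSymbol integer, bits per symbol (log2 of the alphabet size).
#' @slot codes character vector of bit strings, named by symbol.
#' @seealso [dnaAlphabet()]
#' @export
setClass("Alphabet",
  representation(symbols = "character", bitsPerSymbol = "integer",
                 codes = "character"),
  validity = function(object) {
    k <- length(object@symbols)
    if (k < 2L || bitwAnd(k, k - 1L) != 0L)
      return("alphabet size must be a power of two >= 2")
    if (object@bitsPerSymbol != as.integer(round(log2(k))))
      return("bitsPerSymbol must equal log2(|symbols|)")
    if (length(object@codes) != k || anyDuplicated(object@codes))
      return("codes must be distinct, one per symbol")
    if (any(nchar(object@codes) != object@bitsPerSymbol))
      return("every code must have width bitsPerSymbol")
    if (!identical(names(object@codes), object@symbols))
      return("codes must be named by symbols, in order")
    TRUE
  })

#' EncodedText: a power-of-two length encoded symbol sequence
#'
#' Holds a symbol sequence padded up to length \code{N = 2^n} together with
#' its alphabet. Substring words \code{wordAt(x, i, M)} are the bit strings
#' the quantum memory serves at address \code{i}; indices beyond
#' \code{validLimit(x, M)} (padded or overhanging windows, defined by cyclic
#' wrap) are masked out of every match set by the oracle.
#'
#' @slot symbols character vector of length \code{N} (padding included).
#' @slot origLength integer, length before power-of-two padding.
#' @slot N integer, padded length \code{2^n}.
#' @slot n integer, number of address bits.
#' @slot alphabet an [Alphabet-class].
#' @seealso [encodeText()], [wordAt()], [validLimit()]
#' @export
setClass("EncodedText",
  representation(symbols = "character", origLength = "integer",
                 N = "integer", n = "integer", alphabet = "Alphabet"),
  validity = function(object) {
    if (object@N != 2^object@n) return("N must equal 2^n")
    if (length(object@symbols) != object@N)
      return("symbols must have length N")
    if (object@origLength < 1L || object@origLength > object@N)
      return("origLength must be in [1, N]")
    if (!all(object@symbols %in% object@alphabet@symbols))
      return("all symbols must belong to the alphabet")
    TRUE
  })

#' Pattern: a query sequence with its bit encoding
#'
#' @slot id character label for reporting.
#' @slot symbols character vector of length \code{M}.
#' @slot M integer, pattern length in symbols.
#' @slot bits bit string of width \code{M * bitsPerSymbol}.
#' @seealso [dnaPattern()]
#' @export
setClass("Pattern",
  representation(id = "character", symbols = "character", M = "integer",
                 bits = "character"),
  validity = function(object) {
    if (object@M != length(object@symbols)) return("M must equal length(symbols)")
    if (object@M < 1L) return("pattern must be nonempty")
    TRUE
  })

#' QuantumState: dense complex state vector over named registers
#'
#' Amplitudes are indexed by basis states of \code{nQubits} qubits, qubit 0
#' being the most significant bit of the basis index. Registers are named
#' contiguous qubit spans (e.g. address QA, data QD, location QL). The gate
#' log lives in an environment so counts accumulate across the value-semantic
#' updates R applies to the state itself.
#'
#' @slot nQubits integer, total qubits.
#' @slot amplitudes complex vector of length \code{2^nQubits}.
#' @slot registers named list of 0-based integer qubit index vectors.
#' @slot gateLog environment holding a named numeric \code{counts} vector.
#' @seealso [quantumState()], [applyGate()], [measureRegister()]
#' @export
setClass("QuantumState",
  representation(nQubits = "integer", amplitudes = "complex",
                 registers = "list", gateLog = "environment"),
  validity = function(object) {
    if (length(object@amplitudes) != 2^object@nQubits)
      return("amplitudes must have length 2^nQubits")
    qs <- unlist(object@registers, use.names = FALSE)
    if (length(qs) && (anyDuplicated(qs) || any(qs < 0L | qs >= object@nQubits)))
      return("register spans must be disjoint and within [0, nQubits)")
    nrm <- sum(Mod(object@amplitudes)^2)
    if (abs(nrm - 1) > 1e-9) return("state norm must be 1 within 1e-9")
    TRUE
  })

#' ANFTable: algebraic normal forms of the memory's output bits
#'
#' For each of \code{nFuncs} output bits, stores the set of AND-monomials
#' whose XOR computes that bit from the \code{nVars} address bits. A monomial
#' is stored as the integer whose set bits name the participating address
#' variables (variable T0 is the most significant address bit); the integer 0
#' denotes the constant-1 term. The monomials are exactly the positions of
#' ones in the binary Moebius spectrum of the bit's truth-table column.
#'
#' @slot nVars integer, number of address variables.
#' @slot nFuncs integer, number of output bits (substring width in bits).
#' @slot monomials list of integer vectors, one per output bit.
#' @seealso [anfSynthesize()], [anfEvaluate()], [qmemLoad()]
#' @export
setClass("ANFTable",
  representation(nVars = "integer", nFuncs = "integer", monomials = "list"),
  validity = function(object) {
    if (length(object@monomials) != object@nFuncs)
      return("monomials must have one entry per output bit")
    lim <- 2^object@nVars
    for (m in object@monomials) {
      if (length(m) && (any(m < 0) || any(m >= lim)))
        return("monomial indices must lie in [0, 2^nVars)")
      if (anyDuplicated(m)) return("monomials of a bit must be distinct")
    }
    TRUE
  })

#' IterationSchedule: Grover iteration count for a given solution count
#'
#' @slot NSearch numeric, search-space size (a power of two).
#' @slot t numeric, assumed number of solutions.
#' @slot theta numeric, \code{asin(sqrt(t/NSearch))}.
#' @slot rG integer, scheduled Grover iterations.
#' @seealso [groverIterations()], [groverSuccessProbability()]
#' @export
setClass("IterationSchedule",
  representation(NSearch = "numeric", t = "numeric", theta = "numeric",
                 rG = "integer"))

#' FilterResult: candidate start positions surviving approximate filtering
#'
#' @slot LA integer vector, sorted candidate start indices (the location
#'   array, stored classically).
#' @slot t integer, \code{length(LA)}.
#' @slot tq integer, \code{ceiling(log2(max(t, 1)))} location qubits.
#' @slot threshold integer, Hamming-distance threshold used.
#' @slot SL named integer vector: first offset of each distinct pattern symbol.
#' @slot partial logical, TRUE when the simulated collection loop stopped
#'   before gathering every candidate.
#' @seealso [qafFilter()]
#' @export
setClass("FilterResult",
  representation(LA = "integer", t = "integer", tq = "integer",
                 threshold = "integer", SL = "integer", partial = "logical"),
  validity = function(object) {
    if (object@t != length(object@LA)) return("t must equal length(LA)")
    if (is.unsorted(object@LA, strictly = TRUE) && object@t > 1L)
      return("LA must be strictly increasing")
    TRUE
  })

#' CountEstimate: quantum counting result
#'
#' @slot tHat integer, majority estimate of the number of solutions.
#' @slot method character, "exact" or "approx".
#' @slot r integer, precision qubits used.
#' @slot runs integer, repetitions pooled into the majority.
#' @slot rawOutcomes integer vector of per-run estimates.
#' @seealso [exactCount()], [approxCount()]
#' @export
setClass("CountEstimate",
  representation(tHat = "integer", method = "character", r = "integer",
                 runs = "integer", rawOutcomes = "integer"),
  validity = function(object) {
    if (!object@method %in% c("exact", "approx"))
      return("method must be 'exact' or 'approx'")
    if (object@tHat < 0L) return("tHat must be non-negative")
    TRUE
  })

#' MatchReport: verified occurrences of one pattern
#'
#' Every index in \code{found} has been re-verified classically against the
#' encoded text, so false positives cannot appear; a search that exhausted
#' its retry budget with marked states still unfound is flagged
#' \code{aborted}, never silently truncated.
#'
#' @slot patternId character.
#' @slot found integer vector, sorted verified start indices.
#' @slot tAssumed integer, solution count the schedule assumed.
#' @slot groverApplications integer, Grover-operator applications consumed.
#' @slot attempts integer, unverified measurements consumed.
#' @slot aborted logical.
#' @slot balanced logical, TRUE when the filtered search space was close to
#'   half marked (the balanced-oracle regime where amplification stalls).
#' @slot core integer; @slot wave integer.
#' @slot gateCounts numeric, gate-family counts for this pattern's simulator.
#' @slot filter ANY, the [FilterResult-class] for the filtering algorithm,
#'   or NULL.
#' @export
setClass("MatchReport",
  representation(patternId = "character", found = "integer",
                 tAssumed = "integer", groverApplications = "integer",
                 attempts = "integer", aborted = "logical",
                 balanced = "logical", core = "integer", wave = "integer",
                 gateCounts = "numeric", filter = "ANY"))

#' CoreAssignment: round-robin mapping of patterns to emulated cores
#'
#' @slot C integer, number of emulated cores.
#' @slot assignment list, per core the assigned pattern ids in order.
#' @slot waves integer, \code{ceiling(m / C)} sequential waves.
#' @seealso [schedulePatterns()]
#' @export
setClass("CoreAssignment",
  representation(C = "integer", assignment = "list", waves = "integer"))

#' MPMResult: end-to-end multiple-pattern run
#'
#' @slot algorithm character, "enqpbea" or "enqbcea".
#' @slot reports list of [MatchReport-class], one per pattern.
#' @slot assignment a [CoreAssignment-class].
#' @slot parallelCost numeric, sum over waves of the per-wave maximum
#'   Grover-application count across cores.
#' @export
setClass("MPMResult",
  representation(algorithm = "character", reports = "list",
                 assignment = "CoreAssignment", parallelCost = "numeric"))

#' ErrorStats: correct / incorrect / missed index tallies
#'
#' Over a measurement protocol, CIP counts measurements landing on a true
#' occurrence index, IIP counts the rest, and IMP counts true indices that
#' were never measured at all. The error percentage is
#' \code{100 * IIP / (CIP + IIP)}; it is undefined (NA, \code{defined =
#' FALSE}) when no measurements were performed.
#'
#' @slot CIP integer; @slot IIP integer; @slot IMP integer.
#' @slot errorPct numeric (full precision; reports print one decimal).
#' @slot defined logical.
#' @seealso [errorStats()], [runExperimentProtocol()]
#' @export
setClass("ErrorStats",
  representation(CIP = "integer", IIP = "integer", IMP = "integer",
                 errorPct = "numeric", defined = "logical"))
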