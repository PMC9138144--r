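# Accessor generics and show methods. Slots are implementation detail;
# downstream code should use these.

#' @rdname accessors
#' @param x an object of the documented class.
#' @export
setGeneric("foundIndices", function(x) standardGeneric("foundIndices"))
#' Accessors for match, filter, count and error objects
#'
#' \code{foundIndices} returns the verified occurrence start indices of a
#' [MatchReport-class] (or all reports of an [MPMResult-class], as a named
#' list); \code{locationArray} the candidate starts of a
#' [FilterResult-class]; \code{countValue} the majority estimate of a
#' [CountEstimate-class]; \code{errorValues} the CIP/IIP/IMP/error-percent
#' vector of an [ErrorStats-class].
#'
#' @name accessors
#' @rdname accessors
#' @export
setMethod("foundIndices", "MatchReport", function(x) x@found)
#' @rdname accessors
#' @export
setMethod("foundIndices", "MPMResult", function(x)
  stats::setNames(lapply(x@reports, function(r) r@found),
                  vapply(x@reports, function(r) r@patternId, "")))

#' @rdname accessors
#' @export
setGeneric("locationArray", function(x) standardGeneric("locationArray"))
#' @rdname accessors
#' @export
setMethod("locationArray", "FilterResult", function(x) x@LA)

#' @rdname accessors
#' @export
setGeneric("countValue", function(x) standardGeneric("countValue"))
#' @rdname accessors
#' @export
setMethod("countValue", "CountEstimate", function(x) x@tHat)

#' @rdname accessors
#' @export
setGeneric("errorValues", function(x) standardGeneric("errorValues"))
#' @rdname accessors
#' @export
setMethod("errorValues", "ErrorStats", function(x)
  c(CIP = x@CIP, IIP = x@IIP, IMP = x@IMP, errorPct = x@errorPct))

setMethod("show", "Alphabet", function(object) {
  cat("Alphabet:", length(object@symbols), "symbols,",
      object@bitsPerSymbol, "bit(s) per symbol\n")
  cat(" ", paste(names(object@codes), object@codes, sep = "=",
                 collapse = "  "), "\n")
})

setMethod("show", "EncodedText", function(object) {
  cat("EncodedText: length", object@origLength,
      "padded to N =", object@N, "(n =", object@n, "address qubits)\n")
  head <- paste(utils::head(object@symbols, 40), collapse = "")
  cat("  ", head, if (object@N > 40) "...", "\n")
})

setMethod("show", "Pattern", function(object)
  cat("Pattern", object@id, ": ", paste(object@symbols, collapse = ""),
      " (M = ", object@M, ", bits ", object@bits, ")\n", sep = ""))

setMethod("show", "QuantumState", function(object) {
  cat("QuantumState:", object@nQubits, "qubits; registers:",
      paste(names(object@registers), lengths(object@registers),
            sep = ":", collapse = " "), "\n")
  cat("  norm^2 =", format(sum(Mod(object@amplitudes)^2)), "\n")
})

setMethod("show", "ANFTable", function(object) {
  cat("ANFTable:", object@nVars, "address variables ->", object@nFuncs,
      "output bits;", sum(lengths(object@monomials)), "monomials total\n")
})

setMethod("show", "IterationSchedule", function(object)
  cat("IterationSchedule: N =", object@NSearch, "t =", object@t,
      "theta =", format(object@theta, digits = 4), "rG =", object@rG, "\n"))

setMethod("show", "FilterResult", function(object) {
  cat("FilterResult: t =", object@t, "candidates (tq =", object@tq,
      "location qubits), threshold =", object@threshold,
      if (object@partial) "[partial]", "\n")
  cat("  LA:", paste(utils::head(object@LA, 20), collapse = " "),
      if (object@t > 20) "...", "\n")
})

setMethod("show", "CountEstimate", function(object)
  cat("CountEstimate (", object@method, "): t_hat = ", object@tHat,
      " [r = ", object@r, ", majority of ", object@runs, " runs]\n", sep = ""))

setMethod("show", "MatchReport", function(object) {
  cat("MatchReport ", object@patternId, " (core ", object@core, ", wave ",
      object@wave, "): found {", paste(object@found, collapse = ", "),
      "}, t_assumed = ", object@tAssumed, ", ", object@groverApplications,
      " Grover applications", if (object@aborted) " [ABORTED]",
      if (object@balanced) " [balanced oracle]", "\n", sep = "")
})

setMethod("show", "CoreAssignment", function(object) {
  cat("CoreAssignment:", object@C, "cores,", object@waves, "wave(s)\n")
  for (c in seq_len(object@C))
    cat("  core", c, ":", paste(object@assignment[[c]], collapse = " "), "\n")
})

setMethod("show", "MPMResult", function(object) {
  cat("MPMResult [", object@algorithm, "]: ", length(object@reports),
      " pattern(s), parallel cost ", object@parallelCost,
      " Grover applications\n", sep = "")
  for (r in object@reports) show(r)
})

setMethod("show", "ErrorStats", function(object) {
  pct <- if (object@defined) sprintf("%.1f%%", object@errorPct) else "undefined"
  cat("ErrorStats: CIP =", object@CIP, "IIP =", object@IIP,
      "IMP =", object@IMP, "Error% =", pct, "\n")
})
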