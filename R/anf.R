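# Algebraic-normal-form synthesis of the quantum memory's load unitary.
# Each output bit of the address -> substring-word map is a Boolean function
# of the n address variables; its ANF (XOR of AND-monomials) is the binary
# Moebius transform of its truth-table column, computed here with the
# in-place XOR butterfly in O(2^n * n) per bit.

#' Truth table of substring words over all addresses
#'
#' Row \code{i + 1} holds the bits of \code{wordAt(text, i, M)} (cyclic wrap
#' past the text end keeps the table total).
#'
#' @param text an [EncodedText-class].
#' @param M substring length in symbols (\code{M <= origLength}).
#' @return integer 0/1 matrix of dimension \code{2^n x (M * bitsPerSymbol)}.
#' @export
truthTableFromText <- function(text, M) {
  if (M < 1L) stop("M must be >= 1")
  if (M > text@origLength)
    stop("pattern length ", M, " exceeds text length ", text@origLength)
  w <- M * text@alphabet@bitsPerSymbol
  rows <- t(vapply(0:(text@N - 1L),
                   function(i) .bitStringToVec(wordAt(text, i, M)),
                   integer(w)))
  storage.mode(rows) <- "integer"
  rows
}

#' Synthesize ANF monomials from a truth table
#'
#' Applies the binary Moebius transform to each column of the table. The
#' returned monomial sets, XORed as ANDs of address variables, reproduce the
#' table exactly (the transform is an involution). Variable T0 is the most
#' significant address bit, so monomial integer \code{a} names the variables
#' at the set bit positions of \code{a} read MSB-first.
#'
#' @param table 0/1 matrix with \code{2^n} rows (one per address).
#' @return an [ANFTable-class].
#' @export
anfSynthesize <- function(table) {
  table <- as.matrix(table)
  R <- nrow(table)
  if (R < 1 || !.isPow2(R)) stop("row count must be a power of two")
  n <- .log2int(R)
  monomials <- vector("list", ncol(table))
  for (b in seq_len(ncol(table))) {
    f <- as.integer(table[, b])
    if (n > 0) for (j in 0:(n - 1)) {
      stride <- 2^j
      hi <- which(bitwAnd(0:(R - 1), stride) == stride)  # 1-based pos, bit set
      f[hi] <- bitwXor(f[hi], f[hi - stride])
    }
    monomials[[b]] <- which(f == 1L) - 1L
  }
  new("ANFTable", nVars = as.integer(n), nFuncs = ncol(table),
      monomials = monomials)
}

#' Evaluate an ANF at one address
#'
#' Each output bit is the XOR over its monomials of the AND of the named
#' address variables; the empty monomial (integer 0) is the constant 1.
#'
#' @param anf an [ANFTable-class].
#' @param address bit string (width \code{nVars}), 0/1 vector, or integer
#'   address.
#' @return bit string of width \code{nFuncs}.
#' @examples
#' tab <- truthTableFromText(encodeText("ATCG"), 1)
#' anfEvaluate(anfSynthesize(tab), "10")  # "10", the code of C
#' @export
anfEvaluate <- function(anf, address) {
  if (is.character(address)) {
    v <- .bitStringToVec(address)
    if (length(v) != anf@nVars) stop("address width must be ", anf@nVars)
    a <- .bitsToInt(v)
  } else if (length(address) > 1L) {
    if (length(address) != anf@nVars) stop("address width must be ", anf@nVars)
    a <- .bitsToInt(address)
  } else {
    a <- as.integer(address)
    if (a < 0 || a >= 2^anf@nVars) stop("address out of range")
  }
  bits <- vapply(anf@monomials, function(m) {
    if (!length(m)) return(0L)
    sum(bitwAnd(a, m) == m) %% 2L
  }, integer(1))
  .vecToBitString(bits)
}

# Evaluate all addresses at once: integer vector of word values, length 2^n.
.anfEvaluateAll <- function(anf) {
  A <- 0:(2^anf@nVars - 1)
  words <- rep(0, length(A))
  for (b in seq_len(anf@nFuncs)) {
    m <- anf@monomials[[b]]
    bit <- rep(0L, length(A))
    for (a in m) bit <- bitwXor(bit, as.integer(bitwAnd(A, a) == a))
    words <- words * 2 + bit
  }
  words
}

#' Load the quantum memory: entangle substring words with addresses
#'
#' Applies the load unitary: for every address basis component \code{|i>} of
#' the QA register, XORs the ANF-computed word for address i into the QD
#' register, producing \code{sum_i alpha_i |i>|word(i)>}. Address amplitudes
#' are untouched, so the QA marginal distribution is preserved exactly. The
#' map is a basis permutation (hence unitary) and an involution: applying it
#' twice restores QD. Loading expects (and is ordinarily given) QD in the
#' all-zero state; a nonzero QD is XOR-combined, which is what makes the
#' uncompute step of oracles work.
#'
#' The gate log records one (multi-controlled) X per monomial per output bit,
#' the AND-then-XOR realization of the ANF circuit.
#'
#' @param state a [QuantumState-class] with registers QA (width
#'   \code{nVars}) and QD (width \code{nFuncs}).
#' @param anf an [ANFTable-class].
#' @return the updated state.
#' @export
qmemLoad <- function(state, anf) {
  qa <- .regSpan(state, "QA"); qd <- .regSpan(state, "QD")
  if (length(qa) != anf@nVars) stop("QA width must equal nVars")
  if (length(qd) != anf@nFuncs) stop("QD width must equal nFuncs")
  words <- .anfEvaluateAll(anf)
  idx <- 0:(2^state@nQubits - 1)
  av <- .regValues(state, "QA")
  dv <- .regValues(state, "QD")
  lowBits <- state@nQubits - 1L - max(qd)
  place <- 2^lowBits
  dvNew <- bitwXor(as.integer(dv), as.integer(words[av + 1]))
  newIdx <- idx + (dvNew - dv) * place
  amp <- state@amplitudes
  out <- amp
  out[newIdx + 1] <- amp[idx + 1]
  state@amplitudes <- out
  nMon <- sum(lengths(anf@monomials))
  nPlain <- sum(vapply(anf@monomials, function(m) sum(m == 0L), integer(1)))
  state <- .logGate(state, "X", nPlain)
  state <- .logGate(state, "CX", nMon - nPlain)
  .checkNorm(state, 1e-9)
  state
}

#' Serialize an ANF table to plain text
#'
#' One line per output bit: comma-separated monomials, each monomial a
#' dot-separated list of variable names (T0 the most significant address
#' bit), with "1" for the constant term and "0" for an empty (constant-0)
#' function.
#'
#' @param anf an [ANFTable-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeANF <- function(anf, path) {
  lines <- c(paste("#", anf@nVars, anf@nFuncs),
             vapply(anf@monomials, function(m) {
               if (!length(m)) return("0")
               paste(vapply(m, function(a) {
                 if (a == 0L) return("1")
                 paste0("T", which(.intToBits(a, anf@nVars) == 1L) - 1L,
                        collapse = ".")
               }, ""), collapse = ",")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ANF table written by [writeANF()]
#'
#' @param path input path.
#' @return an [ANFTable-class], bit-identical to the one written.
#' @export
readANF <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(sub("^# *", "", lines[1]), " ")[[1]])
  nVars <- hdr[1]; nFuncs <- hdr[2]
  monomials <- lapply(lines[-1], function(ln) {
    if (ln == "0") return(integer(0))
    vapply(strsplit(ln, ",", fixed = TRUE)[[1]], function(tok) {
      if (tok == "1") return(0L)
      vars <- as.integer(sub("^T", "", strsplit(tok, ".", fixed = TRUE)[[1]]))
      as.integer(sum(2^(nVars - 1L - vars)))
    }, integer(1), USE.NAMES = FALSE)
  })
  new("ANFTable", nVars = nVars, nFuncs = nFuncs,
      monomials = lapply(monomials, function(m) as.integer(sort(m))))
}
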