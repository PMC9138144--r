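# Dense state-vector engine. Qubit 0 is the most significant bit of the
# basis index, so for a register spanning qubits a..b the register value of
# basis index i is (i %/% 2^(nQubits-1-b)) %% 2^(b-a+1). Multi-controlled
# gates act as direct amplitude updates; the gate log records the logical
# family {H, X, Rz, CZ, CX}.

.GATE_FAMILIES <- c("H", "X", "Rz", "CZ", "CX")

.newGateLog <- function() {
  e <- new.env(parent = emptyenv())
  e$counts <- stats::setNames(numeric(length(.GATE_FAMILIES)), .GATE_FAMILIES)
  e
}

.logGate <- function(state, family, times = 1) {
  state@gateLog$counts[[family]] <- state@gateLog$counts[[family]] + times
  invisible(state)
}

#' Create a quantum state over named registers
#'
#' Registers are allocated contiguously in the order given; all qubits start
#' in |0>. A register may have width 0 (it then has a single basis value, 0).
#'
#' @param registers named integer vector of register widths, e.g.
#'   \code{c(QA = 3L, QD = 2L)}.
#' @return a [QuantumState-class] in the all-zero basis state.
#' @examples
#' st <- quantumState(c(QA = 2L))
#' @export
quantumState <- function(registers) {
  if (is.null(names(registers)) || any(!nzchar(names(registers))))
    stop("registers must be named")
  widths <- as.integer(registers)
  if (any(widths < 0L)) stop("register widths must be non-negative")
  nQ <- sum(widths)
  if (nQ > 24L) stop("refusing to allocate more than 24 qubits (", nQ, ")")
  spans <- list()
  at <- 0L
  for (k in seq_along(widths)) {
    spans[[names(registers)[k]]] <-
      if (widths[k] > 0L) at + seq_len(widths[k]) - 1L else integer(0)
    at <- at + widths[k]
  }
  amp <- complex(real = c(1, rep(0, 2^nQ - 1)), imaginary = 0)
  new("QuantumState", nQubits = as.integer(nQ), amplitudes = amp,
      registers = spans, gateLog = .newGateLog())
}

.regSpan <- function(state, register) {
  if (!register %in% names(state@registers))
    stop("unknown register: ", register)
  state@registers[[register]]
}

# Register value of every basis index (vector over 0:(2^nQ - 1)).
.regValues <- function(state, register) {
  qs <- .regSpan(state, register)
  if (!length(qs)) return(rep(0, 2^state@nQubits))
  idx <- 0:(2^state@nQubits - 1)
  lowBits <- state@nQubits - 1L - max(qs)
  floor(idx / 2^lowBits) %% 2^length(qs)
}

# Value of all qubits outside `register` (group id for per-register ops).
.otherValues <- function(state, register) {
  qs <- .regSpan(state, register)
  idx <- 0:(2^state@nQubits - 1)
  others <- setdiff(0:(state@nQubits - 1L), qs)
  v <- rep(0, 2^state@nQubits)
  for (q in others) v <- v * 2 + floor(idx / 2^(state@nQubits - 1L - q)) %% 2
  v
}

.checkNorm <- function(state, tol = 1e-6) {
  nrm <- sum(Mod(state@amplitudes)^2)
  if (abs(nrm - 1) > tol)
    stop("state is not normalized (norm^2 = ", format(nrm), ")")
  invisible(nrm)
}

#' Apply a quantum gate
#'
#' Supported gates: \code{H}, \code{X}, \code{Rz} (with angle \code{theta}),
#' and their multi-controlled versions \code{CX}, \code{CZ} with any number
#' of control qubits. The action is a direct amplitude update (no Toffoli
#' decomposition); the gate log is incremented in the matching family.
#'
#' @param state a [QuantumState-class].
#' @param gate one of "H", "X", "Rz", "CX", "CZ".
#' @param target 0-based target qubit index.
#' @param controls integer vector of 0-based control qubits (for CX/CZ).
#' @param theta rotation angle for Rz.
#' @return the updated [QuantumState-class].
#' @export
applyGate <- function(state, gate, target, controls = integer(0), theta = NULL) {
  nQ <- state@nQubits
  if (target < 0L || target >= nQ) stop("target qubit out of range: ", target)
  if (length(controls)) {
    if (any(controls < 0L | controls >= nQ)) stop("control qubit out of range")
    if (target %in% controls || anyDuplicated(controls))
      stop("overlapping control/target sets")
  }
  idx <- 0:(2^nQ - 1)
  tbit <- floor(idx / 2^(nQ - 1L - target)) %% 2
  csel <- rep(TRUE, length(idx))
  for (c in controls) csel <- csel & (floor(idx / 2^(nQ - 1L - c)) %% 2 == 1)
  amp <- state@amplitudes
  stride <- 2^(nQ - 1L - target)
  if (gate == "H") {
    if (length(controls)) stop("controlled H is not supported")
    i0 <- which(tbit == 0)          # 1-based positions with target bit 0
    i1 <- i0 + stride
    a0 <- amp[i0]; a1 <- amp[i1]
    amp[i0] <- (a0 + a1) / sqrt(2)
    amp[i1] <- (a0 - a1) / sqrt(2)
    state <- .logGate(state, "H")
  } else if (gate == "X" || gate == "CX") {
    if (gate == "CX" && !length(controls)) stop("CX requires control qubits")
    i0 <- which(tbit == 0 & csel)
    i1 <- i0 + stride
    tmp <- amp[i0]; amp[i0] <- amp[i1]; amp[i1] <- tmp
    state <- .logGate(state, if (length(controls)) "CX" else "X")
  } else if (gate == "Rz") {
    if (is.null(theta)) stop("Rz requires theta")
    if (length(controls)) stop("controlled Rz is not supported")
    amp <- amp * ifelse(tbit == 1, exp(1i * theta / 2), exp(-1i * theta / 2))
    state <- .logGate(state, "Rz")
  } else if (gate == "CZ") {
    sel <- which(tbit == 1 & csel)
    amp[sel] <- -amp[sel]
    state <- .logGate(state, "CZ")
  } else stop("unknown gate: ", gate)
  state@amplitudes <- amp
  .checkNorm(state, 1e-9)
  state
}

#' Put a register into the uniform superposition
#'
#' Applies one Hadamard per register qubit; the register must currently be in
#' a basis state. A width-k register ends with equal real amplitudes
#' \code{1/sqrt(2^k)} over its basis values; a width-0 register is unchanged.
#'
#' @param state a [QuantumState-class].
#' @param register register name.
#' @return the updated state.
#' @export
initUniform <- function(state, register) {
  qs <- .regSpan(state, register)
  v <- .regValues(state, register)
  nz <- unique(v[Mod(state@amplitudes) > 1e-12])
  if (length(nz) > 1L)
    stop("register ", register, " is not in a basis state")
  for (q in qs) state <- applyGate(state, "H", q)
  state
}

#' Flip the phase of marked basis values of a register
#'
#' Negates the amplitude of every basis component whose register value lies
#' in \code{marked}, tensor-consistently across the other registers. Logged
#' as one multi-controlled-Z application.
#'
#' @param state a [QuantumState-class].
#' @param register register name.
#' @param marked integer vector of register basis values.
#' @return the updated state.
#' @export
phaseFlipMask <- function(state, register, marked) {
  if (!length(marked)) return(state)
  k <- length(.regSpan(state, register))
  if (any(marked < 0 | marked >= 2^k))
    stop("marked index out of range for register ", register)
  v <- .regValues(state, register)
  sel <- v %in% marked
  state@amplitudes[sel] <- -state@amplitudes[sel]
  .logGate(state, "CZ")
  state
}

#' Grover diffusion (inversion about the mean) on a register
#'
#' Reflects the register's amplitudes about their mean within each basis
#' value of the remaining qubits, i.e. applies \code{2|psi><psi| - I} on the
#' register. Logged as the standard H/X/CZ/X/H sandwich: 2k Hadamards, 2k X
#' gates and one (k-1)-controlled Z for a width-k register.
#'
#' @param state a [QuantumState-class].
#' @param register register name.
#' @return the updated state.
#' @export
applyDiffusion <- function(state, register) {
  k <- length(.regSpan(state, register))
  if (k == 0L) return(state)
  ov <- .otherValues(state, register)
  amp <- state@amplitudes
  sums <- rowsum(Re(amp), ov) + 1i * rowsum(Im(amp), ov)
  grpMean <- sums[match(ov, sort(unique(ov))), 1] / 2^k
  state@amplitudes <- 2 * grpMean - amp
  state <- .logGate(state, "H", 2 * k)
  state <- .logGate(state, "X", 2 * k)
  state <- .logGate(state, "CZ")
  .checkNorm(state, 1e-9)
  state
}

#' Measure a register
#'
#' Samples a basis value of the register with its marginal probability
#' (summing squared amplitude moduli over the other registers), collapses the
#' state consistently and renormalizes. Deterministic given the R random
#' seed.
#'
#' @param state a [QuantumState-class].
#' @param register register name.
#' @return list with \code{value} (measured basis value), \code{state} (the
#'   collapsed [QuantumState-class]) and \code{prob} (the value's
#'   pre-measurement probability).
#' @export
measureRegister <- function(state, register) {
  .checkNorm(state)
  k <- length(.regSpan(state, register))
  if (k == 0L) return(list(value = 0L, state = state, prob = 1))
  v <- .regValues(state, register)
  p <- rowsum(Mod(state@amplitudes)^2, v)[, 1]
  vals <- sort(unique(v))
  value <- vals[sample.int(length(vals), 1L, prob = p)]
  sel <- v == value
  keep <- state@amplitudes * sel
  state@amplitudes <- keep / sqrt(sum(Mod(keep)^2))
  list(value = as.integer(value), state = state,
       prob = unname(p[match(value, vals)]))
}

#' Gate-family counts accumulated by a state's simulator
#'
#' @param state a [QuantumState-class].
#' @return named numeric vector over the families H, X, Rz, CZ, CX.
#' @export
gateCounts <- function(state) state@gateLog$counts

#' Dump the gate log as plain text
#'
#' One line per gate family with its count, analogous to a QASM summary.
#'
#' @param state a [QuantumState-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeGateLog <- function(state, path) {
  cnt <- gateCounts(state)
  writeLines(paste(names(cnt), cnt, sep = "\t"), path)
  invisible(path)
}
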