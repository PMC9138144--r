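# Shared fixtures and independent oracles for the test suite. Oracles here
# deliberately avoid the package's own code paths: the Moebius transform is
# the O(4^n) pairwise-subset definition, gates are dense unitary matrices
# built from Kronecker products, and string matching goes through Biostrings.

randomDnaText <- function(N, seed) {
  set.seed(seed)
  encodeText(sample(c("A", "T", "C", "G"), N, replace = TRUE))
}

# Subset-sum Moebius transform: coefficient of monomial a is the XOR of
# f(x) over all x that are bit-subsets of a.
naiveMoebius <- function(column) {
  R <- length(column)
  vapply(0:(R - 1), function(a) {
    xs <- Filter(function(x) bitwAnd(x, a) == x, 0:(R - 1))
    sum(column[xs + 1]) %% 2L
  }, numeric(1))
}

# Dense single/controlled gate unitary on nQ qubits (qubit 0 = MSB).
denseGateMatrix <- function(nQ, gate, target, controls = integer(0),
                            theta = NULL) {
  d <- 2^nQ
  U <- matrix(0 + 0i, d, d)
  g <- switch(gate,
    H  = matrix(c(1, 1, 1, -1), 2, 2) / sqrt(2),
    X  = matrix(c(0, 1, 1, 0), 2, 2),
    Z  = diag(c(1, -1)),
    Rz = diag(c(exp(-1i * theta / 2), exp(1i * theta / 2))))
  for (col in 0:(d - 1)) {
    bits <- as.integer(floor(col / 2^((nQ - 1):0)) %% 2)
    if (length(controls) && !all(bits[controls + 1] == 1L)) {
      U[col + 1, col + 1] <- 1
    } else {
      tb <- bits[target + 1]
      for (newtb in 0:1) {
        amp <- g[newtb + 1, tb + 1]
        if (amp != 0) {
          nb <- bits; nb[target + 1] <- newtb
          row <- sum(nb * 2^((nQ - 1):0))
          U[row + 1, col + 1] <- amp
        }
      }
    }
  }
  U
}

# The eight printed ANF functions of the worked memory example, in
# monomial-integer form (T0 the most significant of four address variables:
# T0 = 8, T1 = 4, T2 = 2, T3 = 1).
workedExampleANF <- function() {
  mono <- list(
    c(2, 14),                                     # f00 = T2 + T0T1T2
    c(1, 2, 3, 6, 7, 10, 11, 13, 14, 15),         # f01
    c(1, 2, 13, 14),                              # f10
    c(0, 3, 5, 7, 9, 11, 12, 15),                 # f11 (has constant 1)
    c(0, 2, 12, 14),                              # f20
    c(0, 2, 3, 4, 5, 6, 7, 8, 9, 10, 13, 15),     # f21
    c(0, 1, 2, 11),                               # f30
    c(0, 1, 10, 12, 13, 14))                      # f31
  new("ANFTable", nVars = 4L, nFuncs = 8L,
      monomials = lapply(mono, as.integer))
}

# Planted-occurrence fixture: pattern TAA at non-overlapping starts.
plantedFixture <- function(N, t, seed, pattern = "TAA") {
  starts <- if (t > 0) as.integer(seq(0, by = 4, length.out = t)) else integer(0)
  stopifnot(t == 0 || max(starts) + nchar(pattern) <= N)
  planted <- if (t > 0) stats::setNames(list(starts), pattern) else list()
  txt <- generateSyntheticText(N, planted, seed = seed)
  list(text = txt, pattern = pattern,
       true = bruteForceMatches(txt, pattern))
}
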