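# Quantum counting: phase estimation on the Grover operator. On the
# two-dimensional invariant span of (uniform-marked, uniform-unmarked) the
# operator is a rotation by 2*theta with theta = asin(sqrt(t/N)), so its
# eigenphases are +/- 2*theta and the uniform start state splits equally
# between the two eigenvectors. Phase estimation with r precision qubits
# therefore has the closed-form outcome law implemented below, which makes
# counting simulable without 2^(n+r) amplitudes; a full-register dense
# reference (.qpeOutcomeDistributionDense) is kept for cross-checking.

# Fejer-style QPE kernel: probability of reading y when the true phase is
# phi (both as fractions of a turn), for r precision qubits.
.qpeKernel <- function(delta, r) {
  d <- ((delta + 0.5) %% 1) - 0.5
  out <- numeric(length(d))
  tiny <- abs(d) < 1e-15
  out[tiny] <- 1
  out[!tiny] <- (sin(2^r * pi * d[!tiny]) / (2^r * sin(pi * d[!tiny])))^2
  out
}

#' Outcome distribution of quantum counting phase estimation
#'
#' Probability of each phase-register reading \code{y} in \code{[0, 2^r)}
#' when estimating the Grover-operator eigenphase for \code{t} marked items
#' in a space of \code{NSearch}.
#'
#' @param NSearch search-space size (power of two).
#' @param t true number of marked items.
#' @param r precision qubits.
#' @return numeric vector of length \code{2^r} summing to 1.
#' @export
qpeOutcomeDistribution <- function(NSearch, t, r) {
  if (r < 1L) stop("r must be >= 1")
  theta <- if (t <= 0) 0 else if (t >= NSearch) pi / 2 else asin(sqrt(t / NSearch))
  phi <- theta / pi
  y <- 0:(2^r - 1)
  p <- 0.5 * .qpeKernel(phi - y / 2^r, r) + 0.5 * .qpeKernel(-phi - y / 2^r, r)
  p / sum(p)
}

# Dense full-register reference: builds the Grover operator as an explicit
# NSearch x NSearch matrix, accumulates its controlled powers and applies the
# inverse QFT analytically. Independent of the closed form above.
.qpeOutcomeDistributionDense <- function(marked, n, r) {
  N <- 2^n
  if (n + r > 16L) stop("dense reference limited to n + r <= 16")
  O <- diag(ifelse(0:(N - 1) %in% marked, -1, 1))
  D <- matrix(2 / N, N, N) - diag(N)
  G <- D %*% O
  psi <- rep(1 / sqrt(N), N)
  cols <- matrix(0 + 0i, N, 2^r)
  v <- psi
  for (x in 0:(2^r - 1)) {
    cols[, x + 1] <- v
    v <- G %*% v
  }
  y <- 0:(2^r - 1)
  P <- numeric(2^r)
  for (yy in y) {
    w <- exp(-2i * pi * (0:(2^r - 1)) * yy / 2^r)
    vec <- (cols %*% w) / 2^r
    P[yy + 1] <- sum(Mod(vec)^2)
  }
  P / sum(P)
}

# Map a phase-register reading to a solution-count estimate.
#   "round": round(NSearch * sin^2(pi y / 2^r)), the direct amplitude formula.
#   "grid":  snap the implied angle to the nearest achievable count angle
#            asin(sqrt(k/NSearch)); robust at the resolution limit.
.estimateFromOutcome <- function(y, NSearch, r, estimator = c("round", "grid")) {
  estimator <- match.arg(estimator)
  thetaHat <- pi * min(y, 2^r - y) / 2^r
  if (estimator == "round") {
    est <- round(NSearch * sin(thetaHat)^2)
  } else {
    ks <- 0:NSearch
    est <- ks[which.min(abs(asin(sqrt(ks / NSearch)) - thetaHat))]
  }
  as.integer(max(0, min(NSearch, est)))
}

#' One quantum-counting measurement
#'
#' Simulates a single phase-estimation run on the Grover operator for the
#' given marked set (or count) and returns a solution-count estimate.
#'
#' @param NSearch search-space size (power of two).
#' @param t true marked count; alternatively supply \code{marked}.
#' @param marked integer vector of marked values (its length is used).
#' @param r precision qubits (1 to 24).
#' @param estimator "round" (direct formula) or "grid" (nearest achievable
#'   count).
#' @return integer estimate in \code{[0, NSearch]}.
#' @export
qpeCountOnce <- function(NSearch, t = NULL, marked = NULL, r,
                         estimator = c("round", "grid")) {
  estimator <- match.arg(estimator)
  if (r > 24L) stop("r > 24 precision qubits exceeds simulable resources")
  if (is.null(t)) {
    if (is.null(marked)) stop("supply t or marked")
    t <- length(marked)
  }
  p <- qpeOutcomeDistribution(NSearch, t, r)
  y <- sample.int(2^r, 1L, prob = p) - 1L
  .estimateFromOutcome(y, NSearch, r, estimator)
}

.majority <- function(x) {
  tab <- table(x)
  winners <- as.integer(names(tab)[tab == max(tab)])
  min(winners)  # ties broken toward the smaller count (conservative)
}

#' Exact quantum counting (majority of repeated runs)
#'
#' Runs phase estimation with \code{n + 2} precision qubits and the grid
#' estimator, repeats \code{runs} times and takes the majority, ties toward
#' the smaller value. Two extra precision bits over the address width make
#' the phase resolution \code{pi/2^(n+2)} smaller than half the gap between
#' neighbouring count angles \code{asin(sqrt(k/N))} for every
#' \code{k < 4N/pi^2}, so the whole small-count regime the search targets is
#' resolved exactly.
#'
#' @param text,pattern optional; when given, the marked set is the
#'   exact-match set of the pattern in the text.
#' @param NSearch,t alternatively, the space size and true count directly.
#' @param runs repetitions pooled into the majority (default 10).
#' @param seed integer seed.
#' @return a [CountEstimate-class].
#' @export
exactCount <- function(text = NULL, pattern = NULL, NSearch = NULL, t = NULL,
                       runs = 10L, seed = NULL) {
  if (!is.null(text)) {
    NSearch <- text@N
    t <- length(qemMatchSet(text, pattern, mode = "mask"))
  }
  if (is.null(NSearch) || is.null(t)) stop("supply text+pattern or NSearch+t")
  n <- .log2int(NSearch)
  r <- n + 2L
  .withSeed(seed, {
    outs <- vapply(seq_len(runs), function(i)
      qpeCountOnce(NSearch, t = t, r = r, estimator = "grid"), integer(1))
    new("CountEstimate", tHat = .majority(outs), method = "exact",
        r = as.integer(r), runs = as.integer(runs),
        rawOutcomes = as.integer(outs))
  })
}

#' Approximate quantum counting at reduced precision
#'
#' Same machinery as [exactCount()] but with \code{r < n} precision qubits,
#' so the estimate carries a resolution error of order
#' \code{NSearch * pi / 2^r}; estimates use the direct rounding formula.
#'
#' @inheritParams exactCount
#' @param r precision qubits, \code{1 <= r < n}.
#' @return a [CountEstimate-class].
#' @export
approxCount <- function(text = NULL, pattern = NULL, NSearch = NULL, t = NULL,
                        r, runs = 10L, seed = NULL) {
  if (!is.null(text)) {
    NSearch <- text@N
    t <- length(qemMatchSet(text, pattern, mode = "mask"))
  }
  if (is.null(NSearch) || is.null(t)) stop("supply text+pattern or NSearch+t")
  n <- .log2int(NSearch)
  if (r >= n) stop("approximate counting requires r < n (exact regime is r >= n)")
  if (r < 1L) stop("r must be >= 1")
  .withSeed(seed, {
    outs <- vapply(seq_len(runs), function(i)
      qpeCountOnce(NSearch, t = t, r = r, estimator = "round"), integer(1))
    new("CountEstimate", tHat = .majority(outs), method = "approx",
        r = as.integer(r), runs = as.integer(runs),
        rawOutcomes = as.integer(outs))
  })
}
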