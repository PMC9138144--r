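test_that("uniform initialization spreads amplitude evenly and H is self-inverse", {
  st <- initUniform(quantumState(c(QA = 3L)), "QA")
  expect_equal(st@amplitudes, rep(complex(real = 1 / sqrt(8)), 8))
  expect_equal(unname(gateCounts(st)["H"]), 3)

  # width-0 register: nothing to do
  st0 <- quantumState(c(QA = 0L, QD = 1L))
  expect_equal(initUniform(st0, "QA")@amplitudes, st0@amplitudes)

  # applying the same Hadamards again restores the basis state
  again <- st
  for (q in 0:2) again <- applyGate(again, "H", q)
  expect_equal(Mod(again@amplitudes), c(1, rep(0, 7)), tolerance = 1e-12)

  expect_error(initUniform(st, "nope"), "unknown register")
})

test_that("gate actions match independently built dense unitaries", {
  set.seed(7)
  for (rep in 1:20) {
    nQ <- sample(2:4, 1)
    st <- quantumState(c(QA = nQ))
    amp <- complex(real = rnorm(2^nQ), imaginary = rnorm(2^nQ))
    st@amplitudes <- amp / sqrt(sum(Mod(amp)^2))
    gate <- sample(c("H", "X", "Rz", "CX", "CZ"), 1)
    target <- sample(0:(nQ - 1), 1)
    controls <- if (gate %in% c("CX", "CZ"))
      sample(setdiff(0:(nQ - 1), target), sample(1:(nQ - 1), 1)) else integer(0)
    theta <- runif(1, -pi, pi)
    out <- applyGate(st, gate, target, controls = controls, theta = theta)
    U <- denseGateMatrix(nQ, switch(gate, CX = "X", CZ = "Z", gate),
                         target, controls, theta)
    expect_equal(out@amplitudes, as.complex(U %*% st@amplitudes),
                 tolerance = 1e-10)
    # U followed by its inverse restores the state
    back <- if (gate == "Rz")
      applyGate(out, "Rz", target, theta = -theta)
    else applyGate(out, gate, target, controls = controls, theta = theta)
    expect_equal(back@amplitudes, st@amplitudes, tolerance = 1e-10)
    expect_equal(sum(Mod(out@amplitudes)^2), 1, tolerance = 1e-9)
  }
})

test_that("multi-controlled Z flips exactly the all-ones control/target component", {
  st <- quantumState(c(QA = 3L))
  st@amplitudes <- rep(complex(real = 1 / sqrt(8)), 8)
  out <- applyGate(st, "CZ", target = 2L, controls = c(0L, 1L))
  signs <- Re(out@amplitudes) * sqrt(8)
  expect_equal(signs, c(1, 1, 1, 1, 1, 1, 1, -1))  # only |111> negated
  expect_error(applyGate(st, "CZ", target = 1L, controls = 1L), "overlapping")
})

test_that("phase-flip masks negate marked register values tensor-consistently", {
  st <- initUniform(quantumState(c(QA = 2L)), "QA")
  out <- phaseFlipMask(st, "QA", 3L)
  expect_equal(Re(out@amplitudes), c(0.5, 0.5, 0.5, -0.5))

  expect_equal(phaseFlipMask(st, "QA", integer(0))@amplitudes, st@amplitudes)

  all4 <- phaseFlipMask(st, "QA", 0:3)
  expect_equal(Mod(all4@amplitudes)^2, Mod(st@amplitudes)^2)  # global phase

  expect_error(phaseFlipMask(st, "QA", 4L), "out of range")

  # consistency across an entangled second register
  st2 <- initUniform(quantumState(c(QA = 2L, QD = 1L)), "QA")
  out2 <- phaseFlipMask(st2, "QA", 2L)
  v <- GroverMatch:::.regValues(out2, "QA")
  expect_true(all(Re(out2@amplitudes[v == 2]) < 0 |
                    Mod(out2@amplitudes[v == 2]) < 1e-12))
})

test_that("measurement reproduces the Born rule and collapses the state", {
  st <- quantumState(c(QA = 3L))
  st@amplitudes <- complex(real = c(0, 0, 0, 0, 0, 1, 0, 0))
  m <- measureRegister(st, "QA")
  expect_equal(m$value, 5L)
  expect_equal(m$prob, 1)

  set.seed(11)
  draws <- replicate(20000, {
    u <- initUniform(quantumState(c(QA = 2L)), "QA")
    measureRegister(u, "QA")$value
  })
  freqs <- tabulate(draws + 1L, 4) / 20000
  expect_true(all(abs(freqs - 0.25) < 0.015))  # ~5 sigma band

  set.seed(3); a <- replicate(20, measureRegister(
    initUniform(quantumState(c(QA = 3L)), "QA"), "QA")$value)
  set.seed(3); b <- replicate(20, measureRegister(
    initUniform(quantumState(c(QA = 3L)), "QA"), "QA")$value)
  expect_identical(a, b)

  bad <- quantumState(c(QA = 1L))
  bad@amplitudes <- complex(real = c(2, 0))
  expect_error(measureRegister(bad, "QA"), "not normalized")
})

test_that("the gate log only grows and records logical families", {
  st <- quantumState(c(QA = 2L))
  st <- applyGate(st, "H", 0L)
  st <- applyGate(st, "X", 1L)
  st <- applyGate(st, "CX", 1L, controls = 0L)
  st <- applyGate(st, "Rz", 0L, theta = 0.3)
  st <- phaseFlipMask(st, "QA", 1L)
  cnt <- gateCounts(st)
  expect_equal(unname(cnt[c("H", "X", "CX", "Rz", "CZ")]), c(1, 1, 1, 1, 1))
  lg <- tempfile()
  writeGateLog(st, lg)
  expect_equal(length(readLines(lg)), 5L)
})
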