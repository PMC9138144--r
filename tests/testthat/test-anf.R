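test_that("truth tables list the substring word of every address", {
  txt <- encodeText("ATCG")
  tab <- truthTableFromText(txt, 1)
  expect_equal(tab, rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L)))

  tabAll <- truthTableFromText(txt, 4)
  expect_equal(paste(tabAll[1, ], collapse = ""), "00011011")

  allA <- truthTableFromText(encodeText("AAAA"), 2)
  expect_true(all(allA == 0L))

  expect_error(truthTableFromText(txt, 5), "exceeds")
})

test_that("synthesis produces the Moebius spectrum, naive-oracle verified", {
  # degenerate columns
  z <- anfSynthesize(matrix(0L, 8, 1))
  expect_equal(z@monomials[[1]], integer(0))
  t0 <- anfSynthesize(matrix(as.integer(0:7 >= 4), 8, 1))  # column = T0
  expect_equal(t0@monomials[[1]], 4L)                      # single monomial {T0}

  # random tables against the O(4^n) pairwise-subset Moebius definition
  set.seed(5)
  for (n in c(2, 4, 6)) {
    col <- sample(0:1, 2^n, replace = TRUE)
    fast <- anfSynthesize(matrix(as.integer(col), ncol = 1))@monomials[[1]]
    slow <- which(naiveMoebius(col) == 1L) - 1L
    expect_equal(fast, slow)
    # monomial count equals the number of ones in the spectrum
    expect_equal(length(fast), sum(naiveMoebius(col)))
  }
  expect_error(anfSynthesize(matrix(0L, 6, 1)), "power of two")
})

test_that("synthesis and evaluation are mutually inverse on random texts", {
  for (s in 1:6) {
    N <- sample(c(8, 32, 128, 1024), 1)
    txt <- randomDnaText(N, seed = 100 + s)
    M <- sample(1:3, 1)
    tab <- truthTableFromText(txt, M)
    anf <- anfSynthesize(tab)
    for (i in sample(0:(txt@N - 1), min(txt@N, 16)))
      expect_equal(anfEvaluate(anf, i), paste(tab[i + 1, ], collapse = ""))
  }
})

test_that("the printed worked-example functions evaluate and re-synthesize correctly", {
  anf <- workedExampleANF()
  expect_equal(anfEvaluate(anf, "0100"), "00011011")
  # constant-1-only survival at the all-zero address for f11
  expect_equal(substr(anfEvaluate(anf, "0000"), 4, 4), "1")
  # f00 at 1110: T2 xor T0T1T2 = 1 xor 1 = 0
  expect_equal(substr(anfEvaluate(anf, "1110"), 1, 1), "0")
  expect_error(anfEvaluate(anf, "010"), "width")

  # evaluate the system over all addresses, re-synthesize, compare monomials
  tab <- t(vapply(0:15, function(a)
    GroverMatch:::.bitStringToVec(anfEvaluate(anf, a)), integer(8)))
  round <- anfSynthesize(tab)
  expect_equal(round@monomials[[1]], c(2L, 14L))   # f00 = T2 xor T0T1T2
  for (b in 1:8)
    expect_equal(sort(round@monomials[[b]]), sort(anf@monomials[[b]]))
})

test_that("the memory load entangles words with addresses and is an involution", {
  txt <- encodeText("ATCG")
  anf <- anfSynthesize(truthTableFromText(txt, 1))
  st <- initUniform(quantumState(c(QA = 2L, QD = 2L)), "QA")
  loaded <- qmemLoad(st, anf)
  av <- GroverMatch:::.regValues(loaded, "QA")
  dv <- GroverMatch:::.regValues(loaded, "QD")
  nz <- Mod(loaded@amplitudes) > 1e-12
  expect_equal(sum(nz), 4L)
  expect_equal(dv[nz][order(av[nz])], c(0, 1, 2, 3))  # |i>|code(symbol_i)>
  expect_equal(Mod(loaded@amplitudes[nz]), rep(0.5, 4))

  # QA marginal is untouched and the norm preserved
  pQA <- rowsum(Mod(loaded@amplitudes)^2, av)[, 1]
  expect_equal(unname(pQA), rep(0.25, 4))

  twice <- qmemLoad(loaded, anf)
  expect_equal(twice@amplitudes, st@amplitudes, tolerance = 1e-12)

  # basis-address load of the worked example: |0100> -> QD = 00011011
  wex <- workedExampleANF()
  stb <- quantumState(c(QA = 4L, QD = 8L))
  stb@amplitudes[1] <- 0i
  stb@amplitudes[4 * 256 + 1] <- 1 + 0i
  outb <- qmemLoad(stb, wex)
  hot <- which(Mod(outb@amplitudes) > 0.5) - 1L
  expect_equal(hot %% 256, strtoi("00011011", base = 2))
})

test_that("ANF tables serialize to text and reload bit-exactly", {
  txt <- randomDnaText(64, seed = 9)
  anf <- anfSynthesize(truthTableFromText(txt, 2))
  f <- tempfile(fileext = ".anf")
  writeANF(anf, f)
  back <- readANF(f)
  expect_equal(back@nVars, anf@nVars)
  expect_equal(back@nFuncs, anf@nFuncs)
  expect_equal(back@monomials, anf@monomials)

  wex <- workedExampleANF()
  writeANF(wex, f)
  expect_equal(readANF(f)@monomials, wex@monomials)
})
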