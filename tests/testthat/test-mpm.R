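test_that("round-robin scheduling fills cores in waves", {
  a <- schedulePatterns(as.list(paste0("P", 1:6)), 3)
  expect_equal(a@waves, 2L)
  expect_equal(lengths(a@assignment), c(2L, 2L, 2L))
  expect_equal(a@assignment[[1]], c("P1", "P4"))

  b <- schedulePatterns(list("P1"), 3)
  expect_equal(b@assignment[[1]], "P1")
  expect_equal(lengths(b@assignment), c(1L, 0L, 0L))  # idle cores allowed
  expect_equal(b@waves, 1L)

  c3 <- schedulePatterns(as.list(paste0("P", 1:3)), 3)
  expect_equal(c3@waves, 1L)
  expect_equal(lengths(c3@assignment), rep(1L, 3))
})

test_that("qubit accounting reproduces the register formulas", {
  expect_equal(qubitsRequired("enqpbea", n = 7, M = 3)$total, 17L)
  expect_equal(qubitsRequired("enqpbea", n = 9, M = 4)$total, 21L)
  expect_equal(qubitsRequired("enqpbea", n = 7, M = 2)$total, 15L)
  bd <- qubitsRequired("enqpbea", n = 7, M = 3)$breakdown
  expect_equal(unname(bd), c(7L, 6L, 2L, 2L))

  q <- qubitsRequired("enqbcea", n = 7, t = 23)
  expect_equal(q$total, 19L)  # 14 + 5
  expect_equal(unname(q$breakdown), c(14L, 5L))
  expect_equal(qubitsRequired("enqbcea", n = 7, t = 1)$total, 14L)
})

test_that("the plain-addressing algorithm recovers every planted occurrence", {
  txt <- generateSyntheticText(128, list(TAA = c(0L, 6L)), seed = 21)
  pats <- list("TAA", "TAG", "TGA")
  res <- runEnqpbea(txt, pats, C = 3, tSource = "exact", seed = 2)
  for (r in res@reports)
    expect_equal(foundIndices(r), bruteForceMatches(txt, r@patternId))
  expect_equal(res@assignment@waves, 1L)
  expect_equal(vapply(res@reports, function(r) r@core, integer(1)), 1:3)

  # absent pattern: clean empty report
  resAbs <- runEnqpbea(txt, list("CCCC"), tSource = "brute", seed = 3)
  expect_equal(foundIndices(resAbs@reports[[1]]), integer(0))
  expect_false(resAbs@reports[[1]]@aborted)

  # determinism from the configuration seed
  r1 <- runEnqpbea(txt, pats, C = 3, tSource = "exact", seed = 11)
  r2 <- runEnqpbea(txt, pats, C = 3, tSource = "exact", seed = 11)
  expect_identical(foundIndices(r1), foundIndices(r2))
  expect_identical(r1@parallelCost, r2@parallelCost)
})

test_that("the filter-then-search algorithm matches on a toy text end to end", {
  txt <- encodeText("ATAGC")
  res <- runEnqbcea(txt, list("TAG"), threshold = 0, tSource = "brute",
                    seed = 1)
  r <- res@reports[[1]]
  expect_equal(foundIndices(r), 1L)
  expect_equal(locationArray(r@filter), 1L)
  expect_equal(r@filter@tq, 0L)
})

test_that("degenerate filtering makes both algorithms outcome-equivalent", {
  txt <- generateSyntheticText(128, list(TAA = c(5L, 50L)), seed = 33)
  pats <- list("TAA", "TGC")
  a <- runEnqpbea(txt, pats, tSource = "exact", seed = 6)
  b <- runEnqbcea(txt, pats, threshold = 3L, tSource = "exact", seed = 6)
  expect_identical(foundIndices(a), foundIndices(b))
})

test_that("filtered search stays within its query budget and flags balance", {
  txt <- generateSyntheticText(128, list(TAA = c(0L, 8L)), seed = 55)
  res <- runEnqbcea(txt, list("TAA"), threshold = 1L, tSource = "exact",
                    seed = 4)
  r <- res@reports[[1]]
  expect_equal(foundIndices(r), bruteForceMatches(txt, "TAA"))
  tFiltered <- 2^r@filter@tq
  tPrime <- length(bruteForceMatches(txt, "TAA"))
  budget <- (3 * tPrime + 10) * max(ceiling(pi / 4 * sqrt(tFiltered)), 1)
  expect_lte(r@groverApplications, pi * sqrt(tFiltered * tPrime) + budget)

  # half the filtered candidates match: balanced-oracle regime is flagged,
  # yet enumeration still completes (amplification at theta = pi/4)
  bal <- encodeText(paste(rep("CGCA", 8), collapse = ""))
  resBal <- runEnqbcea(bal, list("CG"), threshold = 1L, tSource = "brute",
                       seed = 9)
  expect_true(resBal@reports[[1]]@balanced)
  expect_equal(foundIndices(resBal@reports[[1]]),
               bruteForceMatches(bal, "CG"))

  # saturated text: every window matches, still fully enumerated
  sat <- encodeText(paste(rep("T", 32), collapse = ""))
  resSat <- runEnqbcea(sat, list("TT"), threshold = 0L, tSource = "brute",
                       seed = 9)
  expect_equal(foundIndices(resSat@reports[[1]]),
               bruteForceMatches(sat, "TT"))
})

test_that("wave accounting sums the per-wave maximum core cost", {
  txt <- generateSyntheticText(128, list(TAA = c(5L, 50L)), seed = 77)
  pats <- list("TAA", "TAG", "TGA", "TAC", "TGC", "TTT")
  res <- runEnqpbea(txt, pats, C = 3, tSource = "exact", seed = 8)
  expect_equal(res@assignment@waves, 2L)
  waves <- vapply(res@reports, function(r) r@wave, integer(1))
  apps <- vapply(res@reports, function(r) as.numeric(r@groverApplications),
                 numeric(1))
  manual <- sum(tapply(apps, waves, max))
  expect_equal(res@parallelCost, manual)

  # with C >= m, the parallel cost equals the per-pattern maximum
  one <- runEnqpbea(txt, pats, C = 6, tSource = "exact", seed = 8)
  expect_equal(one@parallelCost,
               max(vapply(one@reports, function(r)
                 as.numeric(r@groverApplications), numeric(1))))
})

test_that("both algorithms equal brute force across sizes and counts", {
  sizes <- list(`16` = c(0, 1, 2), `64` = c(0, 1, 2, 5),
                `128` = c(0, 2, 10), `256` = c(1, 5), `512` = c(2, 10))
  for (Ns in names(sizes)) {
    N <- as.integer(Ns)
    for (t in sizes[[Ns]]) {
      fx <- plantedFixture(N, t, seed = 1000 + N + t)
      for (algo in c("enqpbea", "enqbcea")) {
        res <- if (algo == "enqpbea")
          runEnqpbea(fx$text, list(fx$pattern), tSource = "exact",
                     mode = "mask", seed = N + t)
        else
          runEnqbcea(fx$text, list(fx$pattern), threshold = 1L,
                     tSource = "exact", seed = N + t)
        r <- res@reports[[1]]
        if (!r@aborted)
          expect_equal(foundIndices(r), fx$true,
                       label = paste(algo, "N =", N, "t =", t))
        else
          expect_true(all(foundIndices(r) %in% fx$true))  # never wrong, only short
      }
    }
  }
})

test_that("results serialize to TSV, JSON and gate logs", {
  txt <- generateSyntheticText(64, list(TAA = 5L), seed = 14)
  res <- runEnqpbea(txt, list("TAA"), tSource = "brute", seed = 3)
  dir <- tempfile()
  paths <- writeResults(res, dir)
  tab <- utils::read.delim(file.path(dir, "results.tsv"),
                           colClasses = list(found = "character"))
  expect_equal(tab$pattern, "TAA")
  expect_equal(tab$found, paste(foundIndices(res@reports[[1]]), collapse = ","))
  js <- jsonlite::read_json(file.path(dir, "results.json"))
  expect_equal(js$algorithm, "enqpbea")
  expect_true(file.exists(paths[3]))
})
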