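test_that("iteration schedules follow the quarter-pi rule with its edge cases", {
  expect_equal(groverIterations(128, 1)@rG, 8L)
  expect_equal(groverIterations(4, 1)@rG, 1L)
  expect_equal(groverIterations(8, 8)@rG, 0L)
  expect_equal(groverIterations(16, 0)@rG, 3L)   # floor(pi/4 * 4)
  # majority-marked spaces measure directly: one forced round could land on
  # sin^2(3*theta) = 0 at t = 3N/4
  expect_equal(groverIterations(16, 12)@rG, 0L)
  expect_gte(groverSuccessProbability(groverIterations(16, 12)) + 1e-12,
             12 / 16)
  expect_equal(groverIterations(8, 1)@theta, asin(sqrt(1 / 8)))
  expect_error(groverIterations(100, 1), "power of two")
  expect_error(groverIterations(8, 9), "\\[0, NSearch\\]")
})

test_that("the exact-match set equals brute force, in both oracle modes", {
  txt <- encodeText("ATGA")
  expect_equal(qemMatchSet(txt, "TG", mode = "mask"), 1L)
  expect_equal(qemMatchSet(txt, "TG", mode = "dense"), 1L)
  expect_equal(qemMatchSet(txt, "CC", mode = "mask"), integer(0))

  # random sweep: mask mode against brute force
  for (s in 1:60) {
    txt <- randomDnaText(sample(c(16, 64, 128, 512), 1), seed = 200 + s)
    pat <- paste(sample(c("A", "T", "C", "G"), sample(2:3, 1), replace = TRUE),
                 collapse = "")
    expect_equal(qemMatchSet(txt, pat, mode = "mask"),
                 bruteForceMatches(txt, pat))
  }
  # dense comparator circuit agrees with mask mode on small texts
  for (s in 1:10) {
    txt <- randomDnaText(sample(c(8, 16, 32), 1), seed = 300 + s)
    pat <- paste(sample(c("A", "T", "C", "G"), 2, replace = TRUE), collapse = "")
    expect_equal(qemMatchSet(txt, pat, mode = "dense"),
                 qemMatchSet(txt, pat, mode = "mask"))
  }
})

test_that("amplification follows the closed form and keeps two-value structure", {
  sched <- groverIterations(8, 1)
  expect_equal(sched@rG, 2L)
  res <- groverSearchOnce(sched, marked = 5L)
  expect_equal(res$successProb, sin(5 * asin(sqrt(1 / 8)))^2, tolerance = 1e-9)
  expect_equal(res$successProb, 0.9453125, tolerance = 1e-9)

  # two-value amplitude structure after each diffusion
  st <- initUniform(quantumState(c(QA = 4L)), "QA")
  marked <- c(3L, 9L, 12L)
  for (round in 1:3) {
    st <- phaseFlipMask(st, "QA", marked)
    st <- applyDiffusion(st, "QA")
    a <- st@amplitudes
    expect_lt(diff(range(Re(a[marked + 1L]))), 1e-9)
    expect_lt(diff(range(Re(a[-(marked + 1L)]))), 1e-9)
    expect_lt(max(Mod(Im(a))), 1e-12)
  }
})

test_that("empirical success over many seeded runs matches the closed form", {
  sched <- groverIterations(8, 1)
  p <- groverSuccessProbability(sched)
  set.seed(17)
  hits <- sum(replicate(10000, groverSearchOnce(sched, 5L)$index) == 5L)
  sigma <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(hits / 10000 - p), 3 * sigma + 1e-9)
  expect_gte(hits / 10000, sched@t / sched@NSearch)  # at least t/N

  # empty marked set: uniform outcome
  set.seed(4)
  sched0 <- groverIterations(8, 0)
  draws <- replicate(4000, groverSearchOnce(sched0, integer(0))$index)
  expect_gt(stats::chisq.test(tabulate(draws + 1L, 8))$p.value, 0.01)

  # everything marked: zero iterations, outcome uniform and always marked
  schedAll <- groverIterations(4, 4)
  resAll <- groverSearchOnce(schedAll, 0:3)
  expect_equal(resAll$rG, 0L)
  expect_true(resAll$index %in% 0:3)
})

test_that("repeat-until-all-found enumerates every occurrence within budget", {
  for (s in 1:8) {
    fx <- plantedFixture(128, t = 2, seed = 400 + s)
    rep <- searchAllOccurrences(fx$text, fx$pattern, tSource = "known",
                                tKnown = length(fx$true), seed = s)
    expect_equal(foundIndices(rep), fx$true)
    expect_false(rep@aborted)
    t <- length(fx$true)
    budget <- (3 * t + 10) * ceiling(pi / 4 * sqrt(128))
    expect_lte(rep@groverApplications, pi * sqrt(128 * t) + budget)
  }

  # absent pattern, assumed absent: budget-bounded attempts, no abort flag
  txt <- encodeText(paste(rep("A", 64), collapse = ""))
  rep0 <- searchAllOccurrences(txt, "TGC", tSource = "brute", seed = 1)
  expect_equal(foundIndices(rep0), integer(0))
  expect_false(rep0@aborted)
  expect_lte(rep0@attempts, 10L)

  # saturated case: every valid index matches, zero iterations per round
  repAll <- searchAllOccurrences(txt, "A", tSource = "brute", seed = 2)
  expect_equal(foundIndices(repAll), 0:63)
})

test_that("dense and mask oracle modes give identical measurement sequences", {
  fx <- plantedFixture(64, t = 2, seed = 77)
  a <- searchAllOccurrences(fx$text, fx$pattern, tSource = "brute",
                            mode = "dense", seed = 5)
  b <- searchAllOccurrences(fx$text, fx$pattern, tSource = "brute",
                            mode = "mask", seed = 5)
  expect_identical(foundIndices(a), foundIndices(b))
  expect_identical(a@groverApplications, b@groverApplications)
  expect_identical(a@attempts, b@attempts)
})
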