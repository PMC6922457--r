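test_that("analytic entropy handles canonical sources exactly", {
  expect_equal(analyticEntropy(matrix(0.25, 4, 4), 1), 2)
  perm <- diag(4)[, c(2, 3, 4, 1)]
  expect_equal(analyticEntropy(perm, 1), 0)
  expect_equal(analyticEntropy(c(0.5, 0.5), 0), 1)
  expect_error(analyticEntropy(matrix(1, 2, 2), 1), "sum to 1")
  expect_error(analyticEntropy(matrix(0.5, 2, 2), 2), "context rows")
})

test_that("analytic entropy matches a long-run empirical estimate", {
  set.seed(51)
  P <- matrix(rgamma(9, 1), 3); P <- P / rowSums(P)
  alph <- c(-2L, 1L, 3L)
  d <- sampleIntervalChain(P, 1e6, alph, 1)
  p <- as.integer(cumsum(c(0, d)))
  expect_equal(conditionalEntropy(lineTP(p, 1, "chain")),
               analyticEntropy(P, 1), tolerance = 0.01)
})

test_that("an order-2 source has a consistent stationary context chain", {
  set.seed(52)
  alph <- c(-1L, 2L)
  P <- matrix(rgamma(8, 1), 4); P <- P / rowSums(P) # 2^2 contexts
  H <- analyticEntropy(P, 2)
  d <- sampleIntervalChain(P, 2e5, alph, 2)
  p <- as.integer(cumsum(c(0, d)))
  expect_equal(conditionalEntropy(lineTP(p, 2, "chain")), H,
               tolerance = 0.02)
})

test_that("generation is deterministic in the seed", {
  a <- syntheticCorpus(nUnits = 3, tonesPerVoice = 60, alphabet = -3:3,
                       seed = 99)
  b <- syntheticCorpus(nUnits = 3, tonesPerVoice = 60, alphabet = -3:3,
                       seed = 99)
  c2 <- syntheticCorpus(nUnits = 3, tonesPerVoice = 60, alphabet = -3:3,
                        seed = 100)
  expect_identical(lapply(corpusLines(a), pitches),
                   lapply(corpusLines(b), pitches))
  expect_identical(analyticH(a), analyticH(b))
  expect_false(identical(lapply(corpusLines(a), pitches),
                         lapply(corpusLines(c2), pitches)))
})

test_that("zero perturbation and fixed temperature share one generator", {
  sc <- syntheticCorpus(nUnits = 2, tonesPerVoice = 50, alphabet = -2:2,
                        voicePerturbation = 0, temperatureRange = c(1, 1),
                        seed = 5)
  tps <- trueTP(sc)
  expect_equal(tps[[1]]$melody, tps[[1]]$bass)
  expect_equal(tps[[1]]$melody, tps[[2]]$melody)
})

test_that("temperature moves analytic entropy monotonically", {
  hAt <- function(tmp) mean(analyticH(syntheticCorpus(
    nUnits = 4, tonesPerVoice = 30, alphabet = -4:4,
    temperatureRange = c(tmp, tmp), seed = 8))$H_bits)
  hs <- vapply(c(0.2, 0.6, 1, 2), hAt, numeric(1))
  expect_true(all(diff(hs) > 0))
  expect_lt(hs[1], 1.5) # strongly sharpened rows approach determinism
})

test_that("rho = 1 with no perturbation yields identical voice entropies", {
  sc <- syntheticCorpus(nUnits = 6, tonesPerVoice = 30, alphabet = -3:3,
                        voicePerturbation = 0, rho = 1, seed = 13)
  h <- analyticH(sc)
  hm <- h$H_bits[h$voice == "melody"]
  hb <- h$H_bits[h$voice == "bass"]
  expect_equal(hm, hb, tolerance = 1e-12)
})

test_that("sampled lines reproduce their true source", {
  sc <- syntheticCorpus(nUnits = 1, tonesPerVoice = 20000, alphabet = -2:2,
                        modes = "major", seed = 21)
  l <- linesFor(sc, voice = "melody")[[1]]
  emp <- empiricalChainMatrix(pitches(l), -2:2)
  truth <- trueTP(sc)[[unitId(l)]]$melody
  expect_lt(max(abs(emp - truth)), 0.02)
  hTrue <- analyticH(sc)
  hTrue <- hTrue$H_bits[hTrue$voice == "melody"]
  expect_equal(conditionalEntropy(lineTP(pitches(l), 1, "chain")), hTrue,
               tolerance = 0.03)
})

test_that("invalid generator settings are rejected", {
  expect_error(syntheticCorpus(seed = 1, rho = 1.2), "rho")
  expect_error(syntheticCorpus(seed = 1, alphabet = integer(0)),
               "alphabet")
  expect_error(syntheticCorpus(seed = 1, temperatureRange = c(-1, 2)),
               "positive")
  expect_error(syntheticCorpus(seed = 1, nUnits = 10, modes = "paired"),
               "24")
  expect_error(syntheticCorpus(nUnits = 1, tonesPerVoice = 2, order = 1,
                               alphabet = -2:2, seed = 1), "exceed")
  expect_error(syntheticCorpus(nUnits = 1, tonesPerVoice = 2000,
                               alphabet = c(3L, 5L), seed = 1,
                               pitchRange = c(21L, 108L)),
               "widen the range")
})

test_that("MusicXML fixtures round-trip the generated lines exactly", {
  sc <- syntheticCorpus(nUnits = 3, tonesPerVoice = 25, alphabet = -3:3,
                        seed = 33)
  dir <- tempfile()
  man <- writeCorpusFixtures(sc, dir, graceAt = c(2, 5), unisonAt = 3,
                            tieSplitAt = 7)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "analytic_entropy.csv")))
  corpus <- loadCorpus(file.path(dir, "manifest.csv"), pitchRange = NULL,
                       quiet = TRUE)
  for (u in unitIds(sc)) for (v in c("melody", "bass")) {
    orig <- pitches(linesFor(sc, u, v)[[1]])
    back <- pitches(linesFor(corpus, u, v)[[1]])
    expect_identical(back, orig)
  }
})

test_that("fixture writing refuses crossed voices", {
  expect_error(writeMusicXMLFixture(c(60L, 50L), c(55L, 55L), tempfile()),
               "crossing")
})
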