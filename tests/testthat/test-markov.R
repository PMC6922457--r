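test_that("plug-in estimation counts and normalises correctly", {
  # deterministic alternation: conditioning on the previous interval makes
  # every transition certain
  tp <- lineTP(c(60L, 62L, 60L, 62L, 60L), 1, "chain")
  tr <- transitions(tp)
  expect_true(all(tr$prob == 1))
  expect_equal(tr$target[tr$context == "(2)"], -2L)
  expect_equal(tr$target[tr$context == "(-2)"], 2L)

  tp0 <- estimateTP(data.frame(context = "()", target = c(2L, 2L, -1L, 2L)),
                    order = 0)
  tr0 <- transitions(tp0)
  expect_equal(tr0$prob[tr0$target == 2L], 0.75)
  expect_equal(tr0$prob[tr0$target == -1L], 0.25)

  set.seed(3)
  for (i in 1:10) {
    cts <- jointToPairs(randomJoint(4, 5))
    tp <- estimateTP(cts, order = 2)
    s <- tapply(transitions(tp)$prob, transitions(tp)$context, sum)
    expect_true(all(abs(s - 1) < 1e-12))
    expect_equal(sum(contextProbs(tp)$prob), 1, tolerance = 1e-12)
  }

  expect_equal(nTransitions(estimateTP(
    data.frame(context = character(0), target = integer(0)), 1)), 0)
  expect_error(estimateTP(data.frame(context = "(1,2)", target = 1L),
                          order = 1), "mixed orders")
})

test_that("information content is the binary surprisal of observed TPs", {
  expect_equal(informationContent(c(1, 0.5, 0.25)), c(0, 1, 2))
  expect_error(informationContent(0), "\\(0, 1]")
  expect_error(informationContent(1.2), "\\(0, 1]")
})

test_that("conditional entropy evaluates the context-weighted double sum", {
  u8 <- estimateTP(data.frame(context = "()", target = rep(1:8, 2)), 0)
  expect_identical(conditionalEntropy(u8), 3)

  det <- estimateTP(data.frame(context = c("(1)", "(2)", "(3)"),
                               target = c(5L, 1L, 2L)), 2)
  expect_identical(conditionalEntropy(det), 0)

  # two equiprobable contexts, one uniform over 2 targets, one
  # deterministic: H = 0.5 * 1 + 0.5 * 0 (hand-evaluated double sum)
  half <- estimateTP(data.frame(context = c("(1)", "(1)", "(2)", "(2)"),
                                target = c(0L, 1L, 0L, 0L)), 2)
  expect_equal(conditionalEntropy(half), 0.5, tolerance = 1e-15)

  expect_error(conditionalEntropy(estimateTP(
    data.frame(context = character(0), target = integer(0)), 1),
    label = "No5/melody/order 1"), "No5/melody/order 1")
})

test_that("entropy matches an independent double-sum oracle on random joints", {
  set.seed(7)
  for (i in 1:60) {
    counts <- randomJoint(sample(2:5, 1), sample(2:5, 1))
    tp <- estimateTP(jointToPairs(counts), order = 2)
    expect_equal(conditionalEntropy(tp), oracleConditionalEntropy(counts),
                 tolerance = 1e-12)
  }
})

test_that("count pooling merges movements into one empirical distribution", {
  a <- estimateTP(data.frame(context = "(1)", target = rep(7L, 3)), 2)
  b <- estimateTP(data.frame(context = "(1)", target = 9L), 2)
  pooled <- poolTP(list(a, b))
  tr <- transitions(pooled)
  expect_equal(tr$prob[tr$target == 7L], 0.75)
  expect_equal(nTransitions(pooled), 4)

  # identical distributions pool to themselves under any weights
  ident <- poolTP(list(a, a, a), weights = c(0.1, 5, 2), method = "explicit")
  expect_equal(transitions(ident)$prob, transitions(a)$prob)

  # pooled entropy of k identical movements equals one movement's entropy
  m <- estimateTP(jointToPairs(randomJoint(3, 4)), order = 2)
  expect_equal(conditionalEntropy(poolTP(list(m, m, m))),
               conditionalEntropy(m), tolerance = 1e-12)

  expect_error(poolTP(list(a, estimateTP(
    data.frame(context = "()", target = 1L), 0))), "mixed order")
  expect_error(poolTP(list(a, b), weights = c(0, 0), method = "explicit"),
               "zero")
})

test_that("explicit pooling weights conditionals by weight times context share", {
  # piece A: context (1) only; piece B: contexts (1) and (2).
  a <- estimateTP(data.frame(context = "(1)", target = c(0L, 0L)), 2)
  b <- estimateTP(data.frame(context = c("(1)", "(2)"), target = c(1L, 0L)),
                  2)
  pooled <- poolTP(list(a, b), weights = c(1, 1), method = "explicit")
  tr <- transitions(pooled)
  # at context (1): A contributes mass 0.5 to target 0, B mass 0.25 to
  # target 1 -> P(0|(1)) = 2/3
  expect_equal(tr$prob[tr$context == "(1)" & tr$target == 0L], 2 / 3,
               tolerance = 1e-12)
  cx <- contextProbs(pooled)
  expect_equal(cx$prob[cx$context == "(1)"], 0.75, tolerance = 1e-12)
})

test_that("TP estimates are transposition invariant through the full stack", {
  set.seed(9)
  p <- cumsum(c(60L, sample(-5:5, 60, replace = TRUE)))
  for (n in 0:3) {
    base <- lineTP(p, n)
    for (k in c(-12L, 7L)) {
      shifted <- lineTP(p + k, n)
      expect_identical(transitions(base), transitions(shifted))
      expect_identical(conditionalEntropy(base), conditionalEntropy(shifted))
    }
  }
})

test_that("conditioning on longer histories does not raise entropy", {
  # population side: for an order-1 source, the interval marginal entropy
  # (order 0) is at least the conditional entropy (order 1)
  set.seed(21)
  for (i in 1:5) {
    P <- matrix(rgamma(25, 1), 5); P <- P / rowSums(P)
    st <- tonalEntropy:::.stationaryContext(P, 1L)$pi
    marg <- as.vector(st %*% P)
    H0 <- -sum(marg[marg > 0] * log2(marg[marg > 0]))
    expect_gte(H0 + 1e-12, analyticEntropy(P, 1))
  }
  # empirical side on one long line, chain convention, nested orders
  set.seed(22)
  P <- matrix(rgamma(16, 1), 4); P <- P / rowSums(P)
  d <- sampleIntervalChain(P, 4000, c(-2L, -1L, 1L, 2L), 1)
  p <- as.integer(60 + cumsum(c(0, d)))
  Hs <- vapply(0:3, function(n)
    conditionalEntropy(lineTP(p, n, "chain")), numeric(1))
  expect_true(all(diff(Hs) < 0.02))
})

test_that("long-format export mirrors the distribution tables", {
  tp <- lineTP(c(60L, 62L, 64L, 62L, 60L), 1)
  tab <- tpLongTable(list(No1 = list(melody = list("1" = tp))))
  expect_equal(names(tab), c("unit_id", "voice", "order", "context",
                             "target", "count", "prob", "ic_bits"))
  expect_equal(sum(tab$count), nTransitions(tp))
  expect_equal(tab$ic_bits, -log2(tab$prob))
})
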