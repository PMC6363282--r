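mkSequence <- function(queue, lost) {
  new("RankedSequence", queue = queue, lost = lost,
      trace = data.frame(), params = eqParams())
}

test_that("the evaluation score sums ranks and applies the tail penalty", {
  rs <- mkSequence(list("a", "b", "c"), list())
  sc <- evaluationScore(rs, c("a", "c"))
  expect_equal(sc$sigma, 4)
  expect_equal(sc$dMissing, 0)
  # nothing meaningful anywhere: zero score
  expect_equal(evaluationScore(rs, "zz")$sigma, 0)
  # one meaningful EqSet lost: penalty d (s + (l + 1) / 2)
  rs2 <- mkSequence(list("a", "b"), list("m1", "m2", "m3"))
  sc2 <- evaluationScore(rs2, c("a", "m1"))
  expect_equal(sc2$sigma, 1 + 1 * (2 + (3 + 1) / 2))
})

test_that("the printed worked-example arithmetic is reproduced", {
  # 8-long queue with meaningful sets at ranks 1-6 and 8, one meaningful
  # set among 14 lost: sigma = 29 + 1 * (8 + 7.5) = 44.5
  queue <- lapply(1:8, function(i) paste0("q", i))
  lost <- lapply(1:14, function(i) paste0("l", i))
  meaningful <- c(paste0("q", c(1:6, 8)), "l3")
  sc <- evaluationScore(mkSequence(queue, lost), meaningful)
  expect_equal(sc$rankSum, 29)
  expect_equal(sc$sigma, 44.5)
  # the DP counts 67 8-subsets of 1..22 with rank sum <= 44, of C(22,8)
  expect_equal(pvalueExact(sc$sigma, 22, 8) * choose(22, 8), 67)
})

test_that("exact DP p-values match exhaustive enumeration for n <= 9", {
  for (n in c(5, 7, 9)) {
    for (m in c(1, 2, 3)) {
      sums <- colSums(matrix(utils::combn(n, m), nrow = m))
      for (s0 in c(m * (m + 1) / 2, floor(mean(sums)), m * n)) {
        expect_equal(pvalueExact(s0, n, m), mean(sums <= s0),
                     info = sprintf("n=%d m=%d s0=%g", n, m, s0))
      }
    }
  }
})

test_that("exact p-values are nondecreasing in the score and hit the edges", {
  p <- vapply(seq(8, 44, 2), function(s) pvalueExact(s, 12, 4), 0)
  expect_true(all(diff(p) >= 0))
  expect_equal(pvalueExact(1, 3, 1), 1 / 3)
  expect_equal(pvalueExact(3 * 12, 12, 3), 1)
  expect_error(pvalueExact(10, 3, 4), "m must")
})

test_that("Monte-Carlo p-values agree with the exact DP within 3 SE", {
  mc <- pvalueMonteCarlo(30, 12, 4, reps = 20000, seed = 7)
  ex <- pvalueExact(30, 12, 4)
  expect_lt(abs(mc$estimate - ex), 3 * mc$se + 1e-12)
  # degenerate and deterministic behaviour
  one <- pvalueMonteCarlo(30, 12, 4, reps = 1, seed = 3)
  expect_true(one$estimate %in% c(0, 1))
  expect_identical(pvalueMonteCarlo(30, 12, 4, reps = 50, seed = 5)$estimate,
                   pvalueMonteCarlo(30, 12, 4, reps = 50, seed = 5)$estimate)
})

test_that("the tail penalty equals the expected lost-rank sum", {
  # m meaningful sets among l lost, appended in random order after s queued
  s <- 4; l <- 6; dMeaningful <- 2
  set.seed(9)
  sims <- replicate(20000, {
    pos <- s + sample(l, dMeaningful)
    sum(pos)
  })
  expect_equal(mean(sims), dMeaningful * (s + (l + 1) / 2), tolerance = 0.02)
})

test_that("the exact rank-sum test matches a label-permutation oracle", {
  a <- c(0.9, 0.8, 0.75)
  b <- c(0.4, 0.3, 0.5, 0.45)
  rs <- entropyRankSum(a, b)
  # oracle: enumerate all assignments of the 7 values into groups of 3/4
  x <- c(a, b)
  r <- rank(x)
  mu <- 3 * 8 / 2
  obs <- abs(sum(r[1:3]) - mu)
  cmb <- utils::combn(7, 3)
  ws <- colSums(matrix(r[cmb], nrow = 3))
  expect_equal(rs$p.value, mean(abs(ws - mu) >= obs - 1e-9))
  expect_true(rs$exact)
  # identical groups are not distinguishable
  expect_gt(entropyRankSum(c(1, 2), c(1, 2))$p.value, 0.99)
  # complete separation of two pairs: the most extreme of C(4,2) splits
  expect_equal(entropyRankSum(c(10, 11), c(1, 2))$p.value, 2 / 6)
})

test_that("tied values use mid-ranks consistently with the oracle", {
  a <- c(0.5, 0.5, 0.9)
  b <- c(0.5, 0.1)
  rs <- entropyRankSum(a, b)
  x <- c(a, b); r <- rank(x)
  mu <- 3 * 6 / 2
  obs <- abs(sum(r[1:3]) - mu)
  cmb <- utils::combn(5, 3)
  ws <- colSums(matrix(r[cmb], nrow = 3))
  expect_equal(rs$p.value, mean(abs(ws - mu) >= obs - 1e-9))
})

test_that("disease cross-validation is seeded and finds planted structure", {
  net <- netFromLines(c(
    "R1: A -> B", "R2: A -> B", "R3: B -> C", "R4: B -> C",
    "R5: C -> D", "R6: C -> D",
    "EX_A: -> A", "EX_D: D ->"))
  pm <- classifyPathways(enumerateExtremePathways(net), net)
  cpm <- compactPathways(pm)
  disease <- c("R1", "R3")
  cv1 <- diseaseCV(net, cpm, disease, x = 50, repeats = 3, seed = 4)
  cv2 <- diseaseCV(net, cpm, disease, x = 50, repeats = 3, seed = 4)
  expect_identical(cv1, cv2)
  expect_true(is.finite(cv1$chosenInterval) || is.infinite(cv1$chosenInterval))
  # disease set = everything: the top decile can only contain disease sets
  cvAll <- diseaseCV(net, cpm, paste0("R", 1:6), x = 50, repeats = 2, seed = 1)
  expect_equal(cvAll$top10Rate, 1)
})
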