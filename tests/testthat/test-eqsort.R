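profileFor <- function(net) {
  pm <- classifyPathways(enumerateExtremePathways(net), net)
  participationProfile(compactPathways(pm))
}

test_that("parameter validity enforces rhoE <= rhoS and mu >= 0", {
  expect_error(eqParams(mu = -0.1), "mu")
  expect_error(eqParams(rhoE = 5, rhoS = 2), "rhoE")
  expect_s4_class(eqParams(0.1, 3, 5, 10), "EqParams")
})

test_that("buildEqSets partitions reactions and isolates exchanges", {
  net <- parallelNet()
  pr <- profileFor(net)
  sets <- buildEqSets(pr, net)
  ids <- sort(unlist(eqsetMembers(sets)))
  expect_identical(ids, sort(reactionIds(net)))
  expect_true(all(lengths(sets@members[sets@isExchange]) == 1))
  # R1 and R2 are complementary across the two pathways: one internal EqSet
  internal <- sets@members[!sets@isExchange]
  expect_equal(length(internal), 1)
  expect_setequal(internal[[1]], c("R1", "R2"))
})

test_that("distinct employment rows give singleton EqSets", {
  net <- branchedNet()
  pr <- profileFor(net)
  sets <- buildEqSets(pr, net)
  internal <- sets@members[!sets@isExchange]
  # R1 is employed by both pathways, R2/R3 by one each (complementary pair)
  expect_equal(sort(lengths(internal)), c(1, 2))
})

test_that("a finite intra-set radius splits distant equivalent reactions", {
  # R1 and R4 carry identical employment but sit far apart in the chain
  net <- netFromLines(c(
    "R1: A -> B", "R2: B -> C", "R2b: B -> C2", "R3: C -> D", "R3b: C2 -> D",
    "R4: D -> E",
    "EX_A: -> A", "EX_E: E ->"))
  pr <- profileFor(net)
  g <- regulatoryGraph(net)
  wide <- buildEqSets(pr, net, g, rhoE = Inf)
  narrow <- buildEqSets(pr, net, g, rhoE = 1)
  sameSet <- function(sets, a, b) {
    any(vapply(sets@members, function(s) all(c(a, b) %in% s), TRUE))
  }
  expect_true(sameSet(wide, "R1", "R4"))
  expect_false(sameSet(narrow, "R1", "R4"))
})

test_that("the size bonus scales importance as 1 + mu (k - 1)", {
  net <- parallelNet()
  pr <- profileFor(net)
  sets <- buildEqSets(pr, net)
  j <- which(!sets@isExchange)[1]
  pool <- seq_along(sets@members)
  v0 <- regulatoryImportance(j, integer(0), pool, sets, pr, NULL, eqParams(mu = 0))
  v5 <- regulatoryImportance(j, integer(0), pool, sets, pr, NULL, eqParams(mu = 0.5))
  k <- length(sets@members[[j]])
  expect_equal(v5$val, v0$val * (1 + 0.5 * (k - 1)))
})

test_that("importance matches a brute-force evaluation on a small profile", {
  m <- matrix(c(1L, 0L, 1L, 0L,
                1L, 1L, 0L, 0L,
                0L, 1L, 1L, 0L), nrow = 3, byrow = TRUE,
              dimnames = list(c("x", "y", "z"), NULL))
  pr <- new("ParticipationProfile", participation = m)
  sets <- new("EqSetList", members = list("x", "y", "z"),
              isExchange = rep(FALSE, 3))
  params <- eqParams(mu = 0.3)
  # by hand: empty queue, so val(x) = H(x) + min(H(x|y), H(x|z))
  hx <- reactionEntropy(pr, "x")
  byHand <- hx + min(conditionalEntropy(pr, "x", "y"),
                     conditionalEntropy(pr, "x", "z"))
  got <- regulatoryImportance(1, integer(0), 1:3, sets, pr, NULL, params)
  expect_equal(got$val, byHand)
  expect_equal(got$nCompetitors, 2)
})

test_that("reactions employed by every pathway have zero importance", {
  m <- matrix(c(1L, 1L, 1L,
                1L, 0L, 1L), nrow = 2, byrow = TRUE,
              dimnames = list(c("const", "vary"), NULL))
  pr <- new("ParticipationProfile", participation = m)
  sets <- new("EqSetList", members = list("const", "vary"),
              isExchange = c(FALSE, FALSE))
  got <- regulatoryImportance(1, integer(0), 1:2, sets, pr, NULL, eqParams())
  expect_equal(got$val, 0)
})

test_that("the greedy sort is deterministic and label-order invariant", {
  net <- randomToyNetwork(6, 6, 3, seed = 22)
  pr <- profileFor(net)
  sets <- buildEqSets(pr, net)
  s1 <- sortEqSets(sets, pr, NULL, eqParams(mu = 0.1))
  s2 <- sortEqSets(sets, pr, NULL, eqParams(mu = 0.1))
  expect_identical(s1@queue, s2@queue)
  # permuting the EqSet list order must not change the ranked member sets
  perm <- rev(seq_along(sets@members))
  setsP <- new("EqSetList", members = sets@members[perm],
               isExchange = sets@isExchange[perm])
  s3 <- sortEqSets(setsP, pr, NULL, eqParams(mu = 0.1))
  expect_equal(lapply(s1@queue, sort), lapply(s3@queue, sort))
})

test_that("lost EqSets all have zero importance at termination", {
  net <- randomToyNetwork(6, 6, 3, seed = 35)
  pr <- profileFor(net)
  sets <- buildEqSets(pr, net)
  rs <- sortEqSets(sets, pr, NULL, eqParams(mu = 0.1))
  queued <- unlist(rs@queue)
  exq <- rs@trace$members[rs@trace$isExchange]
  cond <- unique(c(queued, unlist(strsplit(exq, ","))))
  for (lostSet in rs@lost) {
    expect_lt(conditionalEntropy(pr, lostSet, intersect(cond, reactionIds(pr))),
              1e-9)
  }
})

test_that("the sliding window and radius gate the neighbour set", {
  # three internal reactions in a chain; tiny rhoS means no neighbours
  net <- netFromLines(c(
    "R1: A -> B", "R2: B -> C", "R3: C -> D",
    "EX_A: -> A", "EX_D: D ->"))
  pr <- profileFor(net)
  g <- regulatoryGraph(net)
  sets <- buildEqSets(pr, net, g)
  params <- eqParams(mu = 0, rhoE = 0.5, rhoS = 0.5, tau = 1)
  j <- which(!sets@isExchange)[1]
  others <- setdiff(seq_along(sets@members), j)
  got <- regulatoryImportance(j, others[1:2], c(j, others[-(1:2)]), sets, pr,
                              g, params)
  expect_equal(got$nNeighbors, 0)
})

test_that("a single informative EqSet yields a queue of length one", {
  net <- chainNet()
  pr <- profileFor(net)
  sets <- buildEqSets(pr, net)
  rs <- sortEqSets(sets, pr, NULL, eqParams())
  # every reaction is employed by the single pathway: all entropies zero
  expect_equal(length(rs@queue), 0)
  net2 <- parallelNet()
  pr2 <- profileFor(net2)
  sets2 <- buildEqSets(pr2, net2)
  rs2 <- sortEqSets(sets2, pr2, NULL, eqParams())
  expect_equal(length(rs2@queue), 1)
})
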