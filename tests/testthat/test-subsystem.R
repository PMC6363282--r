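subsysNet <- function() {
  netFromLines(c(
    "R1: A -> B | target",
    "R2: B -> C | target",
    "R3: C -> D | other",
    "R4: D -> E | other",
    "EX_A: -> A", "EX_E: E ->"))
}

test_that("partitioning splits internal reactions and finds shared metabolites", {
  net <- subsysNet()
  part <- partitionBySubsystem(net, "target")
  expect_setequal(part$targetIds, c("R1", "R2"))
  expect_setequal(part$surroundingIds, c("R3", "R4"))
  # C is made in the target and consumed in the surrounding subsystem
  expect_identical(part$sharedMetabolites, "C")
  # whole-network partition has nothing shared and nothing surrounding
  whole <- partitionBySubsystem(net, c("target", "other"))
  expect_length(whole$surroundingIds, 0)
  expect_length(whole$sharedMetabolites, 0)
  expect_error(partitionBySubsystem(net, "nope"), "available")
})

test_that("augmentation adds one duplicate and one link per shared metabolite", {
  net <- subsysNet()
  part <- partitionBySubsystem(net, "target")
  aug <- augmentWithLinks(net, part)
  expect_equal(nMetabolites(aug), nMetabolites(net) + 1)
  expect_equal(nReactions(aug), nReactions(net) + 1)
  expect_true("LINK_C" %in% reactionIds(aug))
  expect_true(aug@metabolites$isDuplicate[aug@metabolites$id == "C'"])
  # the surrounding reaction now consumes the duplicate
  expect_equal(unname(stoichiometry(aug)["C'", "R3"]), -1)
  expect_equal(unname(stoichiometry(aug)["C", "R3"]), 0)
  # no shared metabolites: untouched network
  whole <- partitionBySubsystem(net, c("target", "other"))
  expect_identical(augmentWithLinks(net, whole), net)
})

test_that("flux variability solves the hand-computable chain", {
  net <- netFromLines(c("EX_A: -> A", "R1: A -> B", "EX_B: B ->"))
  net@reactions$upperBound <- c(10, 1000, 10)
  fv <- fluxVariability(net, "R1")
  expect_equal(fv$min, 0, tolerance = 1e-8)
  expect_equal(fv$max, 10, tolerance = 1e-8)
})

test_that("blocked reactions have a zero flux range", {
  net <- netFromLines(c("R1: A -> B", "EX_A: -> A"))  # B is a dead end
  fv <- fluxVariability(net, "R1")
  expect_equal(fv$min, 0, tolerance = 1e-8)
  expect_equal(fv$max, 0, tolerance = 1e-8)
})

test_that("a reversible isolated cycle spans negative and positive flux", {
  net <- netFromLines(c("R1: A <-> B", "R2: B <-> A", "EX_A: A <->"))
  fv <- suppressWarnings(fluxVariability(net, "R1"))
  expect_lt(fv$min, 0)
  expect_gt(fv$max, 0)
})

test_that("link-reaction augmentation leaves every flux range unchanged", {
  # the flux space over original reactions must be invariant
  for (seed in c(2, 6)) {
    net <- randomToyNetwork(5, 5, 2, seed = seed)
    labs <- rep(c("t", "s"), length.out = sum(net@reactions$kind == "internal"))
    net@reactions$subsystem[net@reactions$kind == "internal"] <- labs
    part <- partitionBySubsystem(net, "t")
    if (!length(part$sharedMetabolites)) next
    aug <- augmentWithLinks(net, part)
    before <- suppressWarnings(fluxVariability(net))
    after <- suppressWarnings(fluxVariability(aug, reactionIds(net)))
    expect_equal(before$min, after$min, tolerance = 1e-6)
    expect_equal(before$max, after$max, tolerance = 1e-6)
  }
})

test_that("exchange constraints follow the four flux-range cases", {
  # target makes C (out-only), consumes F (in-only), trades B both ways,
  # and G is blocked (no exchange added)
  net <- netFromLines(c(
    "R1: A -> B | target",
    "R2: B -> C | target",
    "R5: F -> B | target",
    "R7: G -> H | target",
    "R3: C -> D | other",
    "R4: B <-> D | other",
    "R6: D -> F | other",
    "EX_A: -> A", "EX_D: D ->"))
  part <- partitionBySubsystem(net, "target")
  out <- assignExchangeConstraints(net, part)
  cases <- out$cases
  expect_setequal(cases$metabolite, c("B", "C", "F"))
  expect_equal(cases$case[cases$metabolite == "C"], "out")
  expect_equal(cases$case[cases$metabolite == "F"], "in")
  expect_equal(cases$case[cases$metabolite == "B"], "unconstrained")
  tn <- out$network
  expect_true("EXT_C" %in% reactionIds(tn))
  expect_false(isReversible(tn)[["EXT_C"]])
  expect_true(isReversible(tn)[["EXT_B"]])
  # the blocked metabolite pair G/H contributes no exchange
  expect_false(any(grepl("EXT_G", reactionIds(tn))))
  # target network keeps only target internals plus exchanges
  kinds <- reactionKind(tn)
  expect_setequal(names(kinds)[kinds == "internal"], c("R1", "R2", "R5", "R7"))
})

test_that("extreme pathways of the constrained target are enumerable", {
  net <- subsysNet()
  part <- partitionBySubsystem(net, "target")
  out <- assignExchangeConstraints(net, part)
  pm <- classifyPathways(enumerateExtremePathways(out$network), out$network)
  expect_gte(nPathways(pm), 1)
  V <- compactVectors(pm, keepTypes = c("I", "II"))
  S <- stoichiometry(out$network)
  expect_lt(max(abs(S[, rownames(V)] %*% V)), 1e-9)
})
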