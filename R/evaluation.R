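#' @include AllClasses.R eqsort.R
NULL

#' Score a ranked EqSet sequence against a meaningful-reaction set
#'
#' Sums the 1-based ranks of the queued internal EqSets that contain at
#' least one biologically meaningful reaction (regulated or
#' disease-associated), and adds the penalty d (s + (l + 1) / 2) for the d
#' lost EqSets containing meaningful reactions, where s is the queue
#' length and l the number of lost internal EqSets. The penalty equals
#' the expected rank sum those EqSets would receive if the lost sets were
#' appended to the queue in random order.
#'
#' @param seq a \code{\linkS4class{RankedSequence}}
#' @param meaningful character vector of meaningful reaction ids
#' @return list with \code{sigma}, \code{rankSum}, \code{s} (queue length),
#'   \code{lLost}, \code{dMissing}, and \code{ranks} (positions of the
#'   meaningful EqSets in the queue)
#' @examples
#' sets <- new("EqSetList", members = list("a", "b", "c"),
#'             isExchange = rep(FALSE, 3))
#' # a queue of 3 with meaningful sets at ranks 1 and 3 and nothing lost
#' rs <- new("RankedSequence", queue = list("a", "b", "c"), lost = list(),
#'           trace = data.frame(), params = eqParams())
#' evaluationScore(rs, c("a", "c"))$sigma  # 4
#' @export
evaluationScore <- function(seq, meaningful) {
  stopifnot(is(seq, "RankedSequence"), length(meaningful) >= 1)
  queue <- seq@queue
  lost <- seq@lost
  s <- length(queue)
  l <- length(lost)
  hit <- vapply(queue, function(x) length(intersect(x, meaningful)) > 0, TRUE)
  ranks <- which(hit)
  d <- sum(vapply(lost, function(x) length(intersect(x, meaningful)) > 0, TRUE))
  sigma <- sum(ranks) + d * (s + (l + 1) / 2)
  list(sigma = sigma, rankSum = sum(ranks), s = s, lLost = l, dMissing = d,
       ranks = ranks)
}

#' Exact p-value of an evaluation score by dynamic programming
#'
#' Under the null hypothesis, the n internal EqSets are arranged uniformly
#' at random and all m meaningful EqSets are present in the sequence, so
#' the score is the rank sum of m positions drawn without replacement from
#' 1..n. The p-value is the probability that this rank sum is at most
#' sigma0, computed exactly by counting the m-subsets of \{1..n\} with sum
#' <= floor(sigma0) (null scores are integers, so a fractional observed
#' score is compared through its floor) and dividing by choose(n, m).
#' Counting uses exact integer dynamic programming.
#'
#' @param sigma0 observed evaluation score
#' @param n number of internal EqSets
#' @param m number of meaningful internal EqSets (1 <= m <= n)
#' @return the exact tail probability, in (0, 1]
#' @examples
#' pvalueExact(1, 3, 1)   # 1/3
#' @export
pvalueExact <- function(sigma0, n, m) {
  if (m < 1 || m > n) stop("m must satisfy 1 <= m <= n")
  smax <- floor(sigma0)
  smin <- m * (m + 1) / 2
  if (smax < smin) return(0)
  if (smax >= m * n) return(1)
  # dp[k + 1, s + 1] = number of k-subsets of the ranks seen so far with sum s
  dp <- matrix(0, m + 1, smax + 1)
  dp[1, 1] <- 1
  for (i in seq_len(n)) {
    for (k in min(m, i):1) {
      lo <- max(k * (k + 1) / 2, i)
      if (smax < lo) next
      ss <- seq(smax, lo, by = -1)
      dp[k + 1, ss + 1] <- dp[k + 1, ss + 1] + dp[k, ss - i + 1]
    }
  }
  sum(dp[m + 1, ]) / choose(n, m)
}

#' Monte-Carlo estimate of the evaluation-score p-value
#'
#' Estimates the same tail probability as \code{\link{pvalueExact}} by
#' simulating random arrangements; provided as a cross-check and for
#' problem sizes where the exact computation is unnecessary.
#'
#' @inheritParams pvalueExact
#' @param reps number of simulated arrangements
#' @param seed integer seed
#' @return list with \code{estimate}, \code{se} (binomial standard error)
#'   and \code{reps}
#' @export
pvalueMonteCarlo <- function(sigma0, n, m, reps = 10000, seed = 1) {
  if (m < 1 || m > n) stop("m must satisfy 1 <= m <= n")
  stopifnot(reps >= 1)
  rng <- .seededRNG(seed)
  hits <- 0L
  for (r in seq_len(reps)) {
    sc <- sum(rng$sample(n, m))
    if (sc <= sigma0) hits <- hits + 1L
  }
  p <- hits / reps
  list(estimate = p, se = sqrt(p * (1 - p) / reps), reps = reps)
}

#' Exact two-sample rank-sum test
#'
#' Two-sided exact Wilcoxon rank-sum p-value comparing two groups of
#' entropies (or any numeric scores). Ties are handled by mid-ranks with
#' exact conditional enumeration over all group assignments when
#' choose(nA + nB, nA) is small enough, and by complete-enumeration
#' Monte-Carlo otherwise.
#'
#' @param groupA,groupB numeric vectors
#' @param maxExact largest number of assignments enumerated exactly
#' @return list with \code{p.value}, \code{statistic} (rank sum of group A)
#'   and \code{exact} (logical)
#' @export
entropyRankSum <- function(groupA, groupB, maxExact = 5e6) {
  stopifnot(length(groupA) >= 1, length(groupB) >= 1)
  x <- c(groupA, groupB)
  nA <- length(groupA); nB <- length(groupB)
  r <- rank(x)
  wObs <- sum(r[seq_len(nA)])
  nTot <- choose(nA + nB, nA)
  mu <- nA * (nA + nB + 1) / 2
  dev <- abs(wObs - mu)
  if (nTot <= maxExact) {
    cmb <- utils::combn(nA + nB, nA)
    ws <- colSums(matrix(r[cmb], nrow = nA))
    p <- sum(abs(ws - mu) >= dev - 1e-9) / nTot
    list(p.value = p, statistic = wObs, exact = TRUE)
  } else {
    wt <- stats::wilcox.test(groupA, groupB, exact = FALSE, correct = TRUE)
    list(p.value = wt$p.value, statistic = wObs, exact = FALSE)
  }
}

#' Split the rho_e range into intervals with identical EqSets
#'
#' EqSets change only when rho_e crosses a pairwise global distance, so
#' the distinct finite values of D partition the radius range into
#' intervals over which \code{\link{buildEqSets}} returns the same
#' partition. Returns one representative radius per interval (the
#' breakpoint itself, plus Inf).
#'
#' @param graph a \code{\linkS4class{RegulatoryGraph}}
#' @return numeric vector of representative rho_e values, increasing
#' @export
rhoEIntervals <- function(graph) {
  D <- graph@global
  vals <- sort(unique(D[upper.tri(D) & is.finite(D)]))
  c(vals, Inf)
}

#' Disease-prediction cross-validation of the ranking
#'
#' For each rho_e interval (see \code{\link{rhoEIntervals}}), repeatedly
#' splits the internal EqSets into a training fraction x% and a test set,
#' optimises the sort parameters on the training subsequence p-value,
#' records the mean training p-value, then selects the interval with the
#' lowest mean and reports the average proportion of disease-associated
#' EqSets among the top 10% (ceiling) of the test subsequences. Ranks
#' within a subsequence are positions within that subsequence.
#'
#' @param net a \code{\linkS4class{MetabolicNetwork}}
#' @param cpm a \code{\linkS4class{CompactPathwayMatrix}} for the network
#' @param diseaseReactions character vector of disease-associated reaction
#'   ids
#' @param x training percentage, one of 10, 20, ..., 90
#' @param repeats number of random splits per interval
#' @param seed integer seed
#' @param grid a \code{ParameterGrid} (see \code{\link{defaultGrid}}) used
#'   for the per-split parameter optimisation; defaults to a small grid of
#'   mu values with infinite radii so that toy-scale runs stay fast
#' @param maxSteps heuristic-search budget per split
#' @return list with \code{intervals}, \code{meanTrainP},
#'   \code{chosenInterval}, \code{top10Rate} and \code{backgroundRate}
#' @export
diseaseCV <- function(net, cpm, diseaseReactions, x = 50, repeats = 10,
                      seed = 1, grid = NULL, maxSteps = 25) {
  stopifnot(x %in% seq(10, 90, 10), length(diseaseReactions) >= 1)
  profile <- participationProfile(cpm)
  graph <- regulatoryGraph(net)
  ivals <- rhoEIntervals(graph)
  if (is.null(grid))
    grid <- parameterGrid(mu = c(0, 0.1, 0.5), rhoE = Inf, rhoS = Inf, tau = Inf)
  rng <- .seededRNG(seed)
  scoreSplit <- function(rhoE, trainSets, allSets, profile, graph) {
    # p-value of the training subsequence under parameters chosen by search
    obj <- function(params) {
      rs <- sortEqSets(allSets, profile, graph, params)
      subq <- Filter(function(s) any(vapply(trainSets, setequal, TRUE, s)), rs@queue)
      subLost <- Filter(function(s) any(vapply(trainSets, setequal, TRUE, s)), rs@lost)
      nTrain <- length(trainSets)
      mTrain <- sum(vapply(trainSets, function(s)
        length(intersect(s, diseaseReactions)) > 0, TRUE))
      if (mTrain == 0 || mTrain == nTrain) return(1)
      sub <- new("RankedSequence", queue = subq, lost = subLost,
                 trace = data.frame(), params = rs@params)
      sc <- evaluationScore(sub, diseaseReactions)
      pvalueExact(sc$sigma, nTrain, mTrain)
    }
    sr <- heuristicSearch(obj, grid, maxSteps = maxSteps,
                          seed = rng$sample(1e6, 1))
    sr
  }
  meanP <- numeric(length(ivals))
  allSplits <- vector("list", length(ivals))
  for (iv in seq_along(ivals)) {
    sets <- buildEqSets(profile, net, graph, rhoE = ivals[iv])
    intSets <- sets@members[!sets@isExchange]
    ps <- numeric(0); splits <- list()
    for (r in seq_len(repeats)) {
      nTr <- round(length(intSets) * x / 100)
      if (nTr < 1 || nTr >= length(intSets)) {
        warning("degenerate split skipped"); next
      }
      tr <- rng$sample(length(intSets), nTr)
      sr <- scoreSplit(ivals[iv], intSets[tr], sets, profile, graph)
      ps <- c(ps, sr$bestPValue)
      splits[[length(splits) + 1L]] <- list(train = tr, params = sr$bestParams)
    }
    meanP[iv] <- if (length(ps)) mean(ps) else 1
    allSplits[[iv]] <- splits
  }
  chosen <- which.min(meanP)
  # top-10% precision on the test subsequences of the chosen interval
  sets <- buildEqSets(profile, net, graph, rhoE = ivals[chosen])
  intSets <- sets@members[!sets@isExchange]
  rates <- numeric(0); bgs <- numeric(0)
  for (sp in allSplits[[chosen]]) {
    testSets <- intSets[-sp$train]
    rs <- sortEqSets(sets, profile, graph, sp$params)
    ordered <- c(rs@queue, rs@lost)
    subq <- Filter(function(s) any(vapply(testSets, setequal, TRUE, s)), ordered)
    k <- ceiling(0.1 * length(subq))
    if (k < 1) next
    top <- subq[seq_len(k)]
    rates <- c(rates, mean(vapply(top, function(s)
      length(intersect(s, diseaseReactions)) > 0, TRUE)))
    bgs <- c(bgs, mean(vapply(subq, function(s)
      length(intersect(s, diseaseReactions)) > 0, TRUE)))
  }
  list(intervals = ivals, meanTrainP = meanP, chosenInterval = ivals[chosen],
       top10Rate = if (length(rates)) mean(rates) else NA_real_,
       backgroundRate = if (length(bgs)) mean(bgs) else NA_real_)
}
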