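#' @include AllClasses.R infotheory.R regdistance.R
NULL

.VAL_TOL <- 1e-12

#' Construct the greedy-sort parameter object
#'
#' @param mu size-bonus ratio, >= 0; a k-member EqSet's importance is
#'   weighted by 1 + mu (k - 1).
#' @param rhoE intra-EqSet effective radius (> 0, possibly Inf): every
#'   member of an EqSet must have a counterpart within this global
#'   regulatory distance.
#' @param rhoS inter-EqSet effective radius (> 0, possibly Inf): only
#'   EqSets within this distance act as regulatory neighbours or
#'   competitors. Must be at least rhoE.
#' @param tau sliding-window size on the ranked queue (>= 1, possibly Inf):
#'   at most tau of the most recent queue members count as neighbours.
#' @return an \code{\linkS4class{EqParams}}
#' @examples
#' eqParams(mu = 0.1)   # radii and window default to Inf
#' @export
eqParams <- function(mu = 0, rhoE = Inf, rhoS = Inf, tau = Inf) {
  new("EqParams", mu = mu, rhoE = rhoE, rhoS = rhoS, tau = tau)
}

#' Group reactions into equivalent sets on Shannon entropy
#'
#' Each exchange reaction forms a singleton EqSet. Internal (and link)
#' reactions are partitioned by mutual zero conditional entropy - each
#' pair of members determines one another's on/off state - refined into
#' connected components of the threshold graph D <= rhoE, so that every
#' member has a counterpart within the intra-EqSet radius.
#'
#' @param profile a \code{\linkS4class{ParticipationProfile}} covering the
#'   network's reactions
#' @param net the \code{\linkS4class{MetabolicNetwork}}
#' @param graph a \code{\linkS4class{RegulatoryGraph}} (needed when rhoE is
#'   finite; may be NULL otherwise)
#' @param rhoE intra-EqSet effective radius
#' @param equivalence passed to \code{\link{equivalentCouple}}
#' @return an \code{\linkS4class{EqSetList}}
#' @export
buildEqSets <- function(profile, net, graph = NULL, rhoE = Inf,
                        equivalence = c("literal", "identical_support")) {
  stopifnot(is(profile, "ParticipationProfile"), is(net, "MetabolicNetwork"))
  equivalence <- match.arg(equivalence)
  if (is.finite(rhoE) && is.null(graph))
    stop("a RegulatoryGraph is required for finite rhoE")
  exch <- isExchange(net)
  ids <- reactionIds(net)
  internal <- ids[!exch[ids]]
  m <- profile@participation
  key <- apply(m[internal, , drop = FALSE], 1, paste, collapse = "")
  keyc <- apply(1L - m[internal, , drop = FALSE], 1, paste, collapse = "")
  ng <- length(internal)
  grp <- integer(ng)
  g <- 0
  for (i in seq_len(ng)) if (grp[i] == 0) {
    g <- g + 1; grp[i] <- g
    for (j in seq_len(ng)) if (j > i && grp[j] == 0) {
      same <- if (equivalence == "identical_support") key[j] == key[i]
              else key[j] == key[i] || keyc[j] == key[i]
      if (same) grp[j] <- g
    }
  }
  classes <- unname(split(internal, grp))
  if (is.finite(rhoE)) {
    D <- graph@global
    refined <- list()
    for (cl in classes) {
      if (length(cl) == 1) { refined[[length(refined) + 1L]] <- cl; next }
      sub <- D[cl, cl, drop = FALSE] <= rhoE
      diag(sub) <- TRUE
      gi <- igraph::components(igraph::graph_from_adjacency_matrix(
        sub, mode = "undirected"))$membership
      refined <- c(refined, unname(split(cl, gi)))
    }
    classes <- refined
  }
  members <- c(classes, as.list(ids[exch[ids]]))
  new("EqSetList", members = members,
      isExchange = c(rep(FALSE, length(classes)), rep(TRUE, sum(exch))))
}

# neighbour and competitor sets for pool EqSet j; queue/pool hold indices
# into sets@members
.neighborsCompetitors <- function(j, queueIdx, poolIdx, sets, graph, params) {
  mem <- sets@members
  within <- function(u) {
    if (is.infinite(params@rhoS)) TRUE
    else eqsetDistance(graph, mem[[j]], mem[[u]]) <= params@rhoS
  }
  nearQ <- queueIdx[vapply(queueIdx, within, TRUE)]
  if (is.finite(params@tau) && length(nearQ) > params@tau)
    nearQ <- utils::tail(nearQ, params@tau)
  comp <- setdiff(poolIdx, j)
  comp <- comp[vapply(comp, within, TRUE)]
  list(neighbors = nearQ, competitors = comp)
}

#' Regulatory importance of an EqSet
#'
#' The importance of a candidate EqSet X given the current queue is
#' \deqn{[1 + \mu(|X|-1)] [H(X | \hat N) + \min_{U \in C} H(X | \hat N \cup U)]}
#' where \eqn{\hat N} is the union of reactions of the (at most tau most
#' recent) queued EqSets within distance rhoS, and C the competing pool
#' EqSets within rhoS. The first term is the information the set still
#' provides about the pathway state; the second its non-substitutability.
#' With no competitor in range, the minimum term defaults to
#' \eqn{H(X|\hat N)}: nothing can substitute for X.
#'
#' @param j index of the candidate within \code{sets}
#' @param queueIdx,poolIdx integer indices of queued / remaining EqSets
#' @param sets an \code{\linkS4class{EqSetList}}
#' @param profile a \code{\linkS4class{ParticipationProfile}}
#' @param graph a \code{\linkS4class{RegulatoryGraph}} (may be NULL when
#'   rhoS is infinite)
#' @param params an \code{\linkS4class{EqParams}}
#' @return list with \code{val}, \code{nNeighbors}, \code{nCompetitors}
#' @export
regulatoryImportance <- function(j, queueIdx, poolIdx, sets, profile, graph,
                                 params) {
  nc <- .neighborsCompetitors(j, queueIdx, poolIdx, sets, graph, params)
  Xj <- sets@members[[j]]
  Nhat <- unique(unlist(sets@members[nc$neighbors]))
  h1 <- conditionalEntropy(profile, Xj, Nhat)
  h2 <- if (length(nc$competitors)) {
    min(vapply(nc$competitors, function(u)
      conditionalEntropy(profile, Xj, union(Nhat, sets@members[[u]])), 0))
  } else h1
  w <- 1 + params@mu * (length(Xj) - 1)
  list(val = w * (h1 + h2),
       nNeighbors = length(nc$neighbors), nCompetitors = length(nc$competitors))
}

#' Greedy sort of EqSets by regulatory importance
#'
#' Starting from a pool of all EqSets (exchange EqSets included) and an
#' empty queue, repeatedly evaluates the regulatory importance of every
#' pool EqSet and moves the argmax to the end of the queue, until the pool
#' is empty or every remaining importance is zero. Exchange EqSets compete
#' and condition the neighbourhood while queued but are removed from the
#' output; ranks are 1-based positions among the remaining internal
#' EqSets. Ties in the argmax go to the EqSet with the lexicographically
#' smallest member id, making the output independent of construction
#' order.
#'
#' @param sets an \code{\linkS4class{EqSetList}}
#' @param profile a \code{\linkS4class{ParticipationProfile}}
#' @param graph a \code{\linkS4class{RegulatoryGraph}} (may be NULL when
#'   both radii are infinite)
#' @param params an \code{\linkS4class{EqParams}}
#' @return a \code{\linkS4class{RankedSequence}}
#' @export
sortEqSets <- function(sets, profile, graph = NULL, params = eqParams()) {
  stopifnot(is(sets, "EqSetList"), is(profile, "ParticipationProfile"),
            is(params, "EqParams"))
  if (is.finite(params@rhoS) && is.null(graph))
    stop("a RegulatoryGraph is required for finite rhoS")
  pool <- seq_along(sets@members)
  queue <- integer(0)
  trace <- list()
  repeat {
    if (!length(pool)) break
    evals <- lapply(pool, regulatoryImportance, queueIdx = queue,
                    poolIdx = pool, sets = sets, profile = profile,
                    graph = graph, params = params)
    vals <- vapply(evals, `[[`, 0, "val")
    if (max(vals) <= .VAL_TOL) break
    top <- which(vals >= max(vals) - .VAL_TOL)
    if (length(top) > 1) {
      # locale-independent tie-break: case-insensitive byte order of the
      # smallest member id
      keys <- vapply(pool[top], function(j)
        sort(tolower(sets@members[[j]]), method = "radix")[1], "")
      pick <- top[order(keys, method = "radix")[1]]
    } else pick <- top
    jj <- pool[pick]
    trace[[length(trace) + 1L]] <- data.frame(
      step = length(trace) + 1L,
      members = paste(sort(sets@members[[jj]]), collapse = ","),
      val = vals[pick],
      nNeighbors = evals[[pick]]$nNeighbors,
      nCompetitors = evals[[pick]]$nCompetitors,
      isExchange = sets@isExchange[jj],
      stringsAsFactors = FALSE)
    queue <- c(queue, jj)
    pool <- pool[pool != jj]
  }
  internalQ <- queue[!sets@isExchange[queue]]
  internalAll <- which(!sets@isExchange)
  lost <- setdiff(internalAll, internalQ)
  new("RankedSequence",
      queue = sets@members[internalQ],
      lost = sets@members[lost],
      trace = if (length(trace)) do.call(rbind, trace) else
        data.frame(step = integer(0), members = character(0), val = numeric(0),
                   nNeighbors = integer(0), nCompetitors = integer(0),
                   isExchange = logical(0)),
      params = params)
}
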