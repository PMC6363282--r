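#' @include AllClasses.R
NULL

#' Consumer count C(M) of a metabolite
#'
#' The number of reactions that use M as a substrate. Any metabolite
#' involved in a reversible reaction counts as both a substrate and a
#' product of it, so reversible reactions contribute regardless of the
#' side M appears on.
#'
#' @param net a \code{\linkS4class{MetabolicNetwork}}
#' @param metaboliteId metabolite id
#' @return integer count
#' @export
consumerCount <- function(net, metaboliteId) {
  stopifnot(is(net, "MetabolicNetwork"))
  if (!metaboliteId %in% metaboliteIds(net))
    stop("unknown metabolite: ", metaboliteId)
  row <- net@S[metaboliteId, ]
  rev <- net@reactions$reversible
  sum(row < 0 | (rev & row != 0))
}

.consumerCounts <- function(net) {
  rev <- net@reactions$reversible
  vapply(metaboliteIds(net), function(m) {
    row <- net@S[m, ]
    sum(row < 0 | (rev & row != 0))
  }, 0)
}

#' Local regulatory distance between two reactions
#'
#' Zero for a reaction and itself; infinite when the two reactions share
#' no metabolite; otherwise the smallest consumer count C(M) over the
#' shared metabolites M. A flux change in one reaction perturbs its
#' neighbours through shared metabolite pools, and the perturbation is
#' diluted in proportion to how many reactions drain the pool.
#'
#' @param net a \code{\linkS4class{MetabolicNetwork}}
#' @param ri,rj reaction ids
#' @return non-negative number, possibly \code{Inf}
#' @export
localDistance <- function(net, ri, rj) {
  stopifnot(is(net, "MetabolicNetwork"))
  ids <- reactionIds(net)
  if (!ri %in% ids) stop("unknown reaction: ", ri)
  if (!rj %in% ids) stop("unknown reaction: ", rj)
  if (ri == rj) return(0)
  shared <- metaboliteIds(net)[net@S[, ri] != 0 & net@S[, rj] != 0]
  if (!length(shared)) return(Inf)
  cc <- .consumerCounts(net)
  min(cc[shared])
}

#' Build the regulatory graph with all-pairs global distances
#'
#' Assembles the weighted reaction graph whose arc weights are the local
#' regulatory distances and computes all-pairs shortest paths (the global
#' regulatory distances). Exchange and link reactions are full nodes.
#' Infinite local distances are genuine absences of an arc, and pairs in
#' different components keep an infinite global distance.
#'
#' @param net a \code{\linkS4class{MetabolicNetwork}}
#' @return a \code{\linkS4class{RegulatoryGraph}}
#' @export
regulatoryGraph <- function(net) {
  stopifnot(is(net, "MetabolicNetwork"))
  ids <- reactionIds(net)
  n <- length(ids)
  cc <- .consumerCounts(net)
  S <- net@S
  loc <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(loc) <- 0
  nz <- S != 0
  for (m in seq_len(nrow(S))) {
    rs <- which(nz[m, ])
    if (length(rs) < 2) next
    w <- cc[m]
    for (a in seq_along(rs)) for (b in seq_along(rs)) if (a != b) {
      i <- rs[a]; j <- rs[b]
      if (w < loc[i, j]) loc[i, j] <- w
    }
  }
  g <- igraph::graph_from_adjacency_matrix(
    ifelse(is.infinite(loc), 0, loc), mode = "undirected",
    weighted = TRUE, diag = FALSE)
  # zero-weight arcs are legal (a shared pool nobody consumes)
  finite_pairs <- which(is.finite(loc) & loc == 0 & upper.tri(loc), arr.ind = TRUE)
  if (nrow(finite_pairs)) {
    extra <- t(finite_pairs)
    g <- igraph::add_edges(g, as.vector(extra), weight = 0)
  }
  D <- igraph::distances(g, algorithm = "dijkstra")
  D <- D[ids, ids]
  new("RegulatoryGraph", local = loc, global = D, consumerCounts = cc)
}

#' Regulatory distance between two EqSets
#'
#' The arithmetic mean of the global distances D(Ri, Rj) over all cross
#' pairs Ri in X1, Rj in X2.
#'
#' @param graph a \code{\linkS4class{RegulatoryGraph}}
#' @param x1,x2 non-empty character vectors of reaction ids
#' @return non-negative number, possibly \code{Inf}
#' @export
eqsetDistance <- function(graph, x1, x2) {
  stopifnot(is(graph, "RegulatoryGraph"), length(x1) >= 1, length(x2) >= 1)
  mean(graph@global[x1, x2])
}
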