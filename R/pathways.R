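#' @include AllClasses.R linalg-int.R
NULL

.INTERNAL_CAP <- 400

# split representation bookkeeping for a network: internal reversible
# reactions get a forward and a backward coordinate
.splitMap <- function(net, splitExchange = FALSE) {
  rxn <- net@reactions
  exch <- rxn$kind %in% c("primary-exchange", "currency-exchange")
  splittable <- rxn$reversible & (if (splitExchange) TRUE else !exch)
  n <- nrow(rxn)
  splitOf <- c(seq_len(n), which(splittable))
  dirn <- c(rep(1, n), rep(-1, sum(splittable)))
  rowIds <- c(rxn$id,
              if (any(splittable)) paste0(rxn$id[splittable], "_b") else character(0))
  # forward coordinates are sign-constrained unless the reaction stays signed
  signedKeep <- rxn$reversible & !splittable
  nonneg <- c(which(!signedKeep), n + seq_len(sum(splittable)))
  list(splitOf = splitOf, dirn = dirn, rowIds = rowIds, nonneg = nonneg,
       exch = exch, splittable = splittable)
}

.integerise <- function(S) {
  # scale columns with non-integer entries to integers (small rationals only)
  for (j in seq_len(ncol(S))) {
    col <- S[, j]
    if (max(abs(col - round(col))) > 1e-9) {
      for (d in 2:1000) {
        if (max(abs(col * d - round(col * d))) < 1e-9) { S[, j] <- round(col * d); break }
        if (d == 1000) stop("stoichiometric coefficients are not small rationals")
      }
    } else S[, j] <- round(col)
  }
  S
}

#' Enumerate the extreme pathways of a network
#'
#' Computes the complete set of extreme pathways: the extreme rays of the
#' steady-state flux cone \{v : S v = 0, v_i >= 0 for irreversible i\}
#' after splitting each internal reversible reaction into a forward and a
#' backward irreversible coordinate. Reversible exchange fluxes keep a
#' single signed coordinate, so conic combinations may cancel through the
#' system boundary; this makes extreme pathways a subset of the elementary
#' modes. Enumeration is by double description with exact integer
#' arithmetic; every output vector is scaled to smallest-integer form.
#'
#' The result contains the trivial forward/backward two-cycle of each
#' internal reversible reaction; these carry no exchange flux, are
#' classified type III by \code{\link{classifyPathways}} and are discarded
#' before any entropy analysis.
#'
#' @param net a \code{\linkS4class{MetabolicNetwork}}
#' @param maxInternal refuse networks with more internal reactions than
#'   this (extract a subsystem first); default 400.
#' @return a \code{\linkS4class{PathwayMatrix}} with basis
#'   \code{"extreme_pathway"}
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("R1: A -> B", "EX_A: -> A", "EX_B: B ->"), tf)
#' pm <- enumerateExtremePathways(readModel(tf))
#' nPathways(pm)
#' @export
enumerateExtremePathways <- function(net, maxInternal = .INTERNAL_CAP) {
  stopifnot(is(net, "MetabolicNetwork"))
  if (nReactions(net) < 1) stop("network has no reactions")
  nInt <- sum(net@reactions$kind %in% c("internal", "link"))
  if (nInt > maxInternal)
    stop(sprintf(paste("network has %d internal reactions (cap %d);",
                       "extract a target subsystem first"), nInt, maxInternal))
  S <- .integerise(net@S)
  map <- .splitMap(net, splitExchange = FALSE)
  Ssplit <- cbind(S, -S[, map$splittable, drop = FALSE])
  R <- .extremeRays(Ssplit, map$nonneg)
  pw <- t(R)
  rownames(pw) <- map$rowIds
  new("PathwayMatrix", pathways = pw, reactionIds = net@reactions$id[map$splitOf],
      pathwayType = rep(NA_character_, ncol(pw)), basis = "extreme_pathway")
}

#' Enumerate the elementary modes of a network
#'
#' Elementary modes are the support-minimal steady-state flux vectors
#' respecting irreversibility; they are computed as the extreme rays of the
#' fully split cone (every reversible reaction, exchange included, split
#' into two irreversible coordinates), with the spurious two-cycles of the
#' splitting removed and the pairs recombined. The extreme pathways of the
#' same network are a subset (up to the type III two-cycles, which are not
#' elementary in the unsplit network).
#'
#' @inheritParams enumerateExtremePathways
#' @return a \code{\linkS4class{PathwayMatrix}} with basis
#'   \code{"elementary_mode"}, in the same split-row representation as
#'   extreme pathways
#' @export
enumerateElementaryModes <- function(net, maxInternal = .INTERNAL_CAP) {
  stopifnot(is(net, "MetabolicNetwork"))
  nInt <- sum(net@reactions$kind %in% c("internal", "link"))
  if (nInt > maxInternal)
    stop(sprintf("network has %d internal reactions (cap %d)", nInt, maxInternal))
  S <- .integerise(net@S)
  map <- .splitMap(net, splitExchange = TRUE)
  Ssplit <- cbind(S, -S[, map$splittable, drop = FALSE])
  R <- .extremeRays(Ssplit, map$nonneg)
  n <- ncol(S)
  # drop two-cycles (fwd+bwd of one reaction), artifacts of the splitting
  twoCycle <- apply(R, 1, function(x) {
    s <- which(x != 0)
    length(s) == 2 && map$splitOf[s[1]] == map$splitOf[s[2]]
  })
  R <- R[!twoCycle, , drop = FALSE]
  # recombine to signed vectors over the original reactions
  V <- matrix(0, nrow(R), n)
  for (r in seq_len(nrow(R)))
    for (k in which(R[r, ] != 0))
      V[r, map$splitOf[k]] <- V[r, map$splitOf[k]] + map$dirn[k] * R[r, k]
  # canonical sign for fully reversible supports, then dedupe
  rev <- net@reactions$reversible
  for (r in seq_len(nrow(V))) {
    sup <- which(V[r, ] != 0)
    if (length(sup) && all(rev[sup]) && V[r, sup[1]] < 0) V[r, ] <- -V[r, ]
  }
  V <- V[!duplicated(apply(V, 1, paste, collapse = ",")), , drop = FALSE]
  V <- V[rowSums(V != 0) > 0, , drop = FALSE]
  # re-split internal reversible coordinates to match the EP representation
  mapEP <- .splitMap(net, splitExchange = FALSE)
  pw <- matrix(0, length(mapEP$splitOf), nrow(V))
  rownames(pw) <- mapEP$rowIds
  for (r in seq_len(nrow(V))) {
    for (k in seq_along(mapEP$splitOf)) {
      j <- mapEP$splitOf[k]
      x <- V[r, j]
      if (k <= n) {
        if (mapEP$splittable[j]) pw[k, r] <- max(x, 0)
        else pw[k, r] <- x
      } else pw[k, r] <- max(-x, 0)
    }
  }
  new("PathwayMatrix", pathways = pw,
      reactionIds = net@reactions$id[mapEP$splitOf],
      pathwayType = rep(NA_character_, ncol(pw)), basis = "elementary_mode")
}

#' Classify pathways into types I, II and III
#'
#' Type III pathways carry no exchange flux at all (purely internal cycles,
#' thermodynamically infeasible and discarded downstream). Type II
#' pathways touch the boundary only through currency (cofactor) exchanges.
#' Everything else is type I.
#'
#' @param pm a \code{\linkS4class{PathwayMatrix}}
#' @param net the network the pathways were enumerated from
#' @param currencyIds ids of the currency exchanges; defaults to the
#'   network's \code{"currency-exchange"} reactions
#' @return the PathwayMatrix with \code{pathwayType} filled in
#' @export
classifyPathways <- function(pm, net, currencyIds = NULL) {
  stopifnot(is(pm, "PathwayMatrix"), is(net, "MetabolicNetwork"))
  kinds <- reactionKind(net)
  if (is.null(currencyIds)) currencyIds <- names(kinds)[kinds == "currency-exchange"]
  exchIds <- names(kinds)[kinds %in% c("primary-exchange", "currency-exchange")]
  rid <- pm@reactionIds
  exRows <- rid %in% exchIds
  primRows <- rid %in% setdiff(exchIds, currencyIds)
  ty <- vapply(seq_len(ncol(pm@pathways)), function(j) {
    v <- pm@pathways[, j]
    if (all(v[exRows] == 0)) "III"
    else if (all(v[primRows] == 0)) "II"
    else "I"
  }, "")
  pm@pathwayType <- ty
  pm
}

#' Compact pathways: one signed element per network reaction
#'
#' Merges the forward/backward split pair of every internal reversible
#' reaction by subtracting the backward flux from the forward one. Since a
#' pathway never uses both members of a split pair (outside the discarded
#' type III two-cycles), compaction preserves each pathway's employed
#' reaction set. Type III pathways are dropped first.
#'
#' @param pm a classified \code{\linkS4class{PathwayMatrix}}
#' @param keepTypes pathway types retained; default I and II
#' @return a \code{\linkS4class{CompactPathwayMatrix}}
#' @export
compactPathways <- function(pm, keepTypes = c("I", "II")) {
  stopifnot(is(pm, "PathwayMatrix"))
  if (anyNA(pm@pathwayType))
    stop("classify pathways before compacting (classifyPathways)")
  sel <- pm@pathwayType %in% keepTypes
  if ("III" %in% keepTypes) stop("type III pathways cannot be compacted")
  P <- pm@pathways[, sel, drop = FALSE]
  rid <- pm@reactionIds
  ids <- unique(rid)
  fwd <- match(ids, rownames(P))
  out <- P[fwd, , drop = FALSE]
  rownames(out) <- ids
  splitIds <- unique(rid[duplicated(rid)])
  for (id in splitIds) {
    bwd <- which(rownames(P) == paste0(id, "_b"))
    both <- P[id, ] != 0 & P[bwd, ] != 0
    if (any(both))
      stop(sprintf("pathway uses both directions of '%s'; futile cycle not removed", id))
    out[id, ] <- P[id, ] - P[bwd, ]
  }
  new("CompactPathwayMatrix", pathways = out,
      sourceType = pm@pathwayType[sel], basis = pm@basis)
}

#' Generate artificial pathway sets by random superposition
#'
#' Each draw selects every source pathway independently with probability
#' \code{p} and sums the selected vectors; \code{t} draws are made,
#' all-zero draws are discarded and exact duplicates collapsed, so the
#' returned set holds the unique artificial pathways. Larger \code{p} and
#' \code{t} yield more and more complex pathways, which degrades the
#' entropy structure the ranking relies on.
#'
#' @param cpm a \code{\linkS4class{CompactPathwayMatrix}} of source pathways
#' @param p selection probability per pathway, in (0, 1]
#' @param t number of draws, >= 1
#' @param seed integer seed; fixes the output
#' @return a \code{\linkS4class{CompactPathwayMatrix}} with basis
#'   \code{"artificial"}
#' @export
generateArtificialPathways <- function(cpm, p, t, seed) {
  stopifnot(is(cpm, "CompactPathwayMatrix"), p > 0, p <= 1, t >= 1)
  l <- ncol(cpm@pathways)
  if (l < 1) stop("need at least one source pathway")
  rng <- .seededRNG(seed)
  draws <- matrix(0, nrow(cpm@pathways), 0)
  for (i in seq_len(t)) {
    sel <- rng$runif(l) < p
    if (!any(sel)) next
    draws <- cbind(draws, rowSums(cpm@pathways[, sel, drop = FALSE]))
  }
  if (ncol(draws)) {
    keep <- colSums(draws != 0) > 0
    draws <- draws[, keep, drop = FALSE]
    draws <- draws[, !duplicated(apply(draws, 2, paste, collapse = ",")), drop = FALSE]
  }
  rownames(draws) <- rownames(cpm@pathways)
  new("CompactPathwayMatrix", pathways = draws,
      sourceType = rep("I", ncol(draws)), basis = "artificial")
}

# local RNG that does not disturb the global .Random.seed
.seededRNG <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  use <- function(f) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    f(...)
  }
  list(runif = use(stats::runif), sample = use(base::sample),
       rpois = use(stats::rpois))
}
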