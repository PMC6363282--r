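#' @include AllClasses.R pathways.R infotheory.R regdistance.R eqsort.R evaluation.R
NULL

#' Run the full ranking pipeline on a network
#'
#' Enumerates extreme pathways (or elementary modes), classifies and
#' compacts them, builds the participation profile and regulatory graph,
#' groups reactions into EqSets, sorts the EqSets by regulatory importance
#' and, when a meaningful-reaction set is supplied, evaluates the
#' resulting sequence with its exact p-value.
#'
#' @param net a \code{\linkS4class{MetabolicNetwork}}
#' @param params an \code{\linkS4class{EqParams}}
#' @param meaningful optional character vector of regulated or
#'   disease-associated reaction ids
#' @param basis \code{"ep"} for extreme pathways, \code{"em"} for
#'   elementary modes
#' @param currencyIds optional override of the currency exchange ids
#' @return list with components \code{pathways}
#'   (\code{\linkS4class{PathwayMatrix}}), \code{compact},
#'   \code{profile}, \code{graph}, \code{eqsets}, \code{sequence}
#'   (\code{\linkS4class{RankedSequence}}) and, when \code{meaningful} is
#'   given, \code{score} and \code{pValue}
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("R1: A -> B", "R2: A -> B", "EX_A: -> A", "EX_B: B ->"), tf)
#' res <- runPipeline(readModel(tf), eqParams(mu = 0.1))
#' length(res$sequence@queue)
#' @export
runPipeline <- function(net, params = eqParams(), meaningful = NULL,
                        basis = c("ep", "em"), currencyIds = NULL) {
  basis <- match.arg(basis)
  pm <- if (basis == "ep") enumerateExtremePathways(net)
        else enumerateElementaryModes(net)
  pm <- classifyPathways(pm, net, currencyIds)
  cpm <- compactPathways(pm)
  if (ncol(cpm@pathways) == 0)
    stop("no type I/II pathways; nothing to rank")
  profile <- participationProfile(cpm)
  needGraph <- is.finite(params@rhoE) || is.finite(params@rhoS)
  graph <- if (needGraph) regulatoryGraph(net) else NULL
  sets <- buildEqSets(profile, net, graph, rhoE = params@rhoE)
  seq <- sortEqSets(sets, profile, graph, params)
  out <- list(pathways = pm, compact = cpm, profile = profile, graph = graph,
              eqsets = sets, sequence = seq)
  if (!is.null(meaningful)) {
    sc <- evaluationScore(seq, meaningful)
    nInt <- sum(!sets@isExchange)
    m <- sum(vapply(sets@members[!sets@isExchange], function(s)
      length(intersect(s, meaningful)) > 0, TRUE))
    out$score <- sc
    out$pValue <- if (m >= 1) pvalueExact(sc$sigma, nInt, m) else NA_real_
  }
  out
}

#' Sweep the size-bonus ratio and record score and p-value
#'
#' Re-runs the greedy sort for each value of mu (radii and window taken
#' from \code{params}) and tabulates the evaluation score and exact
#' p-value of the resulting sequence.
#'
#' @param net a \code{\linkS4class{MetabolicNetwork}}
#' @param meaningful character vector of meaningful reaction ids
#' @param muValues numeric vector of mu values
#' @param params template \code{\linkS4class{EqParams}} for the radii and
#'   window
#' @param basis \code{"ep"} or \code{"em"}
#' @return data.frame with columns \code{mu}, \code{sigma}, \code{pValue},
#'   \code{queueLength}
#' @export
sweepMu <- function(net, meaningful, muValues = seq(0, 1, by = 0.025),
                    params = eqParams(), basis = c("ep", "em")) {
  basis <- match.arg(basis)
  pm <- if (basis == "ep") enumerateExtremePathways(net)
        else enumerateElementaryModes(net)
  pm <- classifyPathways(pm, net)
  cpm <- compactPathways(pm)
  profile <- participationProfile(cpm)
  needGraph <- is.finite(params@rhoE) || is.finite(params@rhoS)
  graph <- if (needGraph) regulatoryGraph(net) else NULL
  sets <- buildEqSets(profile, net, graph, rhoE = params@rhoE)
  nInt <- sum(!sets@isExchange)
  m <- sum(vapply(sets@members[!sets@isExchange], function(s)
    length(intersect(s, meaningful)) > 0, TRUE))
  rows <- lapply(muValues, function(mu) {
    p <- eqParams(mu = mu, rhoE = params@rhoE, rhoS = params@rhoS,
                  tau = params@tau)
    sq <- sortEqSets(sets, profile, graph, p)
    sc <- evaluationScore(sq, meaningful)
    data.frame(mu = mu, sigma = sc$sigma,
               pValue = pvalueExact(sc$sigma, nInt, m),
               queueLength = sc$s)
  })
  do.call(rbind, rows)
}
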