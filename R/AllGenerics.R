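#' @include AllClasses.R
NULL

#' Number of reactions in a network
#' @param x a MetabolicNetwork
#' @return integer scalar
#' @export
setGeneric("nReactions", function(x) standardGeneric("nReactions"))

#' Number of metabolites in a network
#' @param x a MetabolicNetwork
#' @return integer scalar
#' @export
setGeneric("nMetabolites", function(x) standardGeneric("nMetabolites"))

#' Reaction identifiers, in model order
#' @param x a MetabolicNetwork, PathwayMatrix or related object
#' @return character vector
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' Metabolite identifiers, in model order
#' @param x a MetabolicNetwork
#' @return character vector
#' @export
setGeneric("metaboliteIds", function(x) standardGeneric("metaboliteIds"))

#' Stoichiometric matrix (metabolites x reactions)
#' @param x a MetabolicNetwork
#' @return numeric matrix
#' @export
setGeneric("stoichiometry", function(x) standardGeneric("stoichiometry"))

#' Reaction kind ("internal", "primary-exchange", "currency-exchange", "link")
#' @param x a MetabolicNetwork
#' @return named character vector
#' @export
setGeneric("reactionKind", function(x) standardGeneric("reactionKind"))

#' Logical: is each reaction reversible?
#' @param x a MetabolicNetwork
#' @return named logical vector
#' @export
setGeneric("isReversible", function(x) standardGeneric("isReversible"))

#' Logical: is each reaction an exchange (primary or currency) flux?
#' @param x a MetabolicNetwork
#' @return named logical vector
#' @export
setGeneric("isExchange", function(x) standardGeneric("isExchange"))

#' Pathway count
#' @param x a PathwayMatrix, CompactPathwayMatrix or ParticipationProfile
#' @return integer scalar
#' @export
setGeneric("nPathways", function(x) standardGeneric("nPathways"))

#' Pathway type (I, II or III) per pathway
#' @param x a PathwayMatrix or CompactPathwayMatrix
#' @return character vector
#' @export
setGeneric("pathwayType", function(x) standardGeneric("pathwayType"))

#' EqSet membership as a list of reaction-id vectors
#' @param x an EqSetList or RankedSequence
#' @return list of character vectors
#' @export
setGeneric("eqsetMembers", function(x) standardGeneric("eqsetMembers"))

## ---- accessors -------------------------------------------------------------

#' @describeIn nReactions reaction count of a network
#' @export
setMethod("nReactions", "MetabolicNetwork", function(x) nrow(x@reactions))

#' @describeIn nMetabolites metabolite count of a network
#' @export
setMethod("nMetabolites", "MetabolicNetwork", function(x) nrow(x@metabolites))

#' @describeIn reactionIds reaction ids of a network
#' @export
setMethod("reactionIds", "MetabolicNetwork", function(x) x@reactions$id)

#' @describeIn reactionIds unsplit reaction ids backing a pathway matrix
#' @export
setMethod("reactionIds", "PathwayMatrix", function(x) unique(x@reactionIds))

#' @describeIn reactionIds reaction ids of a compact pathway matrix
#' @export
setMethod("reactionIds", "CompactPathwayMatrix", function(x) rownames(x@pathways))

#' @describeIn reactionIds reaction ids of a participation profile
#' @export
setMethod("reactionIds", "ParticipationProfile", function(x) rownames(x@participation))

#' @describeIn reactionIds reaction ids of a regulatory graph
#' @export
setMethod("reactionIds", "RegulatoryGraph", function(x) rownames(x@local))

#' @describeIn metaboliteIds metabolite ids of a network
#' @export
setMethod("metaboliteIds", "MetabolicNetwork", function(x) x@metabolites$id)

#' @describeIn stoichiometry the S matrix of a network
#' @export
setMethod("stoichiometry", "MetabolicNetwork", function(x) x@S)

#' @describeIn reactionKind kinds of a network's reactions
#' @export
setMethod("reactionKind", "MetabolicNetwork",
  function(x) stats::setNames(x@reactions$kind, x@reactions$id))

#' @describeIn isReversible reversibility flags of a network's reactions
#' @export
setMethod("isReversible", "MetabolicNetwork",
  function(x) stats::setNames(x@reactions$reversible, x@reactions$id))

#' @describeIn isExchange exchange flags of a network's reactions
#' @export
setMethod("isExchange", "MetabolicNetwork",
  function(x) stats::setNames(
    x@reactions$kind %in% c("primary-exchange", "currency-exchange"),
    x@reactions$id))

#' @describeIn nPathways pathway count of a pathway matrix
#' @export
setMethod("nPathways", "PathwayMatrix", function(x) ncol(x@pathways))

#' @describeIn nPathways pathway count of a compact matrix
#' @export
setMethod("nPathways", "CompactPathwayMatrix", function(x) ncol(x@pathways))

#' @describeIn nPathways pathway count of a participation profile
#' @export
setMethod("nPathways", "ParticipationProfile", function(x) ncol(x@participation))

#' @describeIn pathwayType types of an enumerated pathway matrix
#' @export
setMethod("pathwayType", "PathwayMatrix", function(x) x@pathwayType)

#' @describeIn pathwayType source types of a compact matrix
#' @export
setMethod("pathwayType", "CompactPathwayMatrix", function(x) x@sourceType)

#' @describeIn eqsetMembers member list of an EqSetList
#' @export
setMethod("eqsetMembers", "EqSetList", function(x) x@members)

#' @describeIn eqsetMembers queued EqSets of a ranked sequence, in rank order
#' @export
setMethod("eqsetMembers", "RankedSequence", function(x) x@queue)

#' Participation matrix of a profile
#' @param x a ParticipationProfile
#' @return binary integer matrix, reactions x pathways
#' @export
participationMatrix <- function(x) {
  stopifnot(is(x, "ParticipationProfile"))
  x@participation
}

#' Compact pathway matrix as a plain matrix
#' @param x a CompactPathwayMatrix
#' @return numeric matrix, reactions x pathways
#' @export
compactMatrix <- function(x) {
  stopifnot(is(x, "CompactPathwayMatrix"))
  x@pathways
}

#' Global (shortest-path) regulatory distance matrix
#' @param x a RegulatoryGraph
#' @return numeric matrix, possibly containing Inf
#' @export
globalDistanceMatrix <- function(x) {
  stopifnot(is(x, "RegulatoryGraph"))
  x@global
}

#' Local regulatory distance matrix
#' @param x a RegulatoryGraph
#' @return numeric matrix, possibly containing Inf
#' @export
localDistanceMatrix <- function(x) {
  stopifnot(is(x, "RegulatoryGraph"))
  x@local
}

#' Lost (never-ranked) internal EqSets of a sequence
#' @param x a RankedSequence
#' @return list of character vectors
#' @export
lostEqSets <- function(x) {
  stopifnot(is(x, "RankedSequence"))
  x@lost
}

#' Per-step trace of the greedy sort
#' @param x a RankedSequence
#' @return data.frame with one row per greedy step
#' @export
sortTrace <- function(x) {
  stopifnot(is(x, "RankedSequence"))
  x@trace
}
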