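#' @import methods
NULL

#' MetabolicNetwork: a constraint-based metabolic model
#'
#' Container for a stoichiometric model: an ordered metabolite table, an
#' ordered reaction table and the stoichiometric matrix \code{S}
#' (metabolites x reactions). Reaction and metabolite order is the file
#' order of the source model and is preserved by every operation; all
#' downstream tie-breaking refers to it.
#'
#' Reaction \code{kind} is one of \code{"internal"}, \code{"primary-exchange"},
#' \code{"currency-exchange"} (cofactor loads and leaks, the basis of
#' type II pathway classification) or \code{"link"} (the M<->M' carriers
#' added when a subsystem is carved out of a larger model).
#'
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{isDuplicate}, \code{duplicateOf}.
#' @slot reactions data.frame with columns \code{id}, \code{name},
#'   \code{reversible}, \code{kind}, \code{subsystem}, \code{lowerBound},
#'   \code{upperBound}.
#' @slot S numeric matrix, metabolites x reactions, dimnames set to the ids.
#'
#' @exportClass MetabolicNetwork
setClass("MetabolicNetwork",
  representation(metabolites = "data.frame",
                 reactions = "data.frame",
                 S = "matrix"))

setValidity("MetabolicNetwork", function(object) {
  msg <- character(0)
  met <- object@metabolites; rxn <- object@reactions; S <- object@S
  need_m <- c("id", "name", "isDuplicate", "duplicateOf")
  need_r <- c("id", "name", "reversible", "kind", "subsystem",
              "lowerBound", "upperBound")
  if (!all(need_m %in% names(met))) msg <- c(msg, "metabolite table incomplete")
  if (!all(need_r %in% names(rxn))) msg <- c(msg, "reaction table incomplete")
  if (length(msg)) return(msg)
  if (anyDuplicated(met$id)) msg <- c(msg, "duplicated metabolite ids")
  if (anyDuplicated(rxn$id)) msg <- c(msg, "duplicated reaction ids")
  if (!identical(dim(S), c(nrow(met), nrow(rxn))))
    msg <- c(msg, "S dimensions do not match metabolite/reaction tables")
  else {
    if (!identical(rownames(S), met$id) || !identical(colnames(S), rxn$id))
      msg <- c(msg, "S dimnames do not match the id columns")
    if (any(colSums(S != 0) == 0))
      msg <- c(msg, "reaction with empty stoichiometry")
  }
  bad_kind <- setdiff(rxn$kind,
                      c("internal", "primary-exchange", "currency-exchange", "link"))
  if (length(bad_kind)) msg <- c(msg, paste("unknown reaction kind:", bad_kind[1]))
  if (any(!rxn$reversible & rxn$lowerBound < 0))
    msg <- c(msg, "irreversible reaction with negative lower bound")
  lk <- which(rxn$kind == "link")
  for (j in lk) {
    cj <- S[, j]
    if (sum(cj != 0) != 2 || !setequal(cj[cj != 0], c(-1, 1)))
      msg <- c(msg, sprintf("link reaction '%s' must be one substrate -1, one product +1", rxn$id[j]))
  }
  dup <- met$id[met$isDuplicate]
  for (d in dup) {
    orig <- met$duplicateOf[met$id == d]
    if (is.na(orig) || !orig %in% met$id)
      msg <- c(msg, sprintf("duplicate metabolite '%s' lacks a valid original", d))
  }
  if (length(msg)) msg else TRUE
})

#' PathwayMatrix: enumerated steady-state pathways
#'
#' Pathway vectors over the reversibility-split reaction list: internal
#' reversible reactions contribute a forward and a backward coordinate
#' (the backward one suffixed \code{"_b"}); exchange reactions keep a single
#' signed coordinate. Columns are pathways; rows are split-reaction
#' coordinates. \code{pathwayType} is \code{NA} until
#' \code{\link{classifyPathways}} assigns types I/II/III.
#'
#' @slot pathways numeric matrix, split reactions x pathways.
#' @slot reactionIds character, the unsplit reaction id per row.
#' @slot pathwayType character vector, one of "I","II","III" or NA per column.
#' @slot basis character scalar: "extreme_pathway", "elementary_mode" or
#'   "artificial".
#'
#' @exportClass PathwayMatrix
setClass("PathwayMatrix",
  representation(pathways = "matrix",
                 reactionIds = "character",
                 pathwayType = "character",
                 basis = "character"))

setValidity("PathwayMatrix", function(object) {
  msg <- character(0)
  if (length(object@reactionIds) != nrow(object@pathways))
    msg <- c(msg, "reactionIds length must equal row count")
  if (length(object@pathwayType) != ncol(object@pathways))
    msg <- c(msg, "pathwayType length must equal pathway count")
  if (!object@basis %in% c("extreme_pathway", "elementary_mode", "artificial"))
    msg <- c(msg, "unknown basis")
  bad <- setdiff(stats::na.omit(object@pathwayType), c("I", "II", "III"))
  if (length(bad)) msg <- c(msg, "pathwayType values must be I, II or III")
  if (length(msg)) msg else TRUE
})

#' CompactPathwayMatrix: pathways with one signed element per reaction
#'
#' Forward/backward pairs of each internal reversible reaction are merged
#' by subtracting the backward from the forward flux, so every pathway has
#' exactly one element per network reaction. Merging never changes the set
#' of reactions a pathway employs. Type III (purely internal) pathways are
#' excluded before compaction.
#'
#' @slot pathways numeric matrix, reactions x pathways; rownames are
#'   reaction ids.
#' @slot sourceType character, "I" or "II" per pathway.
#' @slot basis character scalar, as in \code{\linkS4class{PathwayMatrix}}.
#'
#' @exportClass CompactPathwayMatrix
setClass("CompactPathwayMatrix",
  representation(pathways = "matrix",
                 sourceType = "character",
                 basis = "character"))

setValidity("CompactPathwayMatrix", function(object) {
  msg <- character(0)
  if (is.null(rownames(object@pathways)))
    msg <- c(msg, "pathways must have reaction ids as rownames")
  if (length(object@sourceType) != ncol(object@pathways))
    msg <- c(msg, "sourceType length must equal pathway count")
  if (any(object@sourceType == "III"))
    msg <- c(msg, "type III pathways may not enter a compact matrix")
  if (length(msg)) msg else TRUE
})

#' ParticipationProfile: binary reaction-employment matrix
#'
#' Entry (i, j) is 1 when reaction i carries nonzero flux in compact
#' pathway j. Under the uniform-pathway model, one pathway is drawn
#' uniformly from the l columns and each reaction's on/off state is its
#' employment indicator; all entropies are computed from this joint
#' distribution by exact pattern counting.
#'
#' @slot participation integer 0/1 matrix, reactions x pathways, rownames
#'   are reaction ids.
#'
#' @exportClass ParticipationProfile
setClass("ParticipationProfile",
  representation(participation = "matrix"))

setValidity("ParticipationProfile", function(object) {
  m <- object@participation
  msg <- character(0)
  if (ncol(m) < 1) msg <- c(msg, "profile needs at least one pathway")
  if (is.null(rownames(m))) msg <- c(msg, "rownames (reaction ids) required")
  if (!all(m %in% c(0L, 1L))) msg <- c(msg, "participation must be binary")
  if (length(msg)) msg else TRUE
})

#' RegulatoryGraph: local and global regulatory distances
#'
#' Nodes are reactions; the weight of the arc between two reactions is the
#' local regulatory distance (0 on the diagonal, infinite when the two
#' reactions share no metabolite, otherwise the smallest consumer count
#' C(M) over shared metabolites M). Global distances are shortest-path
#' lengths over this weighted graph.
#'
#' @slot local numeric matrix of local distances (may contain Inf).
#' @slot global numeric matrix of shortest-path distances (may contain Inf).
#' @slot consumerCounts named numeric, C(M) per metabolite.
#'
#' @exportClass RegulatoryGraph
setClass("RegulatoryGraph",
  representation(local = "matrix",
                 global = "matrix",
                 consumerCounts = "numeric"))

setValidity("RegulatoryGraph", function(object) {
  msg <- character(0)
  if (!identical(dim(object@local), dim(object@global)))
    msg <- c(msg, "local and global matrices must agree in dimension")
  if (any(diag(object@local) != 0)) msg <- c(msg, "self-distance must be 0")
  if (!isTRUE(all.equal(object@local, t(object@local))))
    msg <- c(msg, "local distances must be symmetric")
  if (any(object@global > object@local + 1e-9))
    msg <- c(msg, "global distance exceeds local distance")
  if (length(msg)) msg else TRUE
})

#' EqSetList: equivalent reaction sets on Shannon entropy
#'
#' A partition of the reactions into EqSets: every exchange reaction is a
#' singleton set; internal reactions are grouped when each pair has zero
#' conditional entropy in both directions and every member has a
#' counterpart within the intra-set radius rho_e.
#'
#' @slot members list of character vectors (reaction ids per set).
#' @slot isExchange logical, per set.
#'
#' @exportClass EqSetList
setClass("EqSetList",
  representation(members = "list",
                 isExchange = "logical"))

setValidity("EqSetList", function(object) {
  msg <- character(0)
  if (length(object@members) != length(object@isExchange))
    msg <- c(msg, "members and isExchange must have equal length")
  if (any(lengths(object@members) == 0)) msg <- c(msg, "empty EqSet")
  if (any(object@isExchange & lengths(object@members) != 1))
    msg <- c(msg, "exchange EqSets must be singletons")
  ids <- unlist(object@members)
  if (anyDuplicated(ids)) msg <- c(msg, "EqSets must be disjoint")
  if (length(msg)) msg else TRUE
})

#' EqParams: tuning parameters of the greedy EqSet sort
#'
#' \code{mu} is the size-bonus ratio (the importance of a k-member EqSet is
#' scaled by 1 + mu (k - 1)); \code{rhoE} the intra-EqSet effective radius;
#' \code{rhoS} the inter-EqSet effective radius bounding which EqSets count
#' as neighbours or competitors; \code{tau} the sliding-window size on the
#' queue. All radii and the window may be infinite, which removes the
#' corresponding locality constraint.
#'
#' @slot mu numeric scalar >= 0.
#' @slot rhoE numeric scalar > 0 (possibly Inf).
#' @slot rhoS numeric scalar > 0 (possibly Inf), rhoE <= rhoS.
#' @slot tau numeric scalar >= 1 (possibly Inf).
#'
#' @exportClass EqParams
setClass("EqParams",
  representation(mu = "numeric", rhoE = "numeric",
                 rhoS = "numeric", tau = "numeric"))

setValidity("EqParams", function(object) {
  msg <- character(0)
  if (object@mu < 0) msg <- c(msg, "mu must be >= 0")
  if (object@rhoE <= 0) msg <- c(msg, "rhoE must be > 0")
  if (object@rhoS <= 0) msg <- c(msg, "rhoS must be > 0")
  if (object@rhoE > object@rhoS) msg <- c(msg, "rhoE must not exceed rhoS")
  if (object@tau < 1) msg <- c(msg, "tau must be >= 1")
  if (length(msg)) msg else TRUE
})

#' RankedSequence: output of the greedy regulatory-importance sort
#'
#' \code{queue} holds the internal EqSets in rank order (1-based positions
#' after exchange EqSets are removed); \code{lost} the internal EqSets whose
#' regulatory importance was zero at termination; \code{trace} one row per
#' greedy step (including steps that picked an exchange EqSet), with the
#' chosen members, its importance value and the neighbour/competitor set
#' sizes.
#'
#' @slot queue list of character vectors.
#' @slot lost list of character vectors.
#' @slot trace data.frame with columns \code{step}, \code{members},
#'   \code{val}, \code{nNeighbors}, \code{nCompetitors}, \code{isExchange}.
#' @slot params the \code{\linkS4class{EqParams}} used.
#'
#' @exportClass RankedSequence
setClass("RankedSequence",
  representation(queue = "list",
                 lost = "list",
                 trace = "data.frame",
                 params = "EqParams"))

setValidity("RankedSequence", function(object) {
  msg <- character(0)
  qids <- unlist(object@queue); lids <- unlist(object@lost)
  if (length(intersect(qids, lids)))
    msg <- c(msg, "queued and lost EqSets overlap")
  if (length(msg)) msg else TRUE
})
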