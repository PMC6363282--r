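#' @include AllClasses.R
NULL

setMethod("show", "MetabolicNetwork", function(object) {
  rxn <- object@reactions
  cat("MetabolicNetwork:", nrow(object@metabolites), "metabolites,",
      nrow(rxn), "reactions\n")
  cat("  internal:", sum(rxn$kind == "internal"),
      " exchange:", sum(rxn$kind %in% c("primary-exchange", "currency-exchange")),
      "(", sum(rxn$kind == "currency-exchange"), "currency )",
      " link:", sum(rxn$kind == "link"), "\n")
  cat("  reversible:", sum(rxn$reversible), "\n")
  subs <- setdiff(unique(rxn$subsystem), "")
  if (length(subs))
    cat("  subsystems:", paste(utils::head(subs, 5), collapse = ", "),
        if (length(subs) > 5) "..." else "", "\n")
})

setMethod("show", "PathwayMatrix", function(object) {
  cat("PathwayMatrix (", object@basis, "): ", ncol(object@pathways),
      " pathways over ", nrow(object@pathways), " split reactions\n", sep = "")
  ty <- object@pathwayType
  if (!anyNA(ty))
    cat("  type I:", sum(ty == "I"), " II:", sum(ty == "II"),
        " III:", sum(ty == "III"), "\n")
  else cat("  unclassified (run classifyPathways)\n")
})

setMethod("show", "CompactPathwayMatrix", function(object) {
  cat("CompactPathwayMatrix (", object@basis, "): ", ncol(object@pathways),
      " pathways x ", nrow(object@pathways), " reactions\n", sep = "")
})

setMethod("show", "ParticipationProfile", function(object) {
  m <- object@participation
  cat("ParticipationProfile:", nrow(m), "reactions x", ncol(m), "pathways\n")
  cat("  mean employment:", round(mean(rowMeans(m)), 3), "\n")
})

setMethod("show", "RegulatoryGraph", function(object) {
  D <- object@global
  cat("RegulatoryGraph:", nrow(D), "reactions\n")
  fin <- D[upper.tri(D)]
  cat("  finite pairs:", sum(is.finite(fin)), "/", length(fin), "\n")
})

setMethod("show", "EqSetList", function(object) {
  int <- !object@isExchange
  cat("EqSetList:", sum(int), "internal EqSets (",
      sum(int & lengths(object@members) > 1), "with >1 member ),",
      sum(!int), "exchange singletons\n")
})

setMethod("show", "EqParams", function(object) {
  cat(sprintf("EqParams: mu=%g rhoE=%g rhoS=%g tau=%g\n",
              object@mu, object@rhoE, object@rhoS, object@tau))
})

setMethod("show", "RankedSequence", function(object) {
  cat("RankedSequence:", length(object@queue), "ranked internal EqSets,",
      length(object@lost), "lost\n")
  for (i in seq_along(object@queue))
    cat(sprintf("  %2d. %s\n", i, paste(object@queue[[i]], collapse = ", ")))
})
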