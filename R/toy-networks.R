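#' @include AllClasses.R model-io.R
NULL

#' Generate a random connected toy network
#'
#' Builds a small mass-balanced random network for testing and
#' simulation: a random spanning chain of internal conversions guarantees
#' that every metabolite takes part in at least one reaction, additional
#' internal reactions (some reversible) connect random metabolite pairs,
#' and the requested number of exchange reactions is attached to distinct
#' random metabolites. Structure is fully reproducible for a given seed.
#'
#' @param nMetabolites,nInternal,nExchange counts, all >= 1
#' @param seed integer seed
#' @param pReversible probability that an internal reaction is reversible
#' @return a \code{\linkS4class{MetabolicNetwork}}
#' @examples
#' net <- randomToyNetwork(4, 3, 2, seed = 1)
#' nReactions(net)
#' @export
randomToyNetwork <- function(nMetabolites, nInternal, nExchange, seed,
                             pReversible = 0.3) {
  stopifnot(nMetabolites >= 1, nInternal >= 1, nExchange >= 1)
  if (nExchange > nMetabolites)
    stop("cannot attach more exchange reactions than metabolites")
  if (nInternal < nMetabolites - 1 && nMetabolites > 1)
    warning("fewer internal reactions than needed to chain all metabolites; ",
            "connectivity is enforced by reusing metabolites")
  rng <- .seededRNG(seed)
  mets <- sprintf("M%02d", seq_len(nMetabolites))
  lines <- character(0)
  # chain step i -> i+1 ensures every metabolite appears somewhere
  ord <- if (nMetabolites > 1) rng$sample(nMetabolites, nMetabolites) else 1
  for (i in seq_len(nInternal)) {
    if (i < nMetabolites) {
      a <- mets[ord[i]]; b <- mets[ord[i + 1]]
    } else {
      pick <- rng$sample(nMetabolites, 2)
      a <- mets[pick[1]]; b <- mets[pick[2]]
    }
    arrow <- if (rng$runif(1) < pReversible) "<->" else "->"
    lines <- c(lines, sprintf("R%02d: %s %s %s", i, a, arrow, b))
  }
  exMets <- mets[rng$sample(nMetabolites, nExchange)]
  # alternate uptake and secretion so the network can carry flux
  for (k in seq_along(exMets)) {
    lines <- c(lines, if (k %% 2 == 1)
      sprintf("EX_%s: -> %s", exMets[k], exMets[k])
      else sprintf("EX_%s: %s ->", exMets[k], exMets[k]))
  }
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  readModel(tmp, format = "tsv")
}
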