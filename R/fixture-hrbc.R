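#' @include AllClasses.R model-io.R
NULL

#' The human red blood cell metabolic network
#'
#' Loads the packaged reconstruction of human erythrocyte metabolism: 39
#' metabolites and 51 reactions (19 of them exchange fluxes) covering
#' glycolysis, the Rapoport-Luebering shunt, the pentose phosphate
#' pathway and adenine nucleotide salvage, together with the physiological
#' load fluxes (ATP consumption by ion pumps, NADH oxidation by
#' methaemoglobin reduction, NADPH oxidation by the glutathione system,
#' 2,3-DPG sequestration by haemoglobin). The reconstruction follows the
#' classic erythrocyte models used for extreme pathway analysis; the
#' fixture file records per-reaction provenance notes.
#'
#' Also returned are the ten reactions documented in the literature as
#' allosterically regulated (the meaningful set for sequence evaluation)
#' and the currency-exchange ids whose pathways constitute type II.
#'
#' @return list with \code{network} (a
#'   \code{\linkS4class{MetabolicNetwork}}), \code{regulated} (character),
#'   \code{currency} (character)
#' @examples
#' fx <- hrbcFixture()
#' nReactions(fx$network)   # 51
#' length(fx$regulated)     # 10
#' @export
hrbcFixture <- function() {
  dir <- system.file("extdata", package = "epareg", mustWork = TRUE)
  currency <- readLines(file.path(dir, "hrbc_currency.txt"))
  currency <- currency[nchar(trimws(currency)) > 0 & !startsWith(currency, "#")]
  exchange <- readLines(file.path(dir, "hrbc_exchange.txt"))
  exchange <- exchange[nchar(trimws(exchange)) > 0 & !startsWith(exchange, "#")]
  regulated <- readLines(file.path(dir, "hrbc_regulated.txt"))
  regulated <- regulated[nchar(trimws(regulated)) > 0 & !startsWith(regulated, "#")]
  net <- readModel(file.path(dir, "hrbc_model.tsv"), format = "tsv",
                   exchangeIds = exchange, currencyIds = currency)
  list(network = net, regulated = regulated, currency = currency)
}
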