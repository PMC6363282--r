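#' @include AllClasses.R
NULL

.DEFAULT_UB <- 1000

# parse one reaction line of the TSV dialect:
#   "id: 2 A + B -> C | subsystem"   ("<->" marks a reversible reaction;
#   an empty side marks an exchange). "#" starts a comment.
.parseReactionLine <- function(line, lineno) {
  line <- sub("#.*$", "", line)
  line <- trimws(line)
  if (!nchar(line)) return(NULL)
  colon <- regexpr(":", line, fixed = TRUE)
  if (colon < 0)
    stop(sprintf("line %d: expected 'id: lhs -> rhs'", lineno))
  id <- trimws(substr(line, 1, colon - 1))
  rest <- trimws(substr(line, colon + 1, nchar(line)))
  subsystem <- ""
  bar <- regexpr("|", rest, fixed = TRUE)
  if (bar > 0) {
    subsystem <- trimws(substr(rest, bar + 1, nchar(rest)))
    rest <- trimws(substr(rest, 1, bar - 1))
  }
  reversible <- grepl("<->", rest, fixed = TRUE)
  sides <- strsplit(rest, if (reversible) "<->" else "->", fixed = TRUE)[[1]]
  if (length(sides) == 1) sides <- c(sides, "")
  if (length(sides) != 2 || !grepl("->", rest, fixed = TRUE))
    stop(sprintf("line %d ('%s'): missing '->' or '<->'", lineno, id))
  parseSide <- function(s, sgn) {
    s <- trimws(s)
    if (!nchar(s)) return(stats::setNames(numeric(0), character(0)))
    out <- numeric(0)
    for (term in trimws(strsplit(s, "+", fixed = TRUE)[[1]])) {
      m <- regmatches(term, regexec("^([0-9]*\\.?[0-9]+)\\s+(\\S.*)$", term))[[1]]
      if (length(m)) { cf <- as.numeric(m[2]); met <- m[3] } else { cf <- 1; met <- term }
      if (!nchar(met)) stop(sprintf("line %d ('%s'): empty metabolite", lineno, id))
      out[met] <- (if (met %in% names(out)) out[[met]] else 0) + sgn * cf
    }
    out
  }
  lhs <- parseSide(sides[1], -1)
  rhs <- parseSide(sides[2], +1)
  st <- lhs
  for (m in names(rhs)) st[m] <- (if (m %in% names(st)) st[[m]] else 0) + rhs[[m]]
  st <- st[st != 0]
  if (!length(st))
    stop(sprintf("line %d ('%s'): reaction has no stoichiometry", lineno, id))
  list(id = id, name = id, stoich = st, reversible = reversible,
       subsystem = subsystem)
}

# assemble a MetabolicNetwork from a list of parsed reactions
.makeNetwork <- function(rxns, exchangeIds = NULL, currencyIds = character(0),
                         metNames = NULL) {
  ids <- vapply(rxns, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicated reaction id: ", ids[duplicated(ids)][1])
  mets <- unique(unlist(lapply(rxns, function(r) names(r$stoich))))
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, ids))
  for (j in seq_along(rxns)) S[names(rxns[[j]]$stoich), j] <- rxns[[j]]$stoich
  onesided <- vapply(rxns, function(r) all(r$stoich > 0) || all(r$stoich < 0), TRUE)
  exch <- if (is.null(exchangeIds)) onesided else ids %in% exchangeIds
  kind <- ifelse(exch, ifelse(ids %in% currencyIds, "currency-exchange",
                              "primary-exchange"), "internal")
  kind[ids %in% currencyIds] <- "currency-exchange"
  rev <- vapply(rxns, `[[`, TRUE, "reversible")
  lb <- vapply(rxns, function(r) {
    b <- r$lowerBound
    if (is.null(b)) (if (r$reversible) -.DEFAULT_UB else 0) else b
  }, 0)
  ub <- vapply(rxns, function(r) {
    b <- r$upperBound
    if (is.null(b)) .DEFAULT_UB else b
  }, 0)
  nm <- if (is.null(metNames)) stats::setNames(mets, mets) else metNames
  new("MetabolicNetwork",
      metabolites = data.frame(id = mets, name = unname(nm[mets]),
                               isDuplicate = FALSE, duplicateOf = NA_character_,
                               stringsAsFactors = FALSE),
      reactions = data.frame(id = ids,
                             name = vapply(rxns, `[[`, "", "name"),
                             reversible = rev, kind = kind,
                             subsystem = vapply(rxns, `[[`, "", "subsystem"),
                             lowerBound = lb, upperBound = ub,
                             stringsAsFactors = FALSE),
      S = S)
}

.readModelTsv <- function(path, exchangeIds, currencyIds) {
  lines <- readLines(path)
  rxns <- list()
  for (i in seq_along(lines)) {
    r <- .parseReactionLine(lines[i], i)
    if (!is.null(r)) rxns[[length(rxns) + 1L]] <- r
  }
  if (!length(rxns)) stop("no reactions found in ", path)
  .makeNetwork(rxns, exchangeIds, currencyIds)
}

.readModelJson <- function(path, exchangeIds, currencyIds) {
  mod <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(mod$reactions)) stop("not a BiGG-style model: no 'reactions' element")
  metNames <- character(0)
  for (m in mod$metabolites)
    metNames[m$id] <- if (!is.null(m$name)) m$name else m$id
  rxns <- lapply(mod$reactions, function(r) {
    st <- unlist(r$metabolites)
    if (is.null(st) || !length(st))
      stop(sprintf("reaction '%s' has no stoichiometry", r$id))
    lb <- if (!is.null(r$lower_bound)) r$lower_bound else NULL
    ub <- if (!is.null(r$upper_bound)) r$upper_bound else NULL
    list(id = r$id, name = if (!is.null(r$name)) r$name else r$id,
         stoich = st,
         reversible = if (!is.null(lb)) lb < 0 else TRUE,
         subsystem = if (!is.null(r$subsystem)) r$subsystem else "",
         lowerBound = lb, upperBound = ub)
  })
  .makeNetwork(rxns, exchangeIds, currencyIds, metNames = metNames)
}

.readModelSbml <- function(path, exchangeIds, currencyIds) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  metNames <- stats::setNames(
    xml2::xml_attr(sp, "name"), xml2::xml_attr(sp, "id"))
  metNames[is.na(metNames)] <- names(metNames)[is.na(metNames)]
  rnodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (!length(rnodes)) stop("no reactions in SBML file ", path)
  rxns <- lapply(rnodes, function(nd) {
    id <- xml2::xml_attr(nd, "id")
    refs <- function(xp, sgn) {
      srefs <- xml2::xml_find_all(nd, xp)
      if (!length(srefs)) return(numeric(0))
      st <- as.numeric(xml2::xml_attr(srefs, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(sgn * st, xml2::xml_attr(srefs, "species"))
    }
    lhs <- refs("./listOfReactants/speciesReference", -1)
    rhs <- refs("./listOfProducts/speciesReference", +1)
    st <- lhs
    for (m in names(rhs)) st[m] <- (if (m %in% names(st)) st[[m]] else 0) + rhs[[m]]
    st <- st[st != 0]
    if (!length(st)) stop(sprintf("reaction '%s' has no stoichiometry", id))
    list(id = id, name = xml2::xml_attr(nd, "name"),
         stoich = st,
         reversible = !identical(xml2::xml_attr(nd, "reversible"), "false"),
         subsystem = "")
  })
  for (i in seq_along(rxns)) if (is.na(rxns[[i]]$name)) rxns[[i]]$name <- rxns[[i]]$id
  .makeNetwork(rxns, exchangeIds, currencyIds, metNames = metNames)
}

#' Read a constraint-based metabolic model
#'
#' Reads a model from the package's TSV dialect, a BiGG-style JSON file or
#' an SBML file, and returns a validated
#' \code{\linkS4class{MetabolicNetwork}}. Exchange reactions are
#' auto-detected as those with metabolites on only one side of the
#' equation; the \code{exchangeIds} override names them explicitly instead
#' (needed for load reactions such as cofactor dissipation, which have
#' metabolites on both sides but cross the system boundary).
#'
#' The TSV dialect has one reaction per line,
#' \code{"id: 2 A + B -> C | subsystem"}, with \code{"<->"} for reversible
#' reactions, an empty side for exchanges and \code{"#"} comments.
#'
#' @param path file path.
#' @param format one of \code{"tsv"}, \code{"json"}, \code{"sbml"}; the
#'   default guesses from the file extension.
#' @param exchangeIds optional character vector naming the exchange
#'   reactions, overriding auto-detection.
#' @param currencyIds optional character vector naming the currency
#'   (cofactor) exchange reactions among the exchanges.
#' @return a \code{\linkS4class{MetabolicNetwork}}
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("R1: A -> B", "EX_A: -> A", "EX_B: B ->"), tf)
#' net <- readModel(tf)
#' nReactions(net)
#' @export
readModel <- function(path, format = c("auto", "tsv", "json", "sbml"),
                      exchangeIds = NULL, currencyIds = character(0)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, json = "json", xml = "sbml", sbml = "sbml", "tsv")
  }
  net <- switch(format,
    tsv = .readModelTsv(path, exchangeIds, currencyIds),
    json = .readModelJson(path, exchangeIds, currencyIds),
    sbml = .readModelSbml(path, exchangeIds, currencyIds))
  validObject(net)
  net
}

#' Write a network in the TSV dialect
#'
#' The written file reproduces the stoichiometric matrix exactly on
#' re-reading (\code{readModel} round trip).
#'
#' @param net a MetabolicNetwork
#' @param path output file path
#' @return invisibly, the path
#' @export
writeModelTsv <- function(net, path) {
  stopifnot(is(net, "MetabolicNetwork"))
  S <- net@S
  fmtSide <- function(v) {
    if (!length(v)) return("")
    paste(vapply(names(v), function(m)
      if (v[[m]] == 1) m else paste(format(v[[m]], scientific = FALSE), m), ""),
      collapse = " + ")
  }
  lines <- vapply(seq_len(ncol(S)), function(j) {
    cj <- S[, j]
    lhs <- -cj[cj < 0]; rhs <- cj[cj > 0]
    arrow <- if (net@reactions$reversible[j]) "<->" else "->"
    sub <- net@reactions$subsystem[j]
    eq <- trimws(paste(fmtSide(lhs), arrow, fmtSide(rhs)))
    if (nchar(sub)) paste0(net@reactions$id[j], ": ", eq, " | ", sub)
    else paste0(net@reactions$id[j], ": ", eq)
  }, "")
  writeLines(lines, path)
  invisible(path)
}
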