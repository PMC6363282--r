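#' @include AllClasses.R model-io.R
NULL

.FVA_ZERO <- 1e-6

#' Partition a network's internal reactions by subsystem label
#'
#' The target subsystem holds the internal reactions whose subsystem label
#' is in \code{labels}; the surrounding subsystem is the complement.
#' Shared metabolites are those appearing in the stoichiometry of both
#' sides.
#'
#' @param net a \code{\linkS4class{MetabolicNetwork}}
#' @param labels non-empty character vector of subsystem labels
#' @return list with \code{targetIds}, \code{surroundingIds},
#'   \code{sharedMetabolites}
#' @export
partitionBySubsystem <- function(net, labels) {
  stopifnot(is(net, "MetabolicNetwork"), length(labels) >= 1)
  rxn <- net@reactions
  known <- unique(rxn$subsystem[rxn$kind == "internal"])
  unknown <- setdiff(labels, known)
  if (length(unknown))
    stop("unknown subsystem label(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(sort(known), collapse = ", "))
  internal <- rxn$kind == "internal"
  target <- rxn$id[internal & rxn$subsystem %in% labels]
  surrounding <- rxn$id[internal & !rxn$subsystem %in% labels]
  metsOf <- function(ids) {
    if (!length(ids)) return(character(0))
    metaboliteIds(net)[rowSums(net@S[, ids, drop = FALSE] != 0) > 0]
  }
  shared <- intersect(metsOf(target), metsOf(surrounding))
  list(targetIds = target, surroundingIds = surrounding,
       sharedMetabolites = shared)
}

#' Add duplicate metabolites and link reactions for a partition
#'
#' For each shared metabolite M, occurrences in the surrounding subsystem
#' are rewritten to a duplicate M', and a reversible link reaction M <-> M'
#' is appended. The link flux equals the net exchange of M between the two
#' subsystems, and because each link has a single substrate and a single
#' product, the reachable steady-state flux space of the original
#' reactions is unchanged.
#'
#' @param net a \code{\linkS4class{MetabolicNetwork}}
#' @param part a partition from \code{\link{partitionBySubsystem}}
#' @return the augmented \code{\linkS4class{MetabolicNetwork}}
#' @export
augmentWithLinks <- function(net, part) {
  stopifnot(is(net, "MetabolicNetwork"))
  shared <- part$sharedMetabolites
  if (!length(shared)) return(net)
  S <- net@S
  met <- net@metabolites
  rxn <- net@reactions
  for (m in shared) {
    dup <- paste0(m, "'")
    newRow <- matrix(0, 1, ncol(S), dimnames = list(dup, NULL))
    surr <- part$surroundingIds
    newRow[1, match(surr, colnames(S))] <- S[m, surr]
    S[m, surr] <- 0
    S <- rbind(S, newRow)
    met <- rbind(met, data.frame(id = dup, name = paste0(met$name[met$id == m], " (surrounding copy)"),
                                 isDuplicate = TRUE, duplicateOf = m,
                                 stringsAsFactors = FALSE))
    linkId <- paste0("LINK_", m)
    newCol <- matrix(0, nrow(S), 1, dimnames = list(rownames(S), linkId))
    newCol[m, 1] <- -1
    newCol[dup, 1] <- 1
    S <- cbind(S, newCol)
    rxn <- rbind(rxn, data.frame(id = linkId, name = linkId, reversible = TRUE,
                                 kind = "link", subsystem = "",
                                 lowerBound = -.DEFAULT_UB, upperBound = .DEFAULT_UB,
                                 stringsAsFactors = FALSE))
  }
  out <- new("MetabolicNetwork", metabolites = met, reactions = rxn, S = S)
  validObject(out)
  out
}

# one LP: optimise flux j over {v : S v = 0, lb <= v <= ub}
.fvaLP <- function(S, lb, ub, j, maximise) {
  # shift v = x + lb so x >= 0; S x = -S lb; 0 <= x <= ub - lb
  n <- ncol(S)
  # drop linearly dependent balance rows (the system is consistent; the
  # redundancy only produces degenerate bases)
  qrS <- qr(t(S))
  S <- S[qrS$pivot[seq_len(qrS$rank)], , drop = FALSE]
  cc <- numeric(n); cc[j] <- if (maximise) 1 else -1
  r <- .lpSolve(cc, S, as.vector(-S %*% lb), ub - lb)
  if (!identical(r$status, "optimal")) stop("flux variability LP infeasible")
  (if (maximise) r$value else -r$value) + lb[j]
}

#' Flux variability analysis
#'
#' Computes the minimum and maximum steady-state flux of each requested
#' reaction over \{v : S v = 0, bounds respected\}, as two linear programs
#' per reaction. Unbounded directions are clamped by the default +-1000
#' bounds (a bound hit is reported via the \code{clamped} column; the
#' downstream constraint logic only needs the signs).
#'
#' @param net a \code{\linkS4class{MetabolicNetwork}}
#' @param reactions reaction ids to analyse; defaults to all
#' @return data.frame with columns \code{reaction}, \code{min}, \code{max},
#'   \code{clamped}
#' @export
fluxVariability <- function(net, reactions = reactionIds(net)) {
  stopifnot(is(net, "MetabolicNetwork"))
  miss <- setdiff(reactions, reactionIds(net))
  if (length(miss)) stop("unknown reaction: ", miss[1])
  S <- net@S
  lb <- net@reactions$lowerBound
  ub <- net@reactions$upperBound
  res <- lapply(reactions, function(id) {
    j <- match(id, reactionIds(net))
    lo <- .fvaLP(S, lb, ub, j, maximise = FALSE)
    hi <- .fvaLP(S, lb, ub, j, maximise = TRUE)
    clamped <- (abs(lo - lb[j]) < .FVA_ZERO && lb[j] == -.DEFAULT_UB) ||
               (abs(hi - ub[j]) < .FVA_ZERO && ub[j] == .DEFAULT_UB)
    data.frame(reaction = id, min = lo, max = hi, clamped = clamped,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (any(out$clamped))
    warning("flux range clamped at default bounds for: ",
            paste(out$reaction[out$clamped], collapse = ", "))
  out
}

#' Build the constrained target network of a subsystem
#'
#' Extracts the target internal reactions and adds one exchange reaction
#' per shared metabolite, with its direction fixed by the flux variability
#' range of the corresponding link reaction: both signs possible gives an
#' unconstrained reversible exchange; only positive gives an out-only
#' exchange (forward = taking M away from the target); only negative
#' gives an in-only exchange; a zero range adds no exchange. The primary
#' exchange reactions of the original model whose metabolites appear in
#' the target are retained.
#'
#' @param net the original \code{\linkS4class{MetabolicNetwork}}
#' @param part a partition from \code{\link{partitionBySubsystem}}
#' @return list with \code{network} (the target
#'   \code{\linkS4class{MetabolicNetwork}}) and \code{cases} (data.frame
#'   reporting the constraint case per shared metabolite)
#' @export
assignExchangeConstraints <- function(net, part) {
  aug <- augmentWithLinks(net, part)
  shared <- part$sharedMetabolites
  cases <- data.frame(metabolite = character(0), min = numeric(0),
                      max = numeric(0), case = character(0),
                      stringsAsFactors = FALSE)
  lines <- character(0)
  S <- net@S
  # target internal reactions, written in the TSV dialect
  tsv <- utils::capture.output(invisible(NULL))
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  sub <- net
  keep <- part$targetIds
  exch <- character(0)
  for (m in shared) {
    linkId <- paste0("LINK_", m)
    fv <- fluxVariability(aug, linkId)
    lo <- fv$min; hi <- fv$max
    zlo <- abs(lo) <= .FVA_ZERO; zhi <- abs(hi) <= .FVA_ZERO
    cs <- if (!zlo && lo < 0 && !zhi && hi > 0) "unconstrained"
          else if (zlo && hi > 0) "out"
          else if (lo < 0 && zhi) "in"
          else "none"
    cases <- rbind(cases, data.frame(metabolite = m, min = lo, max = hi,
                                     case = cs, stringsAsFactors = FALSE))
    ex <- switch(cs,
      unconstrained = sprintf("EXT_%s: %s <->", m, m),
      out = sprintf("EXT_%s: %s ->", m, m),
      `in` = sprintf("EXT_%s: -> %s", m, m),
      none = NULL)
    if (!is.null(ex)) exch <- c(exch, ex)
  }
  # retained primary exchanges of the original model acting on target metabolites
  tmets <- metaboliteIds(net)[rowSums(S[, keep, drop = FALSE] != 0) > 0]
  oldExch <- net@reactions$id[isExchange(net) &
    vapply(net@reactions$id, function(j) {
      nz <- metaboliteIds(net)[S[, j] != 0]
      all(nz %in% tmets) && length(nz) > 0
    }, TRUE)]
  keepAll <- c(keep, oldExch)
  subS <- S[, keepAll, drop = FALSE]
  subS <- subS[rowSums(subS != 0) > 0, , drop = FALSE]
  rxn <- net@reactions[match(keepAll, net@reactions$id), ]
  fmt <- function(j) {
    cj <- subS[, j]
    side <- function(v) paste(vapply(names(v), function(mm)
      if (v[[mm]] == 1) mm else paste(format(v[[mm]], scientific = FALSE), mm), ""),
      collapse = " + ")
    arrow <- if (rxn$reversible[j]) "<->" else "->"
    paste0(rxn$id[j], ": ", trimws(paste(side(-cj[cj < 0]), arrow, side(cj[cj > 0]))))
  }
  lines <- c(vapply(seq_len(ncol(subS)), fmt, ""), exch)
  writeLines(lines, tmp)
  target <- readModel(tmp, format = "tsv",
                      currencyIds = net@reactions$id[net@reactions$kind == "currency-exchange"])
  # carry subsystem labels over
  idx <- match(target@reactions$id, rxn$id)
  target@reactions$subsystem[!is.na(idx)] <- rxn$subsystem[idx[!is.na(idx)]]
  list(network = target, cases = cases)
}
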