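#' @include AllClasses.R
NULL

.EMPLOY_TOL <- 1e-9
.ENTROPY_TOL <- 1e-12

#' Build the binary participation profile of a compact pathway matrix
#'
#' A reaction is employed by a pathway when its compact flux element is
#' nonzero (in either direction). Under the assumption that each pathway
#' is utilised with equal probability, a reaction is "on" with probability
#' equal to its employment fraction, and joint on/off distributions over
#' reaction sets are obtained by counting pathway columns per configuration.
#'
#' @param cpm a \code{\linkS4class{CompactPathwayMatrix}}
#' @return a \code{\linkS4class{ParticipationProfile}}
#' @export
participationProfile <- function(cpm) {
  stopifnot(is(cpm, "CompactPathwayMatrix"))
  if (ncol(cpm@pathways) < 1) stop("need at least one pathway")
  m <- (abs(cpm@pathways) > .EMPLOY_TOL) * 1L
  new("ParticipationProfile", participation = m)
}

# joint on/off configuration counts for a set of reactions; exact integer
# counts over the l pathway columns, never floating accumulation. Columns
# are grouped by an integer encoding of their on/off pattern (compacted
# periodically so the codes stay exact in doubles).
.patternCounts <- function(profile, ids) {
  m <- profile@participation
  missing <- setdiff(ids, rownames(m))
  if (length(missing)) stop("unknown reaction id: ", missing[1])
  sub <- m[ids, , drop = FALSE]
  g <- rep(1, ncol(sub))
  for (i in seq_len(nrow(sub))) {
    g <- g + g + sub[i, ]
    if (i %% 40L == 0L) g <- match(g, unique(g))
  }
  tabulate(match(g, unique(g)))
}

#' Shannon entropy of a reaction set's joint on/off state
#'
#' One pathway is drawn uniformly from the l pathways of the profile; each
#' reaction's state is its employment indicator in that pathway. The
#' entropy (base 2, bits) of the resulting joint configuration
#' distribution is returned. For a single reaction this is the binary
#' entropy of its participation fraction.
#'
#' @param profile a \code{\linkS4class{ParticipationProfile}}
#' @param ids non-empty character vector of reaction ids
#' @return entropy in bits
#' @examples
#' m <- matrix(c(1L,1L,0L,0L, 1L,0L,1L,0L), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("a","b"), NULL))
#' pr <- new("ParticipationProfile", participation = m)
#' reactionEntropy(pr, "a")        # employed by half the pathways: 1 bit
#' reactionEntropy(pr, c("a","b")) # independent halves: 2 bits
#' @export
reactionEntropy <- function(profile, ids) {
  stopifnot(is(profile, "ParticipationProfile"), length(ids) >= 1)
  cnt <- .patternCounts(profile, ids)
  l <- ncol(profile@participation)
  p <- cnt[cnt > 0] / l
  -sum(p * log2(p))
}

#' Conditional entropy H(X1 | X2) between reaction sets
#'
#' Computed as H(X1 union X2) - H(X2) from exact configuration counts.
#' With an empty conditioning set this reduces to
#' \code{\link{reactionEntropy}}. Always non-negative (up to numerical
#' tolerance, which is clamped).
#'
#' @param profile a \code{\linkS4class{ParticipationProfile}}
#' @param x1 non-empty character vector of reaction ids
#' @param x2 character vector of conditioning reaction ids (may be empty)
#' @return conditional entropy in bits
#' @export
conditionalEntropy <- function(profile, x1, x2 = character(0)) {
  stopifnot(length(x1) >= 1)
  if (!length(x2)) return(reactionEntropy(profile, x1))
  h <- reactionEntropy(profile, union(x1, x2)) - reactionEntropy(profile, x2)
  max(h, 0)
}

#' Are two reactions an equivalent couple on Shannon entropy?
#'
#' True when H(Ri | Rj) and H(Rj | Ri) are both zero (within tolerance),
#' i.e. each reaction's on/off state determines the other's. Under the
#' literal definition this holds for identical employment patterns, for
#' complementary patterns, and for pairs of constant reactions; the
#' \code{equivalence = "identical_support"} switch restricts it to
#' identical patterns.
#'
#' @param profile a \code{\linkS4class{ParticipationProfile}}
#' @param ri,rj reaction ids
#' @param equivalence \code{"literal"} (mutual zero conditional entropy) or
#'   \code{"identical_support"}
#' @return logical
#' @export
equivalentCouple <- function(profile, ri, rj,
                             equivalence = c("literal", "identical_support")) {
  equivalence <- match.arg(equivalence)
  m <- profile@participation
  if (equivalence == "identical_support")
    return(all(m[ri, ] == m[rj, ]))
  conditionalEntropy(profile, ri, rj) <= .ENTROPY_TOL &&
    conditionalEntropy(profile, rj, ri) <= .ENTROPY_TOL
}

#' Pairwise conditional-entropy matrix
#'
#' Entry (i, j) is H(Ri | Rj). The zero blocks on the diagonal of this
#' matrix (after grouping) are the EqSets; exporting it as TSV reproduces
#' the conditional-entropy heat map of the worked example.
#'
#' @param profile a \code{\linkS4class{ParticipationProfile}}
#' @param ids reactions to include; defaults to all
#' @return numeric matrix
#' @export
conditionalEntropyMatrix <- function(profile, ids = reactionIds(profile)) {
  n <- length(ids)
  H1 <- vapply(ids, function(i) reactionEntropy(profile, i), 0)
  out <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    out[i, j] <- max(reactionEntropy(profile, c(ids[i], ids[j])) - H1[j], 0)
  out
}
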