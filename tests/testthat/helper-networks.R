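# In-code network builders shared across tests.

netFromLines <- function(lines, ...) {
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  readModel(tf, format = "tsv", ...)
}

# EX_A -> A -> B -> EX_B
chainNet <- function() {
  netFromLines(c("R1: A -> B", "EX_A: -> A", "EX_B: B ->"))
}

# two parallel internal routes between the same boundary metabolites
parallelNet <- function() {
  netFromLines(c("R1: A -> B", "R2: A -> B", "EX_A: -> A", "EX_B: B ->"))
}

# branched toy with three fates for B
branchedNet <- function() {
  netFromLines(c(
    "R1: A -> B",
    "R2: B -> C",
    "R3: B -> D",
    "EX_A: -> A",
    "EX_C: C ->",
    "EX_D: D ->"))
}

# toy with a reversible internal reaction and a currency-style load
loadedNet <- function() {
  netFromLines(c(
    "R1: A + ATP -> B + ADP",
    "R2: B <-> C",
    "R3: C + ADP -> D + ATP",
    "LOAD: ATP -> ADP",
    "EX_A: -> A",
    "EX_D: D ->"),
    exchangeIds = c("EX_A", "EX_D", "LOAD"),
    currencyIds = "LOAD")
}

# brute-force elementary modes for small networks: enumerate supports,
# keep sign-feasible one-dimensional kernels that are support-minimal
bruteForceModes <- function(net) {
  S <- stoichiometry(net)
  rev <- isReversible(net)
  n <- ncol(S)
  found <- list()
  for (size in 1:n) {
    for (sup in utils::combn(n, size, simplify = FALSE)) {
      K <- S[, sup, drop = FALSE]
      ns <- MASS::Null(t(K))
      if (!is.matrix(ns) || ncol(ns) != 1) next
      v <- as.vector(ns)
      if (any(abs(v) < 1e-8)) next      # support not exact
      if (any(!rev[sup] & v < 0)) {
        if (any(!rev[sup] & v > 0)) next
        v <- -v
        if (any(!rev[sup] & v < 0)) next
      }
      full <- numeric(n); full[sup] <- v
      # support-minimality against previously found
      found[[length(found) + 1L]] <- full
    }
  }
  # keep support-minimal vectors only, dedupe up to scaling/sign
  supports <- lapply(found, function(v) which(v != 0))
  keep <- vapply(seq_along(found), function(i) {
    !any(vapply(seq_along(found), function(j) {
      i != j && all(supports[[j]] %in% supports[[i]]) &&
        length(supports[[j]]) < length(supports[[i]])
    }, TRUE))
  }, TRUE)
  found <- found[keep]
  sig <- vapply(found, function(v) {
    v <- v / max(abs(v))
    if (v[which(v != 0)[1]] < 0) v <- -v
    paste(round(v, 6), collapse = ",")
  }, "")
  found[!duplicated(sig)]
}

# signed compact vectors of a classified PathwayMatrix, over the original
# reaction list (for comparison with brute-force modes)
compactVectors <- function(pm, keepTypes = c("I", "II", "III")) {
  sel <- pm@pathwayType %in% keepTypes
  P <- pm@pathways[, sel, drop = FALSE]
  rid <- pm@reactionIds
  ids <- unique(rid)
  out <- matrix(0, length(ids), ncol(P), dimnames = list(ids, NULL))
  for (k in seq_len(nrow(P)))
    out[rid[k], ] <- out[rid[k], ] +
      (if (grepl("_b$", rownames(P)[k]) && rownames(P)[k] != rid[k]) -1 else 1) * P[k, ]
  out
}
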