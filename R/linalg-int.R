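# Exact integer linear algebra for flux-cone enumeration.
# All inputs are integer-valued doubles; every intermediate row is reduced
# by its gcd so entries stay far below 2^53.

.gcd2 <- function(a, b) {
  while (b) { t <- a %% b; a <- b; b <- t }
  a
}

.igcd <- function(v) {
  v <- abs(v[v != 0])
  if (!length(v)) return(1)
  g <- v[1]
  for (x in v[-1]) {
    g <- .gcd2(g, x)
    if (g == 1) break
  }
  g
}

.reduce <- function(x) x / .igcd(x)

# integer kernel basis (rows) of an integer matrix, by fraction-free
# Gauss-Jordan elimination
.kernelInt <- function(S) {
  A <- S; m <- nrow(A); n <- ncol(A)
  pivcol <- integer(0); r <- 0
  for (j in seq_len(n)) {
    if (r == m) break
    prow <- which(A[(r + 1):m, j] != 0)
    if (!length(prow)) next
    prow <- prow[1] + r
    if (prow != r + 1) A[c(r + 1, prow), ] <- A[c(prow, r + 1), ]
    r <- r + 1; pivcol <- c(pivcol, j)
    p <- A[r, j]
    for (i in seq_len(m)) if (i != r && A[i, j] != 0) {
      A[i, ] <- p * A[i, ] - A[i, j] * A[r, ]
      g <- .igcd(A[i, ]); if (g > 1) A[i, ] <- A[i, ] / g
    }
  }
  free <- setdiff(seq_len(n), pivcol)
  if (!length(free)) return(matrix(0, 0, n))
  K <- matrix(0, length(free), n)
  piv <- vapply(seq_along(pivcol), function(i) A[i, pivcol[i]], 0)
  M <- abs(Reduce(function(a, b) a * b / .gcd2(abs(a), abs(b)), piv))
  for (k in seq_along(free)) {
    f <- free[k]
    v <- numeric(n); v[f] <- M
    for (i in seq_along(pivcol)) if (A[i, f] != 0)
      v[pivcol[i]] <- -A[i, f] * M / A[i, pivcol[i]]
    if (max(abs(v - round(v))) > 1e-6)
      stop("integer kernel computation lost exactness")
    K[k, ] <- .reduce(round(v))
  }
  K
}

# Extreme rays of {v : S v = 0, v_i >= 0 for i in nonneg}, coordinates not in
# `nonneg` are free (signed). Double description: the kernel basis is the
# initial lineality space, consumed one sign constraint at a time; once the
# cone is pointed, classic DD steps with the combinatorial adjacency test.
# Returns rays as rows, in smallest-integer form.
.extremeRays <- function(S, nonneg) {
  n <- ncol(S)
  L <- .kernelInt(S)
  R <- matrix(0, 0, n)
  remaining <- nonneg
  processed <- integer(0)
  while (length(remaining)) {
    i <- NA_integer_
    if (nrow(L)) {
      hit <- remaining[colSums(L[, remaining, drop = FALSE] != 0) > 0]
      if (length(hit)) i <- hit[1]
      else stop("flux cone has a lineality space; give the exchange fluxes a direction")
    }
    if (!is.na(i)) {
      k <- which(L[, i] != 0)[1]
      l0 <- L[k, ]; if (l0[i] < 0) l0 <- -l0
      L <- L[-k, , drop = FALSE]
      if (nrow(L))
        L <- t(apply(L, 1, function(l) if (l[i] == 0) l else .reduce(l0[i] * l - l[i] * l0)))
      if (nrow(R))
        R <- t(apply(R, 1, function(rr) if (rr[i] == 0) rr else .reduce(l0[i] * rr - rr[i] * l0)))
      R <- rbind(R, l0)
    } else {
      W <- R[, remaining, drop = FALSE]
      np <- colSums(W > 0); nn <- colSums(W < 0)
      i <- remaining[which.min(np * nn + np + nn)]
      w <- R[, i]
      keep <- R[w >= 0, , drop = FALSE]
      pos <- which(w > 0); neg <- which(w < 0)
      newr <- list()
      if (length(pos) && length(neg)) {
        # zero patterns over the processed sign constraints, packed into
        # 30-bit words so the combinatorial adjacency test is a handful of
        # vectorised bit operations per candidate pair
        nr <- nrow(R)
        npr <- length(processed)
        nw <- max(1L, ceiling(npr / 30))
        Zb <- matrix(0L, nr, nw)
        if (npr) {
          Z <- R[, processed, drop = FALSE] == 0
          for (k in seq_len(npr)) {
            wd <- (k - 1L) %/% 30L + 1L
            bit <- bitwShiftL(1L, (k - 1L) %% 30L)
            Zb[Z[, k], wd] <- bitwOr(Zb[Z[, k], wd], bit)
          }
        }
        for (a in pos) for (b in neg) {
          m <- bitwAnd(Zb[a, ], Zb[b, ])
          ok <- TRUE
          if (nr > 2) {
            if (any(m != 0)) {
              cov <- rep(TRUE, nr)
              for (wd in seq_len(nw)) if (m[wd] != 0)
                cov <- cov & (bitwAnd(Zb[, wd], m[wd]) == m[wd])
              cov[c(a, b)] <- FALSE
              if (any(cov)) ok <- FALSE
            } else ok <- FALSE
          }
          if (ok) newr[[length(newr) + 1L]] <- .reduce((-w[b]) * R[a, ] + w[a] * R[b, ])
        }
      }
      R <- rbind(keep, do.call(rbind, c(list(matrix(0, 0, n)), newr)))
    }
    processed <- c(processed, i)
    remaining <- setdiff(remaining, i)
  }
  R
}
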