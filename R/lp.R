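# Dense two-phase primal simplex with Bland's rule.
# Solves: max c'x  subject to  A x = b, 0 <= x <= u.
# Written for the moderate problem sizes of flux variability analysis;
# Bland's rule guarantees termination on the degenerate bases these
# steady-state systems produce.

.lpSolve <- function(cc, A, b, u, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  # flip rows so b >= 0
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  # variables: x (n), slack s for x + s = u (n), artificial a (m)
  # rows: m equality rows, then n bound rows
  nv <- 2L * n + m
  Tmat <- matrix(0, m + n, nv + 1L)
  Tmat[seq_len(m), seq_len(n)] <- A
  Tmat[seq_len(m), 2L * n + seq_len(m)] <- diag(m)
  Tmat[m + seq_len(n), seq_len(n)] <- diag(n)
  Tmat[m + seq_len(n), n + seq_len(n)] <- diag(n)
  Tmat[, nv + 1L] <- c(b, u)
  basis <- c(2L * n + seq_len(m), n + seq_len(n))
  runSimplex <- function(obj, allowed) {
    # obj: length nv cost vector (maximise); reduced costs computed fresh
    repeat {
      cb <- obj[basis]
      # reduced costs: z_j = obj_j - cb' B^-1 A_j; tableau is kept in
      # B^-1-applied form, so reduced cost is direct
      red <- obj - as.vector(crossprod(Tmat[, seq_len(nv), drop = FALSE], cb))
      cand <- which(red > tol & allowed)
      cand <- setdiff(cand, basis)
      if (!length(cand)) return(TRUE)
      j <- min(cand)                      # Bland: smallest index enters
      col <- Tmat[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(NA)        # unbounded (cannot happen boxed)
      ratio <- Tmat[pos, nv + 1L] / col[pos]
      rmin <- min(ratio)
      rows <- pos[ratio <= rmin + tol]
      r <- rows[which.min(basis[rows])]   # Bland: smallest basic index leaves
      piv <- Tmat[r, j]
      Tmat[r, ] <<- Tmat[r, ] / piv
      for (i in seq_len(nrow(Tmat))) if (i != r && abs(Tmat[i, j]) > 0) {
        Tmat[i, ] <<- Tmat[i, ] - Tmat[i, j] * Tmat[r, ]
      }
      basis[r] <<- j
    }
  }
  # phase 1: drive artificials to zero
  obj1 <- c(rep(0, 2L * n), rep(-1, m))
  runSimplex(obj1, allowed = rep(TRUE, nv))
  art <- which(basis > 2L * n)
  if (length(art) && sum(Tmat[art, nv + 1L]) > 1e-7)
    return(list(status = "infeasible"))
  # pivot degenerate artificials out of the basis so phase-2 moves cannot
  # lift them above zero; a row with no usable pivot is redundant
  dropRows <- integer(0)
  for (r in which(basis > 2L * n)) {
    j <- which(abs(Tmat[r, seq_len(2L * n)]) > tol)
    j <- setdiff(j, basis)
    if (length(j)) {
      j <- j[1]
      piv <- Tmat[r, j]
      Tmat[r, ] <- Tmat[r, ] / piv
      for (i in seq_len(nrow(Tmat))) if (i != r && abs(Tmat[i, j]) > 0)
        Tmat[i, ] <- Tmat[i, ] - Tmat[i, j] * Tmat[r, ]
      basis[r] <- j
    } else dropRows <- c(dropRows, r)
  }
  if (length(dropRows)) {
    Tmat <- Tmat[-dropRows, , drop = FALSE]
    basis <- basis[-dropRows]
  }
  # phase 2: maximise cc over x, artificials barred from re-entering
  obj2 <- c(cc, rep(0, n), rep(0, m))
  allowed <- c(rep(TRUE, 2L * n), rep(FALSE, m))
  runSimplex(obj2, allowed = allowed)
  x <- numeric(n)
  inb <- which(basis <= n)
  x[basis[inb]] <- Tmat[inb, nv + 1L]
  list(status = "optimal", x = x, value = sum(cc * x))
}
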