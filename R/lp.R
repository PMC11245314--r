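# Dense two-phase simplex for small linear programs over free variables:
#
#     maximize / minimize  obj' x   subject to  A x <= b,  x free.
#
# Free variables are split (x = u - v, u, v >= 0), slack variables make the
# system an equality standard form, and phase-1 artificials establish an
# initial basis. Bland's rule is used throughout, so the method terminates
# without cycling. Status is reported explicitly ("optimal", "infeasible",
# "unbounded"); problem sizes here are tiny (tens of rows/columns), so a
# dense tableau is the robust choice.

lp_solve <- function(obj, A, b, maximize = FALSE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m)
  cost <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  # scale rows so tolerances are comparable across constraints
  rs <- pmax(apply(abs(A), 1, max), abs(b), 1)
  A <- A / rs
  b <- b / rs

  # standard form: [A, -A, I] z = b, z >= 0; flip rows with negative b
  M <- cbind(A, -A, diag(m))
  d <- b
  neg <- d < 0
  if (any(neg)) {
    M[neg, ] <- -M[neg, , drop = FALSE]
    d[neg] <- -d[neg]
  }
  n_struct <- 2L * n
  n_total <- n_struct + m

  # phase 1: artificial basis (one artificial per row)
  Tb <- cbind(M, diag(m), d)
  basis <- n_total + seq_len(m)
  p1 <- simplex_iterate(Tb, basis, cost = c(rep(0, n_total), rep(1, m)),
                        ncols = n_total + m, tol = tol)
  if (p1$status == "unbounded") {
    cw_stop("phase-1 LP unbounded: numerical failure", "cw_numeric_error")
  }
  if (p1$objective > 1e-7) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  Tb <- p1$tableau
  basis <- p1$basis
  # drive remaining artificials out of the basis
  for (i in seq_len(m)) {
    if (basis[i] > n_total) {
      piv <- which(abs(Tb[i, seq_len(n_total)]) > tol)
      if (length(piv) == 0L) next # redundant all-zero row; dropped below
      j <- piv[1L]
      Tb <- pivot_tableau(Tb, i, j)
      basis[i] <- j
    }
  }
  # drop redundant rows still pinned to an artificial, then phase 2 on
  # structural + slack columns only
  live <- basis <= n_total
  keep <- c(seq_len(n_total), ncol(Tb))
  Tb2 <- Tb[live, keep, drop = FALSE]
  basis <- basis[live]
  p2 <- simplex_iterate(Tb2, basis, cost = cost_full(cost, n, m),
                        ncols = n_total, tol = tol)
  if (p2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, objective = NA_real_))
  }
  basis <- p2$basis
  Tb2 <- p2$tableau
  z <- numeric(n_total)
  rhs <- Tb2[, ncol(Tb2)]
  ok <- basis <= n_total
  z[basis[ok]] <- rhs[ok]
  x <- z[seq_len(n)] - z[n + seq_len(n)]
  objv <- sum(obj * x)
  list(status = "optimal", x = x, objective = objv)
}

cost_full <- function(cost, n, m) {
  c(cost, -cost, rep(0, m))
}

# One simplex run on tableau Tb (rows = constraints, last col = rhs),
# minimizing cost over columns 1..ncols with Bland's rule.
simplex_iterate <- function(Tb, basis, cost, ncols, tol = 1e-9) {
  # reduced-cost row
  cr <- c(cost, 0)[seq_len(ncol(Tb))]
  cr <- cr - as.numeric(cost[basis] %*% Tb)
  repeat {
    enter <- 0L
    for (j in seq_len(ncols)) {
      if (cr[j] < -tol) { enter <- j; break } # Bland: smallest index
    }
    if (enter == 0L) break
    col <- Tb[, enter]
    rhs <- Tb[, ncol(Tb)]
    cand <- which(col > tol)
    if (length(cand) == 0L) {
      return(list(status = "unbounded", tableau = Tb, basis = basis,
                  objective = NA_real_))
    }
    ratios <- rhs[cand] / col[cand]
    rmin <- min(ratios)
    tied <- cand[ratios <= rmin + tol]
    leave <- tied[which.min(basis[tied])] # Bland tie-break
    # update reduced costs then pivot
    cr <- cr - (cr[enter] / Tb[leave, enter]) * Tb[leave, ]
    Tb <- pivot_tableau(Tb, leave, enter)
    basis[leave] <- enter
  }
  objective <- sum(cost[basis] * Tb[, ncol(Tb)])
  list(status = "optimal", tableau = Tb, basis = basis, objective = objective)
}

pivot_tableau <- function(Tb, pr, pc) {
  pivval <- Tb[pr, pc]
  Tb[pr, ] <- Tb[pr, ] / pivval
  other <- setdiff(seq_len(nrow(Tb)), pr)
  if (length(other)) {
    Tb[other, ] <- Tb[other, , drop = FALSE] -
      outer(Tb[other, pc], Tb[pr, ])
  }
  Tb[, pc] <- 0
  Tb[pr, pc] <- 1
  Tb
}
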