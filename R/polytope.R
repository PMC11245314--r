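#' Construct a convex polytope in half-space representation
#'
#' A polytope is the solution set \eqn{P = \{\theta \in R^n : A\theta \le b\}}
#' of a finite system of linear inequalities. Rows of `A` index constraints,
#' columns index dimensions.
#'
#' @param A numeric matrix (constraints x dimensions); all entries finite.
#' @param b numeric vector of right-hand sides, one per row of `A`.
#' @param label optional character label carried through preprocessing.
#' @return An object of class `"polytope"` with elements `A`, `b`, `label`.
#' @examples
#' P <- polytope(rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)), c(1, 0, 1, 0))
#' contains(P, c(0.5, 0.5))
#' @export
polytope <- function(A, b, label = NULL) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  b <- as.numeric(b)
  if (nrow(A) < 1L || ncol(A) < 1L) {
    cw_stop("polytope needs at least one constraint and one dimension",
            "cw_validation_error")
  }
  cw_check_dim(nrow(A) == length(b),
               sprintf("A has %d rows but b has %d entries", nrow(A), length(b)))
  if (!all(is.finite(A)) || !all(is.finite(b))) {
    cw_stop("polytope entries must all be finite", "cw_validation_error")
  }
  zero_rows <- rowSums(abs(A)) == 0
  if (any(zero_rows & b < 0)) {
    cw_stop("all-zero constraint row with negative bound: trivially infeasible",
            "cw_validation_error")
  }
  structure(list(A = A, b = b, label = label), class = "polytope")
}

#' @export
print.polytope <- function(x, ...) {
  cat(sprintf("<polytope%s: %d constraints in %d dimensions>\n",
              if (!is.null(x$label)) paste0(" '", x$label, "'") else "",
              nrow(x$A), ncol(x$A)))
  invisible(x)
}

#' Number of dimensions of a polytope
#' @param P a [polytope()].
#' @return integer dimension `n`.
#' @export
polytope_dim <- function(P) ncol(P$A)

#' Linear equality system S x = c
#'
#' Represents equality constraints to be eliminated by [embed_equalities()],
#' e.g. the steady-state condition of a stoichiometric matrix or the row and
#' column sums of doubly stochastic matrices.
#'
#' @param S numeric matrix (equalities x dimensions).
#' @param c numeric right-hand-side vector.
#' @return An object of class `"equality_system"`.
#' @export
equality_system <- function(S, c) {
  S <- as.matrix(S)
  storage.mode(S) <- "double"
  c <- as.numeric(c)
  cw_check_dim(nrow(S) == length(c),
               sprintf("S has %d rows but c has %d entries", nrow(S), length(c)))
  if (!all(is.finite(S)) || !all(is.finite(c))) {
    cw_stop("equality system entries must all be finite", "cw_validation_error")
  }
  structure(list(S = S, c = c), class = "equality_system")
}

#' Test whether a point lies inside a polytope
#'
#' @param P a [polytope()].
#' @param point numeric vector of length `polytope_dim(P)`.
#' @param tol nonnegative slack allowed on each inequality.
#' @return `TRUE` iff `A point <= b + tol` elementwise.
#' @export
contains <- function(P, point, tol = 0) {
  cw_check_dim(length(point) == ncol(P$A),
               sprintf("point has length %d but polytope dimension is %d",
                       length(point), ncol(P$A)))
  if (tol < 0) cw_stop("tol must be nonnegative", "cw_validation_error")
  all(P$A %*% point - P$b <= tol)
}

# strict interior test with relative margin (used for chord/sampler starts)
strictly_interior <- function(P, point, margin = 1e-12) {
  slack <- P$b - as.numeric(P$A %*% point)
  all(slack >= margin * (1 + abs(P$b)))
}

#' Feasible segment of a line through a polytope
#'
#' For a strictly interior `origin` and a nonzero `direction` d, returns the
#' maximal interval \eqn{[\lambda_{min}, \lambda_{max}]} with
#' \eqn{\lambda_{min} < 0 < \lambda_{max}} such that
#' `origin + lambda * d` satisfies all inequalities. Constraint rows
#' orthogonal to the direction impose no bound. This chord is the basic
#' geometric primitive of every Hit-and-Run proposal.
#'
#' @param P a [polytope()].
#' @param origin strictly interior point.
#' @param direction nonzero direction vector.
#' @return named numeric vector `c(lambda_min, lambda_max)`.
#' @export
chord_bounds <- function(P, origin, direction) {
  cw_check_dim(length(origin) == ncol(P$A) && length(direction) == ncol(P$A),
               "origin/direction length must equal polytope dimension")
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0) {
    cw_stop("direction must be nonzero", "cw_validation_error")
  }
  if (!strictly_interior(P, origin)) {
    cw_stop("chord origin is not strictly interior", "cw_feasibility_error")
  }
  ad <- as.numeric(P$A %*% direction)
  slack <- P$b - as.numeric(P$A %*% origin)
  pos <- ad > 0
  neg <- ad < 0
  if (!any(pos)) {
    cw_stop(paste0("chord unbounded above along direction (",
                   paste(signif(direction, 4), collapse = ", "), ")"),
            "cw_unbounded_error")
  }
  if (!any(neg)) {
    cw_stop(paste0("chord unbounded below along direction (",
                   paste(signif(direction, 4), collapse = ", "), ")"),
            "cw_unbounded_error")
  }
  lambda_max <- min(slack[pos] / ad[pos])
  lambda_min <- max(slack[neg] / ad[neg])
  c(lambda_min = lambda_min, lambda_max = lambda_max)
}

#' Chebyshev center: the largest ball inscribed in a polytope
#'
#' Solves the linear program maximizing \eqn{r} subject to
#' \eqn{a_i x + r \|a_i\|_2 \le b_i} and \eqn{r \ge 0}. A strictly positive
#' radius certifies a nonempty interior; radius zero flags a flat (degenerate)
#' feasible set. An infeasible program is reported as an error: this doubles
#' as the feasibility check for a polytope.
#'
#' @param P a [polytope()].
#' @return list with `center` (numeric vector) and `radius` (nonnegative).
#' @examples
#' chebyshev_center(hypercube(2)) # center (0.5, 0.5), radius 0.5
#' @export
chebyshev_center <- function(P) {
  n <- ncol(P$A)
  row_norms <- sqrt(rowSums(P$A^2))
  # variables (x, r); maximize r; extra row -r <= 0
  A_lp <- rbind(cbind(P$A, row_norms), c(rep(0, n), -1))
  b_lp <- c(P$b, 0)
  sol <- lp_solve(c(rep(0, n), 1), A_lp, b_lp, maximize = TRUE)
  if (sol$status == "infeasible") {
    cw_stop("polytope is infeasible (Chebyshev LP has no solution)",
            "cw_feasibility_error")
  }
  if (sol$status == "unbounded") {
    cw_stop("polytope is unbounded (inscribed-ball radius grows without bound)",
            "cw_unbounded_error")
  }
  center <- sol$x[seq_len(n)]
  radius <- max(sol$x[n + 1L], 0)
  list(center = center, radius = radius)
}

#' Remove redundant inequality constraints
#'
#' For each row i, maximizes \eqn{a_i x} subject to all other rows; the row is
#' dropped iff the optimum stays below \eqn{b_i - tol}, so the output describes
#' exactly the same point set. Retained rows keep their order.
#'
#' @param P a feasible [polytope()] with nonempty interior.
#' @param tol slack below which a constraint counts as redundant.
#' @return a [polytope()] with redundant rows removed.
#' @export
remove_redundant_constraints <- function(P, tol = 1e-9) {
  cc <- chebyshev_center(P) # errors if infeasible
  keep <- rep(TRUE, nrow(P$A))
  # exact duplicates never test redundant against each other in the LP
  # (each bounds the other), so drop repeats of normalized rows up front
  nrm <- pmax(sqrt(rowSums(P$A^2)), 1e-300)
  sig <- apply(cbind(P$A / nrm, P$b / nrm), 1L,
               function(r) paste(signif(r, 12), collapse = ","))
  keep[duplicated(sig)] <- FALSE
  for (i in seq_len(nrow(P$A))) {
    if (!keep[i]) next
    others <- which(keep & seq_len(nrow(P$A)) != i)
    if (length(others) == 0L) break
    sol <- lp_solve(P$A[i, ], P$A[others, , drop = FALSE], P$b[others],
                    maximize = TRUE)
    if (sol$status == "optimal" && sol$objective < P$b[i] - tol) {
      keep[i] <- FALSE
    }
    # unbounded relaxation means row i is needed; keep it
  }
  polytope(P$A[keep, , drop = FALSE], P$b[keep], label = P$label)
}

#' Eliminate equality constraints by null-space embedding
#'
#' Given the implicit description \eqn{Sx = c}, \eqn{Ax \le b}, computes a
#' particular solution \eqn{x_0} and an orthonormal basis `N` of the null
#' space of `S` (both via singular value decomposition), and returns the
#' full-dimensional reduced polytope \eqn{\{z : (AN) z \le b - A x_0\}}
#' together with the affine map `full = N z + x0` as a [transform_record()].
#' The reduced dimension is `n - rank(S)`.
#'
#' @param eq an [equality_system()].
#' @param P a [polytope()] on the same `n` variables.
#' @return list with elements `polytope` (reduced) and `transform`.
#' @export
embed_equalities <- function(eq, P) {
  n <- ncol(P$A)
  cw_check_dim(ncol(eq$S) == n,
               "equality system and polytope dimensions differ")
  sv <- svd(eq$S, nu = nrow(eq$S), nv = n)
  thresh <- max(dim(eq$S)) * .Machine$double.eps * max(sv$d, 0)
  r <- sum(sv$d > thresh)
  # particular solution via pseudo-inverse
  if (r == 0L) {
    if (any(abs(eq$c) > 1e-10)) {
      cw_stop("equality system is inconsistent (zero matrix, nonzero rhs)",
              "cw_inconsistent_error")
    }
    x0 <- rep(0, n)
  } else {
    d_inv <- 1 / sv$d[seq_len(r)]
    x0 <- sv$v[, seq_len(r), drop = FALSE] %*%
      (d_inv * (t(sv$u[, seq_len(r), drop = FALSE]) %*% eq$c))
    x0 <- as.numeric(x0)
  }
  resid <- sqrt(sum((eq$S %*% x0 - eq$c)^2))
  if (resid > 1e-8 * (1 + sqrt(sum(eq$c^2)))) {
    cw_stop("equality system is inconsistent: no particular solution exists",
            "cw_inconsistent_error")
  }
  if (r >= n) {
    cw_stop("equality system has full rank: the support is a single point",
            "cw_degenerate_error")
  }
  N <- sv$v[, (r + 1L):n, drop = FALSE]
  reduced <- polytope(P$A %*% N, P$b - as.numeric(P$A %*% x0),
                      label = P$label)
  list(polytope = reduced, transform = transform_record(N, x0))
}

#' Unit hypercube \[0,1\]^n
#' @param n dimension (>= 1).
#' @return a [polytope()] with `2n` rows.
#' @export
hypercube <- function(n) {
  n <- as.integer(n)
  if (n < 1L) cw_stop("n must be >= 1", "cw_domain_error")
  polytope(rbind(diag(n), -diag(n)), c(rep(1, n), rep(0, n)),
           label = sprintf("hypercube_%d", n))
}

#' Standard simplex
#'
#' By default returns the full-dimensional form
#' \eqn{\{\theta \in R^n : \theta_i \ge 0, \sum \theta_i \le 1\}} (n + 1 rows).
#' With `implicit = TRUE`, returns instead the probability simplex as a
#' nonnegativity polytope plus the sum-to-one [equality_system()], suitable
#' for [embed_equalities()].
#'
#' @param n dimension (>= 1).
#' @param implicit return the measure-zero face as polytope + equalities.
#' @return a [polytope()], or a list `(polytope, equalities)` if `implicit`.
#' @export
simplex_polytope <- function(n, implicit = FALSE) {
  n <- as.integer(n)
  if (n < 1L) cw_stop("n must be >= 1", "cw_domain_error")
  if (implicit) {
    list(polytope = polytope(-diag(n), rep(0, n),
                             label = sprintf("simplex_face_%d", n)),
         equalities = equality_system(matrix(1, 1L, n), 1))
  } else {
    polytope(rbind(-diag(n), rep(1, n)), c(rep(0, n), 1),
             label = sprintf("simplex_%d", n))
  }
}

#' Birkhoff polytope of doubly stochastic matrices
#'
#' Builds the `n^2` nonnegativity constraints and the `2n` row/column-sum
#' equalities of n-by-n doubly stochastic matrices, then eliminates the
#' equalities with [embed_equalities()]. The reduced polytope has the
#' intrinsic dimension \eqn{(n-1)^2}; the returned transform maps reduced
#' samples back to the `n^2` matrix entries in column-major order.
#'
#' @param n matrix size (>= 2).
#' @return list with `polytope` (reduced, dimension `(n-1)^2`) and `transform`.
#' @examples
#' bk <- birkhoff_polytope(3)
#' polytope_dim(bk$polytope) # 4
#' @export
birkhoff_polytope <- function(n) {
  n <- as.integer(n)
  if (n < 2L) cw_stop("Birkhoff polytope needs n >= 2", "cw_domain_error")
  nn <- n * n
  # column-major vectorization: entry (i, j) sits at index (j - 1) * n + i
  row_sum <- matrix(0, n, nn)
  col_sum <- matrix(0, n, nn)
  for (i in seq_len(n)) {
    row_sum[i, (seq_len(n) - 1L) * n + i] <- 1
    col_sum[i, (i - 1L) * n + seq_len(n)] <- 1
  }
  eq <- equality_system(rbind(row_sum, col_sum), rep(1, 2L * n))
  P <- polytope(-diag(nn), rep(0, nn), label = sprintf("birkhoff_%d", n))
  out <- embed_equalities(eq, P)
  out$polytope$label <- sprintf("birkhoff_%d_reduced", n)
  out
}
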