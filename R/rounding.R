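#' Round a polytope so isotropic proposals mix well
#'
#' Computes an invertible affine reparametrization `full = T z + s` such that
#' the transformed polytope `{z : (A T) z <= b - A s}` contains a unit ball
#' centered at the origin and is close to isotropic. Two methods are
#' provided behind one interface:
#'
#' * `"ellipsoid"` (deterministic): finds the analytic center of the
#'   inequality system by damped Newton iteration on the log-barrier and
#'   uses the inscribed Dikin ellipsoid there -- the inverse square root of
#'   the slack-weighted normal matrix \eqn{\sum_i a_i a_i' / s_i^2} -- as the
#'   shape matrix. This is the constraint-weighted least-squares
#'   approximation of the largest inscribed ellipsoid.
#' * `"covariance_svd"` (stochastic): alternates short uniform pre-sampling
#'   runs of coordinate Hit-and-Run with recomputing the SVD
#'   \eqn{U \Sigma U'} of the (regularized) sample covariance, composing the
#'   transform with \eqn{U \Sigma^{1/2}} until the singular-value spread
#'   stabilizes.
#'
#' Iteration stops once the rounding quality `q` (largest inscribed ball
#' radius over the max axis chord half-length, a cheap enclosing-ball
#' estimate) reaches 0.2, the quality stops improving, or `max_iter` is hit.
#'
#' @param P bounded [polytope()] with nonempty interior.
#' @param method `"ellipsoid"` or `"covariance_svd"`.
#' @param max_iter iteration cap.
#' @param tol relative change in the singular-value ratio below which the
#'   stochastic method declares convergence.
#' @param seed seed for the pre-sampling chain (stochastic method only).
#' @param presample_steps chain steps per covariance update, per dimension.
#' @return list with `polytope` (rounded) and `transform`
#'   (a [transform_record()]).
#' @examples
#' rd <- round_polytope(hypercube(3))
#' # membership is preserved: T z + s lies in the original polytope
#' contains(hypercube(3), map_point(rd$transform, c(0, 0, 0)))
#' @export
round_polytope <- function(P, method = c("ellipsoid", "covariance_svd"),
                           max_iter = 10L, tol = 0.05, seed = 1,
                           presample_steps = 50L) {
  method <- match.arg(method)
  n <- ncol(P$A)
  cc <- chebyshev_center(P)
  if (cc$radius <= 0) {
    cw_stop("polytope has empty interior (Chebyshev radius 0); cannot round",
            "cw_degenerate_error")
  }
  assert_bounded(P)

  basis <- diag(n)
  shift <- cc$center
  Q <- shifted_polytope(P, basis, shift)
  rng <- make_rng(seed, 0)
  quality <- rounding_quality(Q)
  kappa_prev <- Inf

  for (it in seq_len(max_iter)) {
    # the first pass always runs: the axis-chord enclosing-ball estimate can
    # miss anisotropy that is not axis-aligned, so quality only gates
    # follow-up iterations
    if (it > 1L && quality >= 0.2 && method == "ellipsoid") break
    if (method == "ellipsoid") {
      ac <- analytic_center(Q)
      H <- barrier_hessian(Q, ac)
      R <- chol((H + t(H)) / 2)
      Tstep <- backsolve(R, diag(n))
      shift <- shift + as.numeric(basis %*% ac)
      basis <- basis %*% Tstep
    } else {
      pts <- chr_presample(Q, rng, presample_steps * n)
      cv <- stats::cov(pts)
      cv <- cv + diag(1e-12 * max(sum(diag(cv)) / n, 1), n)
      sv <- svd(cv)
      kappa <- sqrt(max(sv$d) / min(sv$d))
      Tstep <- sv$u %*% (sqrt(sv$d) * t(sv$u))
      basis <- basis %*% Tstep
      converged <- is.finite(kappa_prev) &&
        abs(kappa / kappa_prev - 1) < tol
      kappa_prev <- kappa
      if (converged) {
        Q <- shifted_polytope(P, basis, shift)
        quality <- rounding_quality(Q)
        break
      }
    }
    Q <- shifted_polytope(P, basis, shift)
    q_new <- rounding_quality(Q)
    if (method == "ellipsoid" && q_new <= quality * (1 + 1e-6)) {
      quality <- max(quality, q_new)
      break
    }
    quality <- q_new
  }

  # scale so the transformed polytope contains the unit ball at the origin
  row_norms <- sqrt(rowSums((P$A %*% basis)^2))
  r0 <- min((P$b - as.numeric(P$A %*% shift)) / row_norms)
  if (r0 <= 0) {
    cw_stop("rounding lost strict interiority (numerical degeneracy)",
            "cw_numeric_error")
  }
  basis <- basis * r0
  Q <- shifted_polytope(P, basis, shift)
  list(polytope = Q, transform = transform_record(basis, shift))
}

shifted_polytope <- function(P, basis, shift) {
  polytope(P$A %*% basis, P$b - as.numeric(P$A %*% shift),
           label = if (is.null(P$label)) NULL else paste0(P$label, "_rounded"))
}

# bounded iff every coordinate range is bounded (2n LPs)
assert_bounded <- function(P) {
  n <- ncol(P$A)
  for (i in seq_len(n)) {
    e <- numeric(n)
    e[i] <- 1
    for (s in c(1, -1)) {
      sol <- lp_solve(s * e, P$A, P$b, maximize = TRUE)
      if (sol$status == "unbounded") {
        cw_stop(sprintf("polytope is unbounded along coordinate %d", i),
                "cw_unbounded_error")
      }
    }
  }
  invisible(TRUE)
}

# quality = inscribed ball radius / max axis chord half-length from origin
rounding_quality <- function(Q) {
  n <- ncol(Q$A)
  cc <- chebyshev_center(Q)
  half <- 0
  origin <- rep(0, n)
  for (i in seq_len(n)) {
    e <- numeric(n)
    e[i] <- 1
    cb <- chord_bounds(Q, origin, e)
    half <- max(half, abs(cb[1L]), abs(cb[2L]))
  }
  cc$radius / half
}

# analytic center of {x : Ax <= b} by damped Newton on the log-barrier,
# started from the Chebyshev center
analytic_center <- function(Q, max_newton = 50L) {
  x <- chebyshev_center(Q)$center
  A <- Q$A
  b <- Q$b
  for (k in seq_len(max_newton)) {
    s <- b - as.numeric(A %*% x)
    g <- as.numeric(t(A) %*% (1 / s))
    H <- crossprod(A / s)
    step <- tryCatch(-solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    lambda2 <- -sum(g * step)
    if (lambda2 < 1e-10) break
    t_step <- 1
    phi0 <- -sum(log(s))
    repeat {
      xn <- x + t_step * step
      sn <- b - as.numeric(A %*% xn)
      if (all(sn > 0) && -sum(log(sn)) < phi0 - 1e-12) break
      t_step <- t_step / 2
      if (t_step < 1e-12) break
    }
    if (t_step < 1e-12) break
    x <- x + t_step * step
  }
  x
}

barrier_hessian <- function(Q, x) {
  s <- Q$b - as.numeric(Q$A %*% x)
  crossprod(Q$A / s)
}

# lightweight uniform coordinate hit-and-run pre-sampler from the origin
chr_presample <- function(Q, rng, n_steps) {
  n <- ncol(Q$A)
  x <- rep(0, n)
  out <- matrix(0, n_steps, n)
  axes <- rng_integer(rng, n_steps, n)
  us <- rng_uniform(rng, n_steps)
  for (t in seq_len(n_steps)) {
    i <- axes[t]
    ad <- Q$A[, i]
    slack <- Q$b - as.numeric(Q$A %*% x)
    pos <- ad > 0
    neg <- ad < 0
    if (!any(pos) || !any(neg)) {
      cw_stop(sprintf("polytope is unbounded along coordinate %d", i),
              "cw_unbounded_error")
    }
    lmax <- min(slack[pos] / ad[pos])
    lmin <- max(slack[neg] / ad[neg])
    x[i] <- x[i] + lmin + (lmax - lmin) * us[t]
    out[t, ] <- x
  }
  out
}
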