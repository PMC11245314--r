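# The proposal marketplace: interchangeable transition-kernel builders
# behind one minimal contract.
#
# A proposal is a list of class "cw_proposal" with
#   name            registry name
#   params          constructor parameters (for rebuild/serialization)
#   propose(rng, x) -> list(point, log_correction, stuck)
#   advance(x)      engine callback with the realized state after each step
#                   (adaptation hook; most proposals ignore it)
#   step_size() / set_step_size(s)  present iff the kernel is tunable
#   snapshot() / restore(s)         internal mutable state, for checkpointing
#   burn_in         number of initial steps to flag as adaptation burn-in
#
# propose() never mutates stored state; the Metropolis filter is applied by
# the engine. For symmetric proposals log_correction is 0; for asymmetric
# ones it is log q(y -> x) - log q(x -> y).

new_proposal <- function(name, params, propose, advance = NULL,
                         internal = NULL, tunable = FALSE, burn_in = 0L) {
  if (is.null(internal)) internal <- new.env(parent = emptyenv())
  obj <- list(
    name = name,
    params = params,
    internal = internal,
    propose = propose,
    advance = if (is.null(advance)) function(x) invisible(NULL) else advance,
    snapshot = function() as.list(internal),
    restore = function(s) {
      for (nm in names(s)) assign(nm, s[[nm]], envir = internal)
      invisible(NULL)
    },
    step_size = if (tunable) function() internal$step_size else NULL,
    set_step_size = if (tunable) function(s) {
      if (!is.numeric(s) || s <= 0) {
        cw_stop("step size must be positive", "cw_validation_error")
      }
      internal$step_size <- s
      invisible(NULL)
    } else NULL,
    burn_in = burn_in
  )
  class(obj) <- "cw_proposal"
  obj
}

#' @export
print.cw_proposal <- function(x, ...) {
  cat(sprintf("<proposal: %s%s>\n", x$name,
              if (!is.null(x$step_size)) {
                sprintf(" (step size %g)", x$step_size())
              } else ""))
  invisible(x)
}

check_start <- function(P, start) {
  cw_check_dim(length(start) == ncol(P$A),
               "start length must equal polytope dimension")
  if (!strictly_interior(P, start)) {
    cw_stop("start point must be strictly interior", "cw_feasibility_error")
  }
  invisible(TRUE)
}

# unit-sphere direction; redraws degenerate (norm ~ 0) vectors
sphere_direction <- function(rng, n) {
  repeat {
    d <- rng_normal(rng, n)
    nrm <- sqrt(sum(d^2))
    if (nrm > 1e-300) return(d / nrm)
  }
}

#' Hit-and-Run proposal with uniform chord draw
#'
#' Draws a direction uniformly on the unit sphere, computes the feasible
#' chord through the current point, and proposes a uniform point on it.
#' Because the chord is a property of the line (not of the point on it), the
#' kernel is symmetric and the Metropolis acceptance reduces to the target
#' density ratio; for a uniform target every proposal is accepted.
#'
#' @param problem a [sampling_problem()].
#' @param start strictly interior point in reduced coordinates.
#' @return a proposal object (see [make_proposal()]).
#' @export
hit_and_run_proposal <- function(problem, start) {
  P <- problem$polytope
  check_start(P, start)
  n <- ncol(P$A)
  new_proposal(
    name = "hit_and_run", params = list(),
    propose = function(rng, x) {
      d <- sphere_direction(rng, n)
      cb <- chord_bounds(P, x, d)
      lambda <- cb[[1L]] + (cb[[2L]] - cb[[1L]]) * rng_uniform(rng, 1L)
      list(point = x + lambda * d, log_correction = 0, stuck = FALSE)
    }
  )
}

#' Coordinate Hit-and-Run proposal
#'
#' As [hit_and_run_proposal()], but the direction is a uniformly chosen
#' coordinate axis, so each step changes exactly one coordinate. Combined
#' with [round_polytope()] preprocessing and engine-level thinning this is
#' the Coordinate Hit-and-Run with Rounding and Thinning (CHRRT) scheme.
#'
#' @inheritParams hit_and_run_proposal
#' @return a proposal object.
#' @export
coordinate_hit_and_run_proposal <- function(problem, start) {
  P <- problem$polytope
  check_start(P, start)
  n <- ncol(P$A)
  new_proposal(
    name = "coordinate_hit_and_run", params = list(),
    propose = function(rng, x) {
      i <- rng_integer(rng, 1L, n)
      ad <- P$A[, i]
      slack <- P$b - as.numeric(P$A %*% x)
      pos <- ad > 0
      neg <- ad < 0
      if (!any(pos) || !any(neg)) {
        cw_stop(sprintf("chord unbounded along coordinate axis %d", i),
                "cw_unbounded_error")
      }
      lmax <- min(slack[pos] / ad[pos])
      lmin <- max(slack[neg] / ad[neg])
      y <- x
      y[i] <- y[i] + lmin + (lmax - lmin) * rng_uniform(rng, 1L)
      list(point = y, log_correction = 0, stuck = FALSE)
    }
  )
}

#' Gaussian Hit-and-Run proposal (tunable)
#'
#' Direction uniform on the sphere; the step along the chord is drawn from a
#' centered normal with standard deviation `step_size`, truncated to the
#' chord by rejection (at most 100 tries, after which the chain stays put
#' and the event is counted). Truncation makes the kernel asymmetric --
#' the normalizing mass of the truncated normal differs between the current
#' and the proposed point -- so the proposal reports the exact Hastings
#' correction \eqn{\log Z(x) - \log Z(y)}, keeping the Metropolis filter
#' exact for every target.
#'
#' @inheritParams hit_and_run_proposal
#' @param step_size positive standard deviation of the chord step.
#' @return a proposal object exposing `step_size`.
#' @export
gaussian_hit_and_run_proposal <- function(problem, start, step_size = 1) {
  P <- problem$polytope
  check_start(P, start)
  if (!is.numeric(step_size) || length(step_size) != 1L || step_size <= 0) {
    cw_stop("step_size must be a positive number", "cw_validation_error")
  }
  n <- ncol(P$A)
  internal <- new.env(parent = emptyenv())
  internal$step_size <- step_size
  new_proposal(
    name = "gaussian_hit_and_run", params = list(step_size = step_size),
    internal = internal, tunable = TRUE,
    propose = function(rng, x) {
      s <- internal$step_size
      d <- sphere_direction(rng, n)
      cb <- chord_bounds(P, x, d)
      lambda <- NA_real_
      for (try in seq_len(100L)) {
        cand <- s * rng_normal(rng, 1L)
        if (cand >= cb[[1L]] && cand <= cb[[2L]]) {
          lambda <- cand
          break
        }
      }
      if (is.na(lambda)) {
        return(list(point = x, log_correction = 0, stuck = TRUE))
      }
      z_x <- stats::pnorm(cb[[2L]] / s) - stats::pnorm(cb[[1L]] / s)
      z_y <- stats::pnorm((cb[[2L]] - lambda) / s) -
        stats::pnorm((cb[[1L]] - lambda) / s)
      list(point = x + lambda * d,
           log_correction = log(z_x) - log(z_y), stuck = FALSE)
    }
  )
}

#' Over-relaxed Hit-and-Run proposal (uniform targets)
#'
#' Reflects the current point through the midpoint of the feasible chord:
#' with the chord \eqn{[\lambda_{min}, \lambda_{max}]} around the current
#' point, the candidate sits at \eqn{\lambda' = \lambda_{min} +
#' \lambda_{max}}. The move is deterministic given the direction,
#' self-inverse along the chord, and preserves the uniform law, inducing
#' antithetic (negatively autocorrelated) moves that suppress random-walk
#' behavior. It is only valid for uniform targets, which is enforced at
#' construction.
#'
#' @inheritParams hit_and_run_proposal
#' @return a proposal object.
#' @export
over_relaxed_hit_and_run_proposal <- function(problem, start) {
  if (!is_uniform_model(problem$model)) {
    cw_stop(paste("over-relaxed Hit-and-Run preserves only the uniform law;",
                  "use it with uniform_model()"), "cw_unsupported_target_error")
  }
  P <- problem$polytope
  check_start(P, start)
  n <- ncol(P$A)
  new_proposal(
    name = "over_relaxed_hit_and_run", params = list(),
    propose = function(rng, x) {
      d <- sphere_direction(rng, n)
      cb <- chord_bounds(P, x, d)
      list(point = x + (cb[[1L]] + cb[[2L]]) * d,
           log_correction = 0, stuck = FALSE)
    }
  )
}

#' Adaptive SVD Hit-and-Run proposal
#'
#' Learns the shape of the target on the fly instead of rounding the
#' polytope up front: a running mean and covariance of the visited states
#' are maintained, and every `update_interval` steps (while the total step
#' count is below `adaptation_horizon`) the direction distribution is reset
#' to \eqn{U \Sigma^{1/2} z / \| \cdot \|} with \eqn{U \Sigma U'} the SVD of
#' the regularized running covariance and `z` standard normal. The chord
#' draw stays uniform, so each fixed direction distribution leaves the
#' uniform law invariant. After the horizon the transform is frozen
#' (finite adaptation), making the post-freeze chain a valid Markov chain;
#' the engine flags the pre-freeze stretch as burn-in.
#'
#' @inheritParams hit_and_run_proposal
#' @param update_interval steps between direction-matrix updates.
#' @param adaptation_horizon total steps after which adaptation freezes.
#' @return a proposal object.
#' @export
adaptive_svd_proposal <- function(problem, start, update_interval = 100L,
                                  adaptation_horizon = 2000L) {
  P <- problem$polytope
  check_start(P, start)
  update_interval <- as.integer(update_interval)
  adaptation_horizon <- as.integer(adaptation_horizon)
  if (update_interval <= 0L || adaptation_horizon <= 0L) {
    cw_stop("update_interval and adaptation_horizon must be positive",
            "cw_validation_error")
  }
  n <- ncol(P$A)
  internal <- new.env(parent = emptyenv())
  internal$steps <- 0L
  internal$n_obs <- 0L
  internal$mean <- rep(0, n)
  internal$m2 <- matrix(0, n, n)
  internal$dirmat <- NULL # NULL = isotropic fallback
  internal$frozen <- FALSE
  new_proposal(
    name = "adaptive_svd",
    params = list(update_interval = update_interval,
                  adaptation_horizon = adaptation_horizon),
    internal = internal, burn_in = adaptation_horizon,
    propose = function(rng, x) {
      z <- rng_normal(rng, n)
      d <- if (is.null(internal$dirmat)) z else
        as.numeric(internal$dirmat %*% z)
      nrm <- sqrt(sum(d^2))
      while (nrm <= 1e-300) {
        z <- rng_normal(rng, n)
        d <- if (is.null(internal$dirmat)) z else
          as.numeric(internal$dirmat %*% z)
        nrm <- sqrt(sum(d^2))
      }
      d <- d / nrm
      cb <- chord_bounds(P, x, d)
      lambda <- cb[[1L]] + (cb[[2L]] - cb[[1L]]) * rng_uniform(rng, 1L)
      list(point = x + lambda * d, log_correction = 0, stuck = FALSE)
    },
    advance = function(x) {
      if (!internal$frozen) {
        # Welford running mean / scatter
        internal$n_obs <- internal$n_obs + 1L
        delta <- x - internal$mean
        internal$mean <- internal$mean + delta / internal$n_obs
        internal$m2 <- internal$m2 + tcrossprod(delta, x - internal$mean)
      }
      internal$steps <- internal$steps + 1L
      if (!internal$frozen && internal$steps %% update_interval == 0L &&
          internal$n_obs >= 2L) {
        cv <- internal$m2 / (internal$n_obs - 1L)
        cv <- cv + diag(1e-12 * max(sum(diag(cv)) / n, 1), n)
        sv <- svd(cv)
        internal$dirmat <- sv$u %*% (sqrt(pmax(sv$d, 0)) * t(sv$u))
      }
      if (internal$steps >= adaptation_horizon) internal$frozen <- TRUE
      invisible(NULL)
    }
  )
}

# --- registry -----------------------------------------------------------

the_registry <- new.env(parent = emptyenv())

#' Register a proposal constructor under a name
#'
#' Third-party kernels that satisfy the proposal contract integrate with the
#' engine, the tuner, and the CLI by registering a constructor
#' `function(problem, start, ...)`.
#'
#' @param name registry key.
#' @param constructor function(problem, start, ...) returning a proposal.
#' @export
register_proposal <- function(name, constructor) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    cw_stop("proposal name must be a nonempty string", "cw_validation_error")
  }
  if (!is.function(constructor)) {
    cw_stop("constructor must be a function", "cw_validation_error")
  }
  assign(name, constructor, envir = the_registry)
  invisible(name)
}

#' Names of registered proposals
#' @return character vector.
#' @export
proposal_names <- function() sort(ls(the_registry))

#' Build a proposal from the registry
#'
#' @param name registered proposal name (see [proposal_names()]).
#' @param problem a [sampling_problem()].
#' @param start strictly interior start point (reduced coordinates).
#' @param params named list of extra constructor arguments
#'   (e.g. `step_size`).
#' @return a proposal object.
#' @export
make_proposal <- function(name, problem, start, params = list()) {
  if (!exists(name, envir = the_registry, inherits = FALSE)) {
    cw_stop(sprintf("unknown proposal '%s'; registered proposals: %s",
                    name, paste(proposal_names(), collapse = ", ")),
            "cw_registry_error")
  }
  ctor <- get(name, envir = the_registry, inherits = FALSE)
  do.call(ctor, c(list(problem = problem, start = start), params))
}

register_builtin_proposals <- function() {
  register_proposal("hit_and_run", hit_and_run_proposal)
  register_proposal("coordinate_hit_and_run", coordinate_hit_and_run_proposal)
  register_proposal("gaussian_hit_and_run", gaussian_hit_and_run_proposal)
  register_proposal("over_relaxed_hit_and_run",
                    over_relaxed_hit_and_run_proposal)
  register_proposal("adaptive_svd", adaptive_svd_proposal)
}
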