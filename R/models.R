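#' Log-density model contract
#'
#' A model supplies the (possibly unnormalized) log-density of the target on
#' the polytope, plus optionally its gradient and a positive-definite
#' curvature. The support restriction is the polytope's job, not the
#' model's: models are evaluated in ORIGINAL coordinates at points that the
#' engine has already certified feasible. A return of `-Inf` means zero
#' density and is legal; `NaN` is always treated as a bug in the model.
#'
#' @param log_density function(point) -> finite real or -Inf.
#' @param log_gradient optional function(point) -> numeric vector.
#' @param log_curvature optional function(point) -> positive-definite matrix.
#' @param kind internal tag ("uniform", "gaussian", "mixture", "plugin").
#' @return An object of class `"cw_model"`.
#' @export
cw_model <- function(log_density, log_gradient = NULL, log_curvature = NULL,
                     kind = "custom") {
  if (!is.function(log_density)) {
    cw_stop("log_density must be a function", "cw_contract_error")
  }
  structure(list(log_density = log_density, log_gradient = log_gradient,
                 log_curvature = log_curvature, kind = kind),
            class = "cw_model")
}

#' @export
print.cw_model <- function(x, ...) {
  cat(sprintf("<model: %s%s%s>\n", x$kind,
              if (!is.null(x$log_gradient)) " +gradient" else "",
              if (!is.null(x$log_curvature)) " +curvature" else ""))
  invisible(x)
}

is_uniform_model <- function(model) identical(model$kind, "uniform")

#' Uniform target on the polytope
#'
#' Log-density identically zero; the polytope membership filter alone shapes
#' the stationary law.
#' @return a [cw_model()].
#' @export
uniform_model <- function() {
  cw_model(log_density = function(point) 0,
           log_gradient = function(point) rep(0, length(point)),
           kind = "uniform")
}

#' Multivariate Gaussian target
#'
#' Log-density \eqn{-\frac12 (\theta-\mu)' \Sigma^{-1} (\theta-\mu)
#' - \frac12 \log\det(2\pi\Sigma)}, with gradient
#' \eqn{-\Sigma^{-1}(\theta-\mu)} and constant curvature \eqn{\Sigma^{-1}}.
#' The normalizing constant is included so values can be checked against the
#' closed form, although Metropolis ratios would cancel it.
#'
#' @param mean numeric mean vector.
#' @param covariance symmetric positive-definite covariance matrix.
#' @return a [cw_model()].
#' @examples
#' m <- gaussian_model(c(0, 0), diag(2))
#' m$log_density(c(0, 0)) # -log(2*pi)
#' @export
gaussian_model <- function(mean, covariance) {
  mean <- as.numeric(mean)
  covariance <- as.matrix(covariance)
  n <- length(mean)
  cw_check_dim(all(dim(covariance) == n),
               "covariance dimensions must match the mean")
  if (max(abs(covariance - t(covariance))) > 1e-10 * (1 + max(abs(covariance)))) {
    cw_stop("covariance must be symmetric", "cw_validation_error")
  }
  ch <- tryCatch(chol(covariance), error = function(e) NULL)
  if (is.null(ch)) {
    cw_stop("covariance must be positive-definite", "cw_validation_error")
  }
  prec <- chol2inv(ch)
  log_det <- 2 * sum(log(diag(ch)))
  const <- -0.5 * (n * log(2 * pi) + log_det)
  cw_model(
    log_density = function(point) {
      d <- point - mean
      const - 0.5 * sum(d * (prec %*% d))
    },
    log_gradient = function(point) -as.numeric(prec %*% (point - mean)),
    log_curvature = function(point) prec,
    kind = "gaussian"
  )
}

#' Mixture of log-density models
#'
#' Log-density is the log-sum-exp of `log w_k + log f_k(theta)`, computed
#' with max-subtraction for numerical stability. The canonical use is a
#' well-separated Gaussian mixture as a multimodal test target for parallel
#' tempering.
#'
#' @param components list of [cw_model()] objects sharing one dimension.
#' @param weights positive weights; normalized internally.
#' @return a [cw_model()].
#' @export
mixture_model <- function(components, weights = NULL) {
  if (length(components) == 0L) {
    cw_stop("mixture needs at least one component", "cw_validation_error")
  }
  if (is.null(weights)) weights <- rep(1, length(components))
  weights <- as.numeric(weights)
  if (length(weights) != length(components) || any(weights <= 0) ||
      !all(is.finite(weights))) {
    cw_stop("weights must be positive, finite, one per component",
            "cw_validation_error")
  }
  log_w <- log(weights / sum(weights))
  fns <- lapply(components, function(m) m$log_density)
  cw_model(
    log_density = function(point) {
      lv <- vapply(fns, function(f) f(point), numeric(1)) + log_w
      mx <- max(lv)
      if (!is.finite(mx)) return(-Inf)
      mx + log(sum(exp(lv - mx)))
    },
    kind = "mixture"
  )
}

#' Adapt a user object to the model contract
#'
#' Accepts any object carrying a log-density callable -- a bare function, or
#' a list/environment with a `log_density` element (optionally
#' `log_gradient`, `log_curvature`) -- and wraps it as a [cw_model()]. If a
#' probe point is supplied, the wrapper evaluates it once at wrap time and
#' rejects non-finite answers other than `-Inf` immediately; at sampling
#' time, a `NaN` raises an error naming the offending point rather than
#' corrupting the chain.
#'
#' @param user_object function, list, or environment exposing a log-density.
#' @param probe optional strictly interior point evaluated at wrap time.
#' @return a [cw_model()].
#' @export
wrap_plugin <- function(user_object, probe = NULL) {
  if (is.function(user_object)) {
    f <- user_object
    g <- NULL
    h <- NULL
  } else if (is.list(user_object) || is.environment(user_object)) {
    f <- user_object[["log_density"]]
    g <- user_object[["log_gradient"]]
    h <- user_object[["log_curvature"]]
  } else {
    f <- NULL
  }
  if (!is.function(f)) {
    cw_stop("plugin must expose a log-density callable", "cw_contract_error")
  }
  guarded <- function(point) {
    v <- f(point)
    if (length(v) != 1L || is.nan(v) || (is.infinite(v) && v > 0)) {
      cw_stop(paste0("plugin log-density returned a non-finite value (not ",
                     "-Inf) at point (",
                     paste(signif(point, 6), collapse = ", "), ")"),
              "cw_plugin_error")
    }
    as.numeric(v)
  }
  if (!is.null(probe)) {
    pv <- f(probe)
    if (length(pv) != 1L || is.nan(pv) || (is.infinite(pv) && pv > 0)) {
      cw_stop("plugin log-density failed the wrap-time probe", "cw_plugin_error")
    }
  }
  cw_model(log_density = guarded, log_gradient = g, log_curvature = h,
           kind = "plugin")
}

#' Bundle a polytope, a target model, and a change of variables
#'
#' The sampling target. Proposals act on the (reduced, possibly rounded)
#' `polytope`; the `model` is always evaluated in original coordinates at
#' `map_point(transform, z)`. `original_polytope`, when given, lets
#' consumers re-verify membership of mapped draws.
#'
#' @param polytope the [polytope()] the chain moves in.
#' @param model a [cw_model()]; defaults to the uniform target.
#' @param transform optional [transform_record()] (reduced -> original).
#' @param original_polytope optional original-space [polytope()].
#' @return An object of class `"sampling_problem"`.
#' @export
sampling_problem <- function(polytope, model = uniform_model(),
                             transform = NULL, original_polytope = NULL) {
  if (!inherits(polytope, "polytope")) {
    cw_stop("polytope must be a polytope object", "cw_validation_error")
  }
  if (!inherits(model, "cw_model")) {
    cw_stop("model must be a cw_model", "cw_validation_error")
  }
  if (!is.null(transform)) {
    cw_check_dim(ncol(transform$basis) == ncol(polytope$A),
                 "transform basis columns must match polytope dimension")
  }
  structure(list(polytope = polytope, model = model, transform = transform,
                 original_polytope = original_polytope),
            class = "sampling_problem")
}

#' @export
print.sampling_problem <- function(x, ...) {
  cat(sprintf("<sampling problem: %d-D polytope, %s target%s>\n",
              ncol(x$polytope$A), x$model$kind,
              if (!is.null(x$transform)) {
                sprintf(", mapped to %d-D original space",
                        nrow(x$transform$basis))
              } else ""))
  invisible(x)
}

# evaluate the target model at a reduced-space point (original coordinates)
eval_target <- function(problem, z) {
  full <- map_point(problem$transform, z)
  v <- problem$model$log_density(full)
  if (length(v) != 1L || is.nan(v) || (is.infinite(v) && v > 0)) {
    cw_stop(paste0("model log-density returned a non-finite value (not -Inf)",
                   " at point (", paste(signif(full, 6), collapse = ", "), ")"),
            "cw_plugin_error")
  }
  as.numeric(v)
}

#' Preprocess a polytope into a ready-to-sample problem
#'
#' Convenience pipeline: optional equality embedding, redundant-constraint
#' removal, and optional rounding, with the individual transform records
#' composed into one. The model stays expressed in original coordinates.
#'
#' @param P original-space [polytope()].
#' @param equalities optional [equality_system()] to eliminate first.
#' @param model a [cw_model()] in original coordinates.
#' @param round apply [round_polytope()] after embedding.
#' @param rounding_method passed to [round_polytope()].
#' @param redundancy_tol passed to [remove_redundant_constraints()];
#'   `NULL` skips removal.
#' @param seed seed for the stochastic rounding method.
#' @return a [sampling_problem()].
#' @export
prepare_problem <- function(P, equalities = NULL, model = uniform_model(),
                            round = TRUE, rounding_method = "ellipsoid",
                            redundancy_tol = 1e-9, seed = 1) {
  transform <- NULL
  Q <- P
  if (!is.null(equalities)) {
    emb <- embed_equalities(equalities, Q)
    Q <- emb$polytope
    transform <- emb$transform
  }
  if (!is.null(redundancy_tol)) {
    Q <- remove_redundant_constraints(Q, tol = redundancy_tol)
  }
  if (round) {
    rd <- round_polytope(Q, method = rounding_method, seed = seed)
    Q <- rd$polytope
    transform <- if (is.null(transform)) rd$transform else
      compose_transforms(transform, rd$transform)
  }
  sampling_problem(Q, model = model, transform = transform,
                   original_polytope = P)
}
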