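#' Generate a synthetic test fixture on disk
#'
#' Produces self-contained, fully offline test inputs: polytope CSVs,
#' optional equality system and transform, an optional model block, and a
#' `manifest.json` recording the fixture's analytic ground truth (dimension,
#' Chebyshev data, coordinate moments where known). Every manifest entry is
#' confirmed by the corresponding library computation at generation time.
#'
#' Kinds:
#' * `hypercube`: \[0,1\]^n; mean 1/2 and variance 1/12 per coordinate.
#' * `simplex`: full-dimensional standard simplex; marginals are
#'   Beta(1, n).
#' * `birkhoff`: reduced Birkhoff polytope of n-by-n doubly stochastic
#'   matrices, with the transform back to matrix entries.
#' * `stretched_box`: box \[0,1\]^(n-1) x \[0, anisotropy\] under a seeded
#'   random rotation -- anisotropic in every coordinate direction, the
#'   standard stress test for rounding.
#' * `random_hpoly`: box \[-1,1\]^n intersected with `k` random half-spaces
#'   through sampled interior points (nonempty and bounded by
#'   construction).
#' * `bimodal_gaussian`: unit square with a two-component Gaussian mixture
#'   model (means (0.2, 0.2) and (0.8, 0.8), sd 0.03, equal weights), the
#'   multimodal target used to exercise parallel tempering.
#'
#' @param kind fixture kind (see above).
#' @param n dimension parameter (matrix size for `birkhoff`).
#' @param seed integer seed for the fixture's randomness.
#' @param params named list of kind-specific parameters
#'   (`anisotropy`, `k`, `modes`, `mode_sd`).
#' @param dir output directory (created if missing).
#' @return the manifest list, invisibly.
#' @export
make_fixture <- function(kind = c("hypercube", "simplex", "birkhoff",
                                  "stretched_box", "random_hpoly",
                                  "bimodal_gaussian"),
                         n, seed = 1, params = list(), dir) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rng <- make_rng(seed, 0)
  manifest <- list(kind = kind, n = n, seed = seed)
  model_cfg <- list(name = "uniform")

  if (kind == "hypercube") {
    if (n < 1L) cw_stop("hypercube needs n >= 1", "cw_domain_error")
    P <- hypercube(n)
    manifest$coordinate_mean <- rep(0.5, n)
    manifest$coordinate_var <- rep(1 / 12, n)
  } else if (kind == "simplex") {
    if (n < 1L) cw_stop("simplex needs n >= 1", "cw_domain_error")
    P <- simplex_polytope(n)
    manifest$coordinate_mean <- rep(1 / (n + 1), n)
    manifest$coordinate_var <- rep(n / ((n + 1)^2 * (n + 2)), n)
  } else if (kind == "birkhoff") {
    if (n < 2L) cw_stop("birkhoff needs n >= 2", "cw_domain_error")
    bk <- birkhoff_polytope(n)
    P <- bk$polytope
    write_transform(bk$transform, file.path(dir, "transform"))
    manifest$reduced_dim <- (n - 1L)^2
    stopifnot(polytope_dim(P) == manifest$reduced_dim) # generation-time check
    manifest$full_dim <- n^2
  } else if (kind == "stretched_box") {
    if (n < 2L) cw_stop("stretched_box needs n >= 2", "cw_domain_error")
    anis <- if (is.null(params$anisotropy)) 100 else params$anisotropy
    lengths <- c(rep(1, n - 1L), anis)
    # seeded random rotation via QR of a standard normal matrix
    M <- matrix(rng_normal(rng, n * n), n, n)
    qrd <- qr(M)
    Q <- qr.Q(qrd)
    Q <- Q %*% diag(sign(diag(qr.R(qrd))), n)
    A_box <- rbind(diag(n), -diag(n))
    b_box <- c(lengths, rep(0, n))
    P <- polytope(A_box %*% t(Q), b_box, label = "stretched_box")
    manifest$anisotropy <- anis
    manifest$axis_lengths <- lengths
    manifest$rotation <- Q
    manifest$long_axis <- Q[, n]
    manifest$long_axis_var <- anis^2 / 12
    manifest$coordinate_mean <- as.numeric(Q %*% (lengths / 2))
  } else if (kind == "random_hpoly") {
    if (n < 2L) cw_stop("random_hpoly needs n >= 2", "cw_domain_error")
    k <- if (is.null(params$k)) 2L * n else as.integer(params$k)
    A <- rbind(diag(n), -diag(n))
    b <- rep(1, 2L * n)
    # sample all probe points first; every cut passes just beyond the
    # extremal probe, so all probes (and the origin) stay feasible
    probes <- matrix(rng_uniform(rng, k * n) - 0.5, k, n)
    for (i in seq_len(k)) {
      a <- sphere_direction(rng, n)
      A <- rbind(A, a)
      b <- c(b, max(probes %*% a, 0) + 0.05)
    }
    P <- polytope(A, b, label = sprintf("random_hpoly_%d", n))
    stopifnot(all(apply(probes, 1L, function(p) contains(P, p, 1e-9))))
    manifest$k <- k
    manifest$probe_points <- probes
  } else { # bimodal_gaussian
    if (n != 2L) cw_stop("bimodal_gaussian is two-dimensional",
                         "cw_domain_error")
    P <- hypercube(2L)
    P$label <- "bimodal_gaussian_support"
    modes <- if (is.null(params$modes)) {
      list(c(0.2, 0.2), c(0.8, 0.8))
    } else {
      params$modes
    }
    sd_mode <- if (is.null(params$mode_sd)) 0.03 else params$mode_sd
    model_cfg <- list(
      name = "mixture",
      weights = rep(1 / length(modes), length(modes)),
      components = lapply(modes, function(m) {
        list(name = "gaussian", mean = m,
             covariance = diag(sd_mode^2, 2L))
      })
    )
    manifest$modes <- modes
    manifest$mode_sd <- sd_mode
  }

  cc <- chebyshev_center(P) # generation-time feasibility certificate
  manifest$dim <- polytope_dim(P)
  manifest$chebyshev_center <- cc$center
  manifest$chebyshev_radius <- cc$radius
  write_polytope(P, file.path(dir, "polytope"))
  jsonlite::write_json(model_cfg, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$files <- list(polytope = "polytope", model = "model.json")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Build a model from a config block
#'
#' Understands the blocks written by [make_fixture()] and accepted by the
#' CLI: `uniform`, `gaussian` (mean + covariance), and `mixture`
#' (components + weights). Plugin models are a library-only feature.
#'
#' @param cfg named list with at least `name`.
#' @return a [cw_model()].
#' @export
model_from_config <- function(cfg) {
  if (is.null(cfg) || is.null(cfg$name)) {
    cw_stop("model config needs a 'name' field", "cw_config_error")
  }
  if (cfg$name == "uniform") {
    uniform_model()
  } else if (cfg$name == "gaussian") {
    gaussian_model(as.numeric(cfg$mean), as.matrix(cfg$covariance))
  } else if (cfg$name == "mixture") {
    comps <- cfg$components
    if (is.data.frame(comps)) {
      comps <- lapply(seq_len(nrow(comps)), function(i) {
        list(name = comps$name[i], mean = comps$mean[[i]],
             covariance = comps$covariance[[i]])
      })
    }
    mixture_model(lapply(comps, model_from_config),
                  weights = as.numeric(cfg$weights))
  } else {
    cw_stop(sprintf("unknown model name '%s'", cfg$name), "cw_config_error")
  }
}
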