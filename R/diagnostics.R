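# Convergence and efficiency diagnostics, computed natively on
# (chains x iterations x dimensions) arrays. Output layout is directly
# consumable by standard MCMC-analysis tooling.

as_draws_array <- function(draws) {
  if (inherits(draws, "sample_batch")) draws <- draws$draws
  if (is.matrix(draws)) draws <- array(draws, c(1L, dim(draws)))
  if (length(dim(draws)) != 3L) {
    cw_stop("draws must be a (chains x iterations x dimensions) array",
            "cw_validation_error")
  }
  draws
}

#' Split Gelman-Rubin potential scale reduction
#'
#' Classic split-R-hat: each chain is halved, the between- and
#' within-variance of the `2 * n_chains` half-chains are combined as
#' \eqn{\hat R = \sqrt{((N-1)/N \cdot W + B/N) / W}} per dimension. Values
#' near 1 indicate convergence. Dimensions whose within-variance is zero
#' (all-constant chains) yield `NA` with a `"degenerate"` attribute rather
#' than an error. The statistic is invariant under affine reparametrization
#' of each dimension.
#'
#' @param draws array (chains x iterations x dimensions), a matrix
#'   (iterations x dimensions, one chain), or a `"sample_batch"`.
#' @return numeric vector of R-hat values, one per dimension, with
#'   attribute `degenerate` (logical).
#' @export
split_rhat <- function(draws) {
  x <- as_draws_array(draws)
  n_chains <- dim(x)[1L]
  n_iter <- dim(x)[2L]
  n_dim <- dim(x)[3L]
  if (n_chains < 1L || n_iter < 4L) {
    cw_stop("split R-hat needs at least 4 iterations", "cw_validation_error")
  }
  half <- n_iter %/% 2L
  out <- numeric(n_dim)
  degen <- logical(n_dim)
  for (d in seq_len(n_dim)) {
    halves <- vector("list", 2L * n_chains)
    for (k in seq_len(n_chains)) {
      halves[[2L * k - 1L]] <- x[k, seq_len(half), d]
      halves[[2L * k]] <- x[k, half + seq_len(half), d]
    }
    m <- vapply(halves, mean, numeric(1))
    v <- vapply(halves, stats::var, numeric(1))
    W <- mean(v)
    B <- half * stats::var(m)
    if (!is.finite(W) || W <= 0) {
      out[d] <- NA_real_
      degen[d] <- TRUE
    } else {
      out[d] <- sqrt(((half - 1) / half * W + B / half) / W)
    }
  }
  attr(out, "degenerate") <- degen
  out
}

#' Effective sample size
#'
#' Autocorrelation-based ESS: autocorrelations are computed per chain on
#' centered draws, averaged across chains, and truncated by Geyer's initial
#' positive sequence (adjacent autocorrelation pairs are summed while the
#' pair sums stay positive). ESS is capped at the total draw count;
#' all-constant dimensions report ESS 1 with a `"degenerate"` attribute.
#'
#' @inheritParams split_rhat
#' @param max_lag largest autocorrelation lag considered.
#' @return numeric vector of ESS values per dimension, with attribute
#'   `degenerate` (logical).
#' @export
effective_sample_size <- function(draws, max_lag = 1000L) {
  x <- as_draws_array(draws)
  n_chains <- dim(x)[1L]
  n_iter <- dim(x)[2L]
  n_dim <- dim(x)[3L]
  if (n_iter < 10L) {
    cw_stop("effective sample size needs at least 10 iterations",
            "cw_validation_error")
  }
  lag_max <- min(as.integer(max_lag), n_iter - 1L)
  total <- n_chains * n_iter
  out <- numeric(n_dim)
  degen <- logical(n_dim)
  for (d in seq_len(n_dim)) {
    rho <- matrix(0, n_chains, lag_max + 1L)
    ok <- TRUE
    for (k in seq_len(n_chains)) {
      v <- x[k, , d]
      if (stats::var(v) <= 0 || !is.finite(stats::var(v))) {
        ok <- FALSE
        break
      }
      ac <- stats::acf(v, lag.max = lag_max, plot = FALSE,
                       demean = TRUE)$acf[, 1L, 1L]
      rho[k, ] <- ac
    }
    if (!ok) {
      out[d] <- 1
      degen[d] <- TRUE
      next
    }
    r <- colMeans(rho)
    # Geyer initial positive sequence on pair sums rho[2t] + rho[2t+1]
    tau <- 1
    t <- 1L
    while (t + 1L <= lag_max) {
      pair <- r[t + 1L] + r[t + 2L]
      if (pair <= 0) break
      tau <- tau + 2 * pair
      t <- t + 2L
    }
    out[d] <- min(total / tau, total)
  }
  attr(out, "degenerate") <- degen
  out
}

#' Per-dimension summary of a sample batch
#'
#' Deterministic table with mean, standard deviation, 2.5/50/97.5%
#' quantiles (linear interpolation), split R-hat, effective sample size,
#' and the mean acceptance rate.
#'
#' @param object a `"sample_batch"`.
#' @param ... unused.
#' @return a data frame with one row per original-space dimension.
#' @export
summary.sample_batch <- function(object, ...) {
  x <- object$draws
  n_dim <- dim(x)[3L]
  flat <- matrix(aperm(x, c(2L, 1L, 3L)), ncol = n_dim)
  qs <- t(apply(flat, 2L, stats::quantile, probs = c(0.025, 0.5, 0.975),
                type = 7L))
  rh <- tryCatch(suppressWarnings(split_rhat(x)),
                 error = function(e) rep(NA_real_, n_dim))
  es <- tryCatch(effective_sample_size(x),
                 error = function(e) rep(NA_real_, n_dim))
  data.frame(
    dimension = seq_len(n_dim),
    mean = colMeans(flat),
    sd = apply(flat, 2L, stats::sd),
    q2.5 = qs[, 1L],
    q50 = qs[, 2L],
    q97.5 = qs[, 3L],
    rhat = as.numeric(rh),
    ess = as.numeric(es),
    acceptance = mean(object$acceptance_rates)
  )
}
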