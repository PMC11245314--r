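#' Initialize a Markov chain on a sampling problem
#'
#' A chain bundles the problem, a proposal built from the registry, a
#' dedicated PCG64 random stream, the current (reduced-space) position with
#' its cached log-density, and bookkeeping counters. All mutable state
#' lives in the returned environment, so [checkpoint_chain()] can capture it
#' exactly.
#'
#' @param problem a [sampling_problem()].
#' @param proposal registered proposal name.
#' @param start strictly interior start (reduced coordinates); `NULL` uses
#'   the Chebyshev center jittered inside one tenth of the inscribed ball.
#' @param seed,stream_id RNG stream selectors (see [make_rng()]).
#' @param temperature positive tempering temperature (1 = cold chain).
#' @param proposal_params named list of extra proposal arguments.
#' @return an environment of class `"cw_chain"`.
#' @export
init_chain <- function(problem, proposal = "hit_and_run", start = NULL,
                       seed = 1, stream_id = 1, temperature = 1,
                       proposal_params = list()) {
  P <- problem$polytope
  rng <- make_rng(seed, stream_id)
  if (is.null(start)) {
    cc <- chebyshev_center(P)
    if (cc$radius <= 0) {
      cw_stop("polytope has empty interior; cannot start a chain",
              "cw_degenerate_error")
    }
    start <- jitter_start(cc, rng)
  }
  check_start(P, start)
  prop <- make_proposal(proposal, problem, start, proposal_params)
  ch <- new.env(parent = emptyenv())
  ch$problem <- problem
  ch$proposal <- prop
  ch$proposal_name <- proposal
  ch$proposal_params <- proposal_params
  ch$rng <- rng
  ch$position <- as.numeric(start)
  ch$logf <- eval_target(problem, ch$position)
  ch$temperature <- as.numeric(temperature)
  ch$step_count <- 0L
  ch$accepted <- 0L
  ch$stuck <- 0L
  class(ch) <- "cw_chain"
  ch
}

# uniform draw inside the ball of radius 0.1 * r around the center
jitter_start <- function(cc, rng) {
  n <- length(cc$center)
  d <- sphere_direction(rng, n)
  u <- rng_uniform(rng, 1L)
  cc$center + 0.1 * cc$radius * u^(1 / n) * d
}

#' Advance a chain by one Metropolis-Hastings step
#'
#' Asks the proposal for a candidate, rejects candidates outside the
#' polytope without evaluating the model, and otherwise accepts with log
#' probability `min(0, (f(y) - f(x)) / T + log_correction)`. The cached
#' log-density and the step count are updated either way, and the proposal's
#' adaptation hook is notified with the realized state.
#'
#' @param chain a [init_chain()] environment.
#' @return the chain, invisibly.
#' @export
metropolis_step <- function(chain) {
  pr <- chain$proposal$propose(chain$rng, chain$position)
  if (pr$stuck) {
    chain$stuck <- chain$stuck + 1L
  } else {
    y <- pr$point
    P <- chain$problem$polytope
    if (all(P$A %*% y - P$b <= 1e-9)) {
      logfy <- eval_target(chain$problem, y)
      loga <- (logfy - chain$logf) / chain$temperature + pr$log_correction
      if (loga >= 0 || log(rng_uniform(chain$rng, 1L)) < loga) {
        chain$position <- y
        chain$logf <- logfy
        chain$accepted <- chain$accepted + 1L
      }
    }
  }
  chain$proposal$advance(chain$position)
  chain$step_count <- chain$step_count + 1L
  invisible(chain)
}

#' Advance a chain and record thinned states
#'
#' Runs `n_records * record_every` Metropolis steps, recording the reduced
#' position after every `record_every`-th step.
#'
#' @param chain a [init_chain()] environment.
#' @param n_records number of states to record.
#' @param record_every thinning interval (>= 1).
#' @return numeric matrix (`n_records` x dimension), reduced coordinates.
#' @export
advance_chain <- function(chain, n_records, record_every = 1L) {
  n_records <- as.integer(n_records)
  record_every <- as.integer(record_every)
  out <- matrix(NA_real_, n_records, length(chain$position))
  for (j in seq_len(n_records)) {
    for (t in seq_len(record_every)) metropolis_step(chain)
    out[j, ] <- chain$position
  }
  out
}

#' Run independent Markov chains on a polytope-constrained target
#'
#' Advances `n_chains` logically independent chains (one PCG64 stream each,
#' derived from `seed`), records every `thinning`-th state, and returns the
#' draws mapped to original coordinates. Identical inputs give bit-identical
#' outputs regardless of scheduling, because determinism is defined per
#' (seed, stream).
#'
#' @param problem a [sampling_problem()].
#' @param proposal registered proposal name (see [proposal_names()]).
#' @param n_chains number of chains.
#' @param n_samples recorded draws per chain.
#' @param thinning record every `thinning`-th state.
#' @param seed integer seed; chain k uses stream k.
#' @param starts optional matrix (`n_chains` x dim) or list of start points
#'   in reduced coordinates; default jitters the Chebyshev center.
#' @param proposal_params named list of extra proposal arguments.
#' @return An object of class `"sample_batch"`: list with
#'   * `draws`: array (chains x iterations x original dimension),
#'   * `reduced`: array (chains x iterations x reduced dimension),
#'   * `acceptance_rates`: per-chain acceptance fractions,
#'   * `meta`: seeds, proposal, thinning, polytope label, burn-in length,
#'     stuck-step counts.
#' @examples
#' pb <- sampling_problem(hypercube(2))
#' sb <- sample_polytope(pb, n_chains = 2, n_samples = 50, seed = 1)
#' dim(sb$draws)
#' @export
sample_polytope <- function(problem, proposal = "hit_and_run", n_chains = 4L,
                            n_samples = 1000L, thinning = 1L, seed = 1,
                            starts = NULL, proposal_params = list()) {
  n_chains <- as.integer(n_chains)
  n_samples <- as.integer(n_samples)
  thinning <- as.integer(thinning)
  if (n_chains < 1L || n_samples < 1L || thinning < 1L) {
    cw_stop("n_chains, n_samples and thinning must be positive",
            "cw_validation_error")
  }
  P <- problem$polytope
  cc <- chebyshev_center(P) # feasibility gate before any stepping
  if (cc$radius <= 0) {
    cw_stop("polytope has empty interior", "cw_degenerate_error")
  }
  start_list <- normalize_starts(starts, n_chains, ncol(P$A))
  n_red <- ncol(P$A)
  n_full <- if (is.null(problem$transform)) n_red else
    nrow(problem$transform$basis)
  draws <- array(NA_real_, c(n_chains, n_samples, n_full))
  reduced <- array(NA_real_, c(n_chains, n_samples, n_red))
  acc <- numeric(n_chains)
  stuck <- integer(n_chains)
  burn_in <- 0L
  for (k in seq_len(n_chains)) {
    ch <- init_chain(problem, proposal = proposal, start = start_list[[k]],
                     seed = seed, stream_id = k,
                     proposal_params = proposal_params)
    red <- advance_chain(ch, n_samples, thinning)
    reduced[k, , ] <- red
    draws[k, , ] <- if (is.null(problem$transform)) red else
      map_back(problem$transform, red)
    acc[k] <- ch$accepted / ch$step_count
    stuck[k] <- ch$stuck
    burn_in <- max(burn_in, ch$proposal$burn_in)
  }
  structure(list(
    draws = draws,
    reduced = reduced,
    acceptance_rates = acc,
    meta = list(seed = seed, proposal = proposal,
                proposal_params = proposal_params, n_chains = n_chains,
                n_samples = n_samples, thinning = thinning,
                polytope_label = P$label,
                burn_in_draws = as.integer(ceiling(burn_in / thinning)),
                stuck_steps = stuck)
  ), class = "sample_batch")
}

normalize_starts <- function(starts, n_chains, n) {
  if (is.null(starts)) return(vector("list", n_chains))
  if (is.matrix(starts)) {
    cw_check_dim(nrow(starts) == n_chains && ncol(starts) == n,
                 "starts matrix must be n_chains x dimension")
    return(lapply(seq_len(n_chains), function(k) starts[k, ]))
  }
  if (is.list(starts)) {
    cw_check_dim(length(starts) == n_chains,
                 "need one start per chain")
    return(starts)
  }
  if (n_chains == 1L && is.numeric(starts)) return(list(starts))
  cw_stop("starts must be a matrix, list, or single numeric vector",
          "cw_validation_error")
}

#' @export
print.sample_batch <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf(paste0("<sample batch: %d chain(s) x %d draws x %d dim(s), ",
                     "proposal '%s', mean acceptance %.3f>\n"),
              d[1], d[2], d[3], x$meta$proposal,
              mean(x$acceptance_rates)))
  invisible(x)
}

#' Tune a proposal's step size toward a target acceptance rate
#'
#' Robbins-Monro stochastic approximation on the log step size: after each
#' batch of `batch_size` steps the update is
#' `log s <- log s + gamma_k (rate_k - target_rate)` with
#' `gamma_k = 2 / (k + 1)`. The default target 0.234 is the classical
#' random-walk optimum.
#'
#' @param problem a [sampling_problem()].
#' @param proposal registered name of a tunable proposal (one exposing
#'   `step_size`).
#' @param target_rate desired acceptance rate, strictly inside (0, 1).
#' @param n_tuning total tuning steps.
#' @param seed RNG seed.
#' @param batch_size steps per Robbins-Monro update.
#' @param proposal_params extra proposal arguments (e.g. initial
#'   `step_size`).
#' @return list with `step_size`, `achieved_rate` (last batch), and a
#'   `trace` data frame of per-batch rates and step sizes.
#' @export
tune_step_size <- function(problem, proposal = "gaussian_hit_and_run",
                           target_rate = 0.234, n_tuning = 5000L, seed = 1,
                           batch_size = 100L, proposal_params = list()) {
  if (!is.numeric(target_rate) || target_rate <= 0 || target_rate >= 1) {
    cw_stop("target_rate must lie strictly inside (0, 1)",
            "cw_validation_error")
  }
  ch <- init_chain(problem, proposal = proposal, seed = seed, stream_id = 1L,
                   proposal_params = proposal_params)
  if (is.null(ch$proposal$step_size)) {
    cw_stop(sprintf("proposal '%s' has no step size and cannot be tuned",
                    proposal), "cw_not_tunable_error")
  }
  n_batches <- max(1L, as.integer(n_tuning) %/% as.integer(batch_size))
  trace <- data.frame(batch = seq_len(n_batches), rate = NA_real_,
                      step_size = NA_real_)
  rate <- NA_real_
  for (k in seq_len(n_batches)) {
    before <- ch$accepted
    for (t in seq_len(batch_size)) metropolis_step(ch)
    rate <- (ch$accepted - before) / batch_size
    gamma_k <- 2 / (k + 1)
    s <- ch$proposal$step_size()
    ch$proposal$set_step_size(exp(log(s) + gamma_k * (rate - target_rate)))
    trace$rate[k] <- rate
    trace$step_size[k] <- ch$proposal$step_size()
  }
  list(step_size = ch$proposal$step_size(), achieved_rate = rate,
       trace = trace)
}

#' Parallel tempering over a temperature ladder
#'
#' Runs one chain per temperature, all on the SAME polytope (the support is
#' never tempered -- the hottest chain stays polytope-confined), with chain
#' k targeting \eqn{f / T_k}. Every `swap_interval` sweeps, adjacent pairs
#' (alternating even/odd offsets between swap rounds) exchange states with
#' log acceptance \eqn{(1/T_i - 1/T_j)(f(\theta_j) - f(\theta_i))}. Only
#' the cold chain's draws are returned, together with per-pair swap
#' statistics. A one-temperature ladder reproduces [sample_polytope()] with
#' one chain exactly.
#'
#' @param problem a [sampling_problem()].
#' @param proposal registered proposal name.
#' @param temperatures ladder starting at 1, non-decreasing.
#' @param n_samples recorded cold-chain draws.
#' @param swap_interval sweeps between swap rounds.
#' @param thinning record every `thinning`-th sweep.
#' @param seed integer seed; temperature k uses stream k, swaps use stream
#'   `K + 1`.
#' @param starts optional start points, as in [sample_polytope()] (one per
#'   temperature).
#' @param proposal_params extra proposal arguments.
#' @return a `"sample_batch"` for the cold chain with an extra element
#'   `swap_stats`: data frame of proposed/accepted swap counts per adjacent
#'   pair.
#' @export
parallel_tempering <- function(problem, proposal = "gaussian_hit_and_run",
                               temperatures = c(1, 4, 16), n_samples = 1000L,
                               swap_interval = 10L, thinning = 1L, seed = 1,
                               starts = NULL, proposal_params = list()) {
  temperatures <- as.numeric(temperatures)
  if (length(temperatures) < 1L || temperatures[1L] != 1 ||
      any(temperatures <= 0) || any(diff(temperatures) < 0)) {
    cw_stop("temperatures must start at 1, be positive and non-decreasing",
            "cw_validation_error")
  }
  K <- length(temperatures)
  n_samples <- as.integer(n_samples)
  thinning <- as.integer(thinning)
  swap_interval <- as.integer(swap_interval)
  if (n_samples < 1L || thinning < 1L || swap_interval < 1L) {
    cw_stop("n_samples, thinning and swap_interval must be positive",
            "cw_validation_error")
  }
  P <- problem$polytope
  cc <- chebyshev_center(P)
  if (cc$radius <= 0) {
    cw_stop("polytope has empty interior", "cw_degenerate_error")
  }
  start_list <- normalize_starts(starts, K, ncol(P$A))
  chains <- lapply(seq_len(K), function(k) {
    init_chain(problem, proposal = proposal, start = start_list[[k]],
               seed = seed, stream_id = k, temperature = temperatures[k],
               proposal_params = proposal_params)
  })
  swap_rng <- make_rng(seed, K + 1L)
  proposed <- integer(max(K - 1L, 1L))
  accepted <- integer(max(K - 1L, 1L))
  swap_round <- 0L
  n_red <- ncol(P$A)
  red <- matrix(NA_real_, n_samples, n_red)
  rec <- 0L
  total_sweeps <- n_samples * thinning
  for (sweep in seq_len(total_sweeps)) {
    for (k in seq_len(K)) metropolis_step(chains[[k]])
    if (K > 1L && sweep %% swap_interval == 0L) {
      swap_round <- swap_round + 1L
      first <- 1L + (swap_round - 1L) %% 2L
      pairs <- if (first <= K - 1L) seq(first, K - 1L, by = 2L) else integer(0)
      for (i in pairs) {
        j <- i + 1L
        proposed[i] <- proposed[i] + 1L
        delta <- (1 / temperatures[i] - 1 / temperatures[j]) *
          (chains[[j]]$logf - chains[[i]]$logf)
        ok <- delta >= 0 || log(rng_uniform(swap_rng, 1L)) < delta
        if (ok) {
          accepted[i] <- accepted[i] + 1L
          pos_i <- chains[[i]]$position
          logf_i <- chains[[i]]$logf
          chains[[i]]$position <- chains[[j]]$position
          chains[[i]]$logf <- chains[[j]]$logf
          chains[[j]]$position <- pos_i
          chains[[j]]$logf <- logf_i
        }
      }
    }
    if (sweep %% thinning == 0L) {
      rec <- rec + 1L
      red[rec, ] <- chains[[1L]]$position
    }
  }
  n_full <- if (is.null(problem$transform)) n_red else
    nrow(problem$transform$basis)
  draws <- array(NA_real_, c(1L, n_samples, n_full))
  reduced <- array(NA_real_, c(1L, n_samples, n_red))
  reduced[1L, , ] <- red
  draws[1L, , ] <- if (is.null(problem$transform)) red else
    map_back(problem$transform, red)
  swap_stats <- if (K > 1L) {
    data.frame(pair = paste(seq_len(K - 1L), 2:K, sep = "-"),
               proposed = proposed, accepted = accepted,
               rate = ifelse(proposed > 0, accepted / proposed, NA_real_))
  } else {
    data.frame(pair = character(), proposed = integer(),
               accepted = integer(), rate = numeric())
  }
  structure(list(
    draws = draws,
    reduced = reduced,
    acceptance_rates = chains[[1L]]$accepted / chains[[1L]]$step_count,
    swap_stats = swap_stats,
    meta = list(seed = seed, proposal = proposal,
                proposal_params = proposal_params,
                temperatures = temperatures, swap_interval = swap_interval,
                n_samples = n_samples, thinning = thinning,
                polytope_label = P$label,
                burn_in_draws = as.integer(
                  ceiling(chains[[1L]]$proposal$burn_in / thinning)),
                stuck_steps = vapply(chains, function(c) c$stuck, integer(1)))
  ), class = "sample_batch")
}
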