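#' Create a reproducible random-number stream
#'
#' Streams are permuted congruential generators (PCG64, XSL-RR 128/64) with
#' 128-bit state and period \eqn{2^{128}}. Distinct `stream_id`s select
#' statistically independent sequences from the same seed, which is how
#' parallel chains obtain independent randomness. Normal deviates are
#' produced by inverse-CDF transform of the uniform stream, so the full
#' generator state is the 256-bit (state, increment) pair and serializes
#' exactly.
#'
#' @param seed nonnegative integer seed.
#' @param stream_id nonnegative integer stream selector.
#' @return An object of class `"cw_rng"`.
#' @examples
#' r <- make_rng(1, 0)
#' rng_uniform(r, 3)
#' @export
make_rng <- function(seed, stream_id = 0) {
  structure(list(ptr = .pcg64_new(as.double(seed), as.double(stream_id)),
                 seed = seed, stream_id = stream_id),
            class = "cw_rng")
}

#' Uniform(0, 1) draws from a stream
#' @param rng a [make_rng()] stream.
#' @param n number of draws.
#' @return numeric vector in (0, 1).
#' @export
rng_uniform <- function(rng, n = 1L) {
  .pcg64_runif(rng$ptr, as.integer(n))
}

#' Standard normal draws from a stream
#' @inheritParams rng_uniform
#' @return numeric vector.
#' @export
rng_normal <- function(rng, n = 1L) {
  stats::qnorm(.pcg64_runif(rng$ptr, as.integer(n)))
}

#' Uniform integer draws in 1..k from a stream
#' @inheritParams rng_uniform
#' @param k upper bound (inclusive).
#' @return integer vector.
#' @export
rng_integer <- function(rng, n = 1L, k) {
  pmin(floor(.pcg64_runif(rng$ptr, as.integer(n)) * k) + 1L, k)
}

#' Capture or restore the exact state of a stream
#'
#' `rng_state` returns the generator state as four 16-digit hex words
#' (state hi/lo, increment hi/lo); `rng_from_state` rebuilds a stream that
#' continues the sequence bit-for-bit.
#'
#' @param rng a [make_rng()] stream.
#' @return character vector of length 4.
#' @export
rng_state <- function(rng) {
  .pcg64_get_state(rng$ptr)
}

#' @rdname rng_state
#' @param state character vector of length 4 as returned by `rng_state`.
#' @export
rng_from_state <- function(state) {
  r <- make_rng(0, 0)
  .pcg64_set_state(r$ptr, state)
  r
}
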