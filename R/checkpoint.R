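# Checkpointing: a chain's complete mutable state -- position, cached
# log-density, proposal configuration and internal adaptation state, RNG
# state, counters, temperature -- serializes to a self-describing blob with
# a schema tag and an Adler-32 checksum. Restoring and continuing
# reproduces the uninterrupted draw stream bit-for-bit.

CHECKPOINT_SCHEMA <- "chordwalk-chain/1"

adler32 <- function(raw) {
  d <- as.integer(raw)
  if (length(d) == 0L) return(1)
  # process in blocks so the running sums stay inside double precision
  a <- 1
  b <- 0
  block <- 4096L
  for (start in seq(1L, length(d), by = block)) {
    chunk <- d[start:min(start + block - 1L, length(d))]
    ca <- a + cumsum(chunk)
    b <- (b + sum(ca)) %% 65521
    a <- ca[length(ca)] %% 65521
  }
  b * 65536 + a
}

#' Snapshot of a chain's state
#'
#' Returns the serializable view of a chain: reduced-space position, cached
#' log-density, proposal name/parameters/internal state, RNG state, step
#' count and temperature.
#'
#' @param chain a [init_chain()] environment.
#' @return a named list.
#' @export
chain_state <- function(chain) {
  list(schema = CHECKPOINT_SCHEMA,
       position = chain$position,
       logf = chain$logf,
       proposal_name = chain$proposal_name,
       proposal_params = chain$proposal_params,
       proposal_internal = chain$proposal$snapshot(),
       rng_state = rng_state(chain$rng),
       step_count = chain$step_count,
       accepted = chain$accepted,
       stuck = chain$stuck,
       temperature = chain$temperature)
}

#' Checkpoint a chain to an opaque blob
#'
#' @param chain a [init_chain()] environment.
#' @return raw vector (versioned, checksummed).
#' @export
checkpoint_chain <- function(chain) {
  payload <- serialize(chain_state(chain), NULL)
  serialize(list(magic = "chordwalk-checkpoint", version = 1L,
                 checksum = adler32(payload), payload = payload), NULL)
}

#' Restore a chain from a checkpoint blob
#'
#' Verifies the schema tag and checksum, rebuilds the proposal from the
#' registry and the RNG from its serialized state, and revalidates the
#' cached log-density against a fresh model evaluation (tolerance 1e-12).
#' Continuing the restored chain reproduces the uninterrupted run exactly.
#'
#' @param blob raw vector from [checkpoint_chain()].
#' @param problem the [sampling_problem()] the chain was running on.
#' @return an environment of class `"cw_chain"`.
#' @export
restore_chain <- function(blob, problem) {
  outer <- tryCatch(unserialize(blob), error = function(e) NULL)
  if (!is.list(outer) || !identical(outer$magic, "chordwalk-checkpoint")) {
    cw_stop("not a chain checkpoint (bad magic)", "cw_integrity_error")
  }
  if (!identical(outer$version, 1L)) {
    cw_stop(sprintf("unsupported checkpoint version %s", outer$version),
            "cw_integrity_error")
  }
  if (!identical(adler32(outer$payload), outer$checksum)) {
    cw_stop("checkpoint checksum mismatch: blob is corrupted",
            "cw_integrity_error")
  }
  st <- unserialize(outer$payload)
  if (!identical(st$schema, CHECKPOINT_SCHEMA)) {
    cw_stop(sprintf("checkpoint schema '%s' does not match '%s'",
                    st$schema, CHECKPOINT_SCHEMA), "cw_integrity_error")
  }
  prop <- make_proposal(st$proposal_name, problem, st$position,
                        st$proposal_params)
  prop$restore(st$proposal_internal)
  ch <- new.env(parent = emptyenv())
  ch$problem <- problem
  ch$proposal <- prop
  ch$proposal_name <- st$proposal_name
  ch$proposal_params <- st$proposal_params
  ch$rng <- rng_from_state(st$rng_state)
  ch$position <- st$position
  ch$logf <- st$logf
  ch$temperature <- st$temperature
  ch$step_count <- st$step_count
  ch$accepted <- st$accepted
  ch$stuck <- st$stuck
  class(ch) <- "cw_chain"
  check <- eval_target(problem, ch$position)
  if (abs(check - ch$logf) > 1e-12 * (1 + abs(check))) {
    cw_stop("restored log-density disagrees with a fresh model evaluation",
            "cw_integrity_error")
  }
  ch
}
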