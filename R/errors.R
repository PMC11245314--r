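# Classed error conditions so callers (and the CLI) can branch on failure kind.

cw_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "cw_error"), call = call))
}

cw_check_dim <- function(ok, msg) {
  if (!ok) cw_stop(msg, "cw_dim_error")
  invisible(TRUE)
}
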