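# Classed error conditions used across the package. Every user-facing
# failure carries both a specific class (e.g. "anchorprobe_value_error")
# and the umbrella class "anchorprobe_error" so callers can catch either.

ap_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("anchorprobe_", class),
                                     "anchorprobe_error")))
}

ap_check <- function(cond, msg, class) {
  if (!isTRUE(cond)) ap_stop(msg, class)
  invisible(TRUE)
}
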