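## Classed conditions so callers (and tests) can distinguish failure modes.

abort_qm <- function(message, class, call. = FALSE) {
  stop(structure(
    class = c(class, "qm_error", "error", "condition"),
    list(message = message, call = if (call.) sys.call(-1) else NULL)
  ))
}

warn_qm <- function(message, class) {
  warning(structure(
    class = c(class, "qm_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}
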