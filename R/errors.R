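# Structured conditions. Every error raised by the package carries class
# c("<specific>", "cysanchor_error") so callers (and the CLI) can dispatch on it.

cys_abort <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "cysanchor_error")))
}

cys_warn <- function(class, msg, ...) {
  warning(warningCondition(msg, ..., class = c(class, "cysanchor_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
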