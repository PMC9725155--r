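# Classed conditions used across the package. Every error signalled by
# audioloc carries the "audioloc_error" class plus one of the specific
# classes below, so callers can distinguish e.g. malformed files
# ("audioloc_format_error") from semantically invalid values
# ("audioloc_validation_error").

al_stop <- function(msg, class = "validation", call = sys.call(-1)) {
  stop(errorCondition(
    msg,
    class = c(paste0("audioloc_", class, "_error"), "audioloc_error")
  ))
}

al_warn <- function(msg, class = "general") {
  warning(warningCondition(
    msg,
    class = c(paste0("audioloc_", class, "_warning"), "audioloc_warning")
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
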