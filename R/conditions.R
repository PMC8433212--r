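# Classed error conditions so callers can distinguish failure modes
# programmatically (tryCatch on the class, not on message text).

ng_error <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "ng_error", "error")))
}

ng_stopifnot <- function(cond, message, class = "ng_invalid_argument") {
  if (!isTRUE(cond)) ng_error(message, class)
  invisible(TRUE)
}
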