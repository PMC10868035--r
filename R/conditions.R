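# Classed conditions so callers can distinguish bad arguments from degenerate
# data without matching on message text.

cond_stop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "ltrEHR_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_invalid <- function(msg, call = sys.call(-1)) {
  cond_stop("ltrEHR_invalid_argument", msg, call)
}

stop_degenerate <- function(msg, call = sys.call(-1)) {
  cond_stop("ltrEHR_degenerate_input", msg, call)
}

stop_missing_code <- function(codes, call = sys.call(-1)) {
  cond_stop(
    "ltrEHR_missing_code",
    sprintf(
      "code(s) not in the embedding vocabulary: %s",
      paste(codes, collapse = ", ")
    ),
    call
  )
}
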