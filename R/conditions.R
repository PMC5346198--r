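# Typed condition constructors. Every error raised by the package carries a
# subclass of "biocurate_error" so callers can handle failure modes
# programmatically rather than matching message strings.

stop_biocurate <- function(subclass, message, ..., call = sys.call(-1)) {
  cond <- structure(
    class = c(subclass, "biocurate_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

# Invalid query: carries the full violation list.
stop_validation <- function(violations) {
  stop_biocurate(
    "biocurate_validation_error",
    paste0(
      "invalid query: ",
      paste(violations, collapse = "; ")
    ),
    violations = violations,
    call = sys.call(-2)
  )
}

# Transport / retrieval failure: carries the URL that failed.
stop_retrieval <- function(message, url) {
  stop_biocurate(
    "biocurate_retrieval_error",
    paste0(message, " [", url, "]"),
    url = url,
    call = sys.call(-2)
  )
}

stop_parse <- function(message, ...) {
  stop_biocurate("biocurate_parse_error", message, ..., call = sys.call(-2))
}

stop_schema <- function(message, ...) {
  stop_biocurate("biocurate_schema_error", message, ..., call = sys.call(-2))
}
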