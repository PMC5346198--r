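# Transports. The core never opens a network connection itself: a transport
# is any function that maps a structured_request to raw payload bytes, so the
# live HTTP transport and the in-memory fixture transport are interchangeable.

#' Execute a structured request through a transport
#'
#' Returns the payload bytes unmodified. Any transport failure (unreachable
#' host, non-success status, empty payload, unmapped fixture URL) surfaces as
#' a retrieval error of class `biocurate_retrieval_error` carrying the URL.
#'
#' @param request a [structured_request()].
#' @param transport a transport function, e.g. [http_transport()] or
#'   [fixture_transport()].
#' @return Raw vector of payload bytes.
#' @export
execute_request <- function(request, transport) {
  stopifnot(inherits(request, "structured_request"), is.function(transport))
  payload <- tryCatch(
    transport(request),
    biocurate_retrieval_error = function(e) stop(e),
    error = function(e) stop_retrieval(
      paste0("transport failure: ", conditionMessage(e)), request$url
    )
  )
  if (!is.raw(payload))
    stop_retrieval("transport returned a non-raw payload", request$url)
  if (length(payload) == 0L)
    stop_retrieval("empty payload", request$url)
  payload
}

#' Live HTTP transport
#'
#' Fetches a request over HTTP(S) using the curl package. Only needed for
#' live curation; the test suite and examples run entirely on
#' [fixture_transport()].
#'
#' @return A transport function.
#' @export
http_transport <- function() {
  function(request) {
    if (!requireNamespace("curl", quietly = TRUE))
      stop_retrieval("the 'curl' package is required for live retrieval",
                     request$url)
    res <- tryCatch(curl::curl_fetch_memory(request$url),
                    error = function(e) stop_retrieval(
                      paste0("network failure: ", conditionMessage(e)),
                      request$url
                    ))
    if (res$status_code >= 300L)
      stop_retrieval(paste0("HTTP status ", res$status_code), request$url)
    res$content
  }
}

#' In-memory fixture transport
#'
#' Builds a transport resolving exactly the mapped URLs; any other URL yields
#' a retrieval error. Map values may be raw vectors, character strings, or
#' [fixture_spec()] objects (rendered once, at construction, so repeated
#' executions return identical bytes).
#'
#' @param mapping named list, names are absolute URLs.
#' @return A transport function.
#' @examples
#' spec <- fixture_spec("pubmed-xml", demo_articles())
#' tr <- fixture_transport(list("http://example.org/efetch" = spec))
#' doc <- execute_request(structured_request("http://example.org/efetch"), tr)
#' length(parse_pubmed_articles(doc))
#' @export
fixture_transport <- function(mapping = list()) {
  stopifnot(is.list(mapping))
  if (length(mapping) && is.null(names(mapping)))
    stop_schema("fixture transport mapping must be named by URL")
  payloads <- lapply(mapping, function(x) {
    if (inherits(x, "fixture_spec")) generate_fixture(x)
    else if (is.character(x)) charToRaw(paste(x, collapse = "\n"))
    else if (is.raw(x)) x
    else stop_schema("fixture mapping values must be raw, character or fixture_spec")
  })
  function(request) {
    hit <- payloads[[request$url]]
    if (is.null(hit))
      stop_retrieval("no fixture mapped for URL", request$url)
    hit
  }
}
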