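# Structured URL interfaces: deterministic translation of query objects into
# the fixed URL syntaxes of the supported repositories.

#' Structured request
#'
#' A structured request pairs an absolute URL with the payload type the caller
#' expects back. Requests are inert values; [execute_request()] runs them
#' through a transport.
#'
#' @param url absolute URL string.
#' @param expected_payload `"xml"` or `"html"`.
#' @return An object of class `structured_request`.
#' @export
structured_request <- function(url, expected_payload = c("xml", "html")) {
  expected_payload <- match.arg(expected_payload)
  stopifnot(is.character(url), length(url) == 1L,
            grepl("^[a-zA-Z][a-zA-Z0-9+.-]*://", url))
  structure(list(url = url, expected_payload = expected_payload),
            class = "structured_request")
}

#' @export
print.structured_request <- function(x, ...) {
  cat("<structured_request>", toupper(x$expected_payload), "\n ", x$url, "\n")
  invisible(x)
}

# Entrez value encoding: spaces become "+"; brackets and separators are
# emitted literally so generated URLs match the eUtils house style.
encode_entrez <- function(x) gsub(" ", "+", x, fixed = TRUE)

#' Translate a query into an Entrez eUtils URL
#'
#' Fetch queries map onto `efetch.fcgi` (`db`, comma-joined `id`, `retmode`);
#' search queries map onto `esearch.fcgi` (`db`, `term`, `retmode`,
#' `rettype=uilist`). In the `term` expression, field constraints render as
#' `value[tag]` and precede the free-text terms; constraints are joined by
#' `+`, terms by `+AND+` (or `+OR+` for an OR query). The translation is
#' deterministic: equal queries yield byte-identical URLs.
#'
#' @param q a valid query targeting an Entrez database (e.g. `"PUBMED"`).
#' @param registry repository registry; supplies the eUtils base URL.
#' @param field_table search-field vocabulary from [search_field_table()].
#' @return A [structured_request()] expecting XML.
#' @examples
#' q <- add_id(add_id(query("PUBMED", "FETCH"), "23371018"), "10227670")
#' build_entrez_url(q)$url
#' @export
build_entrez_url <- function(q, registry = default_registry(),
                             field_table = search_field_table()) {
  violations <- validate_query(q, registry)
  if (length(violations)) stop_validation(violations)
  entry <- registry_entry(registry, q$database)
  if (entry$interface != "entrez")
    stop_biocurate(
      "biocurate_unsupported_repository",
      paste0("repository '", q$database, "' has no Entrez interface")
    )
  base <- entry$endpoint
  if (q$search_type == "FETCH") {
    url <- paste0(base, "/efetch.fcgi?db=", entry$wire,
                  "&id=", paste(q$ids, collapse = ","),
                  "&retmode=xml")
  } else {
    parts <- character()
    if (nrow(q$fields)) {
      tags <- field_table[q$fields$field]
      if (anyNA(tags))
        stop_schema(paste0("unknown search field: ",
                           paste(q$fields$field[is.na(tags)], collapse = ", ")))
      parts <- sprintf("%s[%s]", encode_entrez(q$fields$value), tags)
    }
    if (length(q$terms)) {
      joined <- paste(encode_entrez(q$terms),
                      collapse = paste0("+", q$connector, "+"))
      parts <- c(parts, joined)
    }
    url <- paste0(base, "/esearch.fcgi?db=", entry$wire,
                  "&term=", paste(parts, collapse = "+"),
                  "&retmode=xml&rettype=uilist")
  }
  structured_request(url, "xml")
}

#' Recover a query from a generated Entrez URL
#'
#' Inverse of [build_entrez_url()] for round-trip checking: parses the query
#' string of a generated eUtils URL back into database wire name, search
#' type, ids, terms, field constraints and connector. Terms whose values
#' contain encoded spaces are not disambiguated (the `+` encoding is lossy by
#' construction).
#'
#' @param url a URL produced by [build_entrez_url()].
#' @param field_table search-field vocabulary used to invert the field tags.
#' @return A list with elements `db`, `search_type`, `ids`, `terms`,
#'   `fields`, `connector`.
#' @export
parse_entrez_url <- function(url, field_table = search_field_table()) {
  path <- sub("\\?.*$", "", url)
  qs <- sub("^[^?]*\\?", "", url)
  kv <- strsplit(strsplit(qs, "&", fixed = TRUE)[[1]], "=", fixed = TRUE)
  params <- setNames(
    vapply(kv, function(p) paste(p[-1], collapse = "="), character(1)),
    vapply(kv, `[[`, character(1), 1L)
  )
  out <- list(db = unname(params[["db"]]),
              ids = character(), terms = character(),
              fields = data.frame(field = character(), value = character(),
                                  stringsAsFactors = FALSE),
              connector = "AND")
  if (grepl("efetch.fcgi", path, fixed = TRUE)) {
    out$search_type <- "FETCH"
    out$ids <- strsplit(params[["id"]], ",", fixed = TRUE)[[1]]
  } else if (grepl("esearch.fcgi", path, fixed = TRUE)) {
    out$search_type <- "SEARCH"
    tokens <- strsplit(params[["term"]], "+", fixed = TRUE)[[1]]
    is_field <- grepl("^.+\\[[^][]+\\]$", tokens)
    n_field <- match(FALSE, is_field, nomatch = length(tokens) + 1L) - 1L
    if (n_field > 0L) {
      ftok <- tokens[seq_len(n_field)]
      tags <- sub("^.*\\[", "", sub("\\]$", "", ftok))
      vals <- sub("\\[[^][]+\\]$", "", ftok)
      names_by_tag <- setNames(names(field_table), field_table)
      out$fields <- data.frame(field = unname(names_by_tag[tags]),
                               value = vals, stringsAsFactors = FALSE)
    }
    rest <- tokens[seq_along(tokens) > n_field]
    if (length(rest)) {
      conn <- rest[rest %in% c("AND", "OR")]
      if (length(conn)) out$connector <- conn[[1]]
      out$terms <- rest[!(rest %in% c("AND", "OR"))]
    }
  } else {
    stop_parse(paste0("not an eUtils search/fetch URL: ", url))
  }
  out
}

#' Translate a query into a MalaCards search URL
#'
#' The MalaCards endpoint template (a registry configuration entry, since the
#' service publishes no formal API grammar) carries a `{term}` placeholder
#' substituted with the percent-encoded first search term.
#'
#' @inheritParams build_entrez_url
#' @return A [structured_request()] expecting HTML.
#' @examples
#' build_malacards_url(add_term(query("MALA_CARDS"), "aneurysm"))$url
#' @export
build_malacards_url <- function(q, registry = default_registry()) {
  violations <- validate_query(q, registry)
  if (length(violations)) stop_validation(violations)
  entry <- registry_entry(registry, q$database)
  if (entry$interface != "malacards")
    stop_biocurate("biocurate_unsupported_repository",
                   paste0("repository '", q$database, "' is not MalaCards"))
  if (length(q$terms) == 0L)
    stop_validation("MalaCards search requires at least one term")
  term <- URLencode(q$terms[[1]], reserved = TRUE)
  structured_request(sub("{term}", term, entry$endpoint, fixed = TRUE), "html")
}

#' Translate a query into a BioModels record request
#'
#' Fetch queries retrieve the XML record of a model accession
#' (`BIOMD` + 10 digits); search queries substitute the first term into the
#' repository's search template.
#'
#' @inheritParams build_entrez_url
#' @return A [structured_request()] expecting XML.
#' @examples
#' q <- add_id(query("BIOMODELS", "FETCH"), "BIOMD0000000058")
#' build_biomodels_request(q)$url
#' @export
build_biomodels_request <- function(q, registry = default_registry()) {
  violations <- validate_query(q, registry)
  if (length(violations)) stop_validation(violations)
  entry <- registry_entry(registry, q$database)
  if (entry$interface != "biomodels")
    stop_biocurate("biocurate_unsupported_repository",
                   paste0("repository '", q$database, "' is not BioModels"))
  if (length(q$ids)) {
    id <- q$ids[[1]]
    if (!grepl("^BIOMD[0-9]{10}$", id))
      stop_biocurate("biocurate_malformed_id",
                     paste0("'", id, "' is not a BioModels accession ",
                            "(expected BIOMD followed by 10 digits)"))
    return(structured_request(sub("{id}", id, entry$endpoint, fixed = TRUE),
                              "xml"))
  }
  if (length(q$terms)) {
    cfg <- read_endpoint_config()
    term <- URLencode(q$terms[[1]], reserved = TRUE)
    return(structured_request(
      sub("{term}", term, cfg[["BIOMODELS_SEARCH"]], fixed = TRUE), "xml"
    ))
  }
  stop_validation("BioModels query requires a model id or a search term")
}
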