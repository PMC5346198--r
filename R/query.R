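#' Build a repository query
#'
#' A query object captures a search intent declaratively: which repository to
#' target, whether to search (term-based discovery of record identifiers) or
#' fetch (retrieval of full records for known identifiers), the free-text
#' terms, the field-constrained terms, and the identifiers. Queries are plain
#' values: the `add_*` helpers return a modified copy and never mutate their
#' argument.
#'
#' @param database symbolic repository name, one of the entries of
#'   [default_registry()] (e.g. `"PUBMED"`, `"MALA_CARDS"`).
#' @param type `"SEARCH"` or `"FETCH"`.
#' @param connector logical relation applied between free-text terms,
#'   `"AND"` (default) or `"OR"`.
#' @return An object of class `biocurate_query`.
#' @examples
#' q <- query("PUBMED", type = "FETCH")
#' q <- add_id(q, "23371018")
#' q <- add_id(q, "10227670")
#' validate_query(q)
#' @export
query <- function(database, type = c("SEARCH", "FETCH"),
                  connector = c("AND", "OR")) {
  type <- match.arg(toupper(type), c("SEARCH", "FETCH"))
  connector <- match.arg(toupper(connector), c("AND", "OR"))
  structure(
    list(
      database = toupper(database),
      search_type = type,
      terms = character(),
      ids = character(),
      fields = data.frame(field = character(), value = character(),
                          stringsAsFactors = FALSE),
      connector = connector
    ),
    class = "biocurate_query"
  )
}

#' @rdname query
#' @param q a query object.
#' @param term free-text search term.
#' @export
add_term <- function(q, term) {
  stopifnot(inherits(q, "biocurate_query"), is.character(term), length(term) == 1L)
  q$terms <- c(q$terms, term)
  q
}

#' @rdname query
#' @export
remove_term <- function(q, term) {
  stopifnot(inherits(q, "biocurate_query"))
  hit <- which(q$terms == term)
  if (length(hit)) q$terms <- q$terms[-hit[length(hit)]]
  q
}

#' @rdname query
#' @param id record identifier (e.g. a PMID or a BioModels accession).
#' @export
add_id <- function(q, id) {
  stopifnot(inherits(q, "biocurate_query"), is.character(id), length(id) == 1L)
  q$ids <- c(q$ids, id)
  q
}

#' @rdname query
#' @param field symbolic search-field name from [search_field_table()].
#' @param value value the field is constrained to.
#' @export
add_field <- function(q, field, value) {
  stopifnot(inherits(q, "biocurate_query"),
            is.character(field), length(field) == 1L,
            is.character(value), length(value) == 1L)
  q$fields <- rbind(q$fields, data.frame(field = toupper(field), value = value,
                                         stringsAsFactors = FALSE))
  q
}

#' Validate a query against its structural invariants
#'
#' Violations are returned as data, not raised: an empty character vector
#' means the query is valid. A fetch query must carry at least one
#' identifier and no terms or field constraints; a search query must carry at
#' least one term or field constraint; identifiers must be non-empty and
#' unique.
#'
#' @param q a query object.
#' @param registry repository registry used to check the database name;
#'   `NULL` skips that check.
#' @return Character vector of violation descriptions (empty when valid).
#' @export
validate_query <- function(q, registry = default_registry()) {
  stopifnot(inherits(q, "biocurate_query"))
  v <- character()
  if (!is.null(registry) && !(q$database %in% registry$name))
    v <- c(v, paste0("unknown database '", q$database, "'"))
  if (q$search_type == "FETCH") {
    if (length(q$ids) == 0L)
      v <- c(v, "fetch query must carry at least one id")
    if (length(q$terms) > 0L || nrow(q$fields) > 0L)
      v <- c(v, "fetch query must not carry terms or field constraints")
  } else {
    if (length(q$terms) == 0L && nrow(q$fields) == 0L)
      v <- c(v, "search query must carry at least one term or field constraint")
  }
  if (anyNA(q$ids) || any(!nzchar(q$ids[!is.na(q$ids)])))
    v <- c(v, "ids must be non-empty strings")
  if (anyDuplicated(q$ids))
    v <- c(v, "ids must not contain duplicates")
  v
}

#' @export
print.biocurate_query <- function(x, ...) {
  cat("<query>", x$search_type, "on", x$database, "\n")
  if (length(x$terms))
    cat("  terms: ", paste(x$terms, collapse = paste0(" ", x$connector, " ")), "\n", sep = "")
  if (nrow(x$fields))
    cat("  fields: ",
        paste(sprintf("%s=%s", x$fields$field, x$fields$value), collapse = ", "),
        "\n", sep = "")
  if (length(x$ids))
    cat("  ids: ", paste(x$ids, collapse = ", "), "\n", sep = "")
  invisible(x)
}
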