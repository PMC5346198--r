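#' Repository registry and controlled vocabularies
#'
#' The database repository is the table of data sources a query may target.
#' Each entry has a symbolic name (used in code), a wire name (used inside
#' generated URLs), an access mode, and the interface family that knows how to
#' build its requests. The registry is ordinary data and therefore
#' user-extensible with [register_database()].
#'
#' @param config named character vector of endpoint templates, as returned by
#'   [read_endpoint_config()]. Defaults to the templates shipped with the
#'   package.
#' @return A data frame with columns `name`, `wire`, `access`, `interface`
#'   and `endpoint`.
#' @examples
#' default_registry()
#' @export
default_registry <- function(config = read_endpoint_config()) {
  reg <- data.frame(
    name = c("PUBMED", "PMC", "MALA_CARDS", "BIOMODELS", "ANEURISK_LOCAL"),
    wire = c("pubmed", "pmc", "malacards", "biomodels", "aneurisk"),
    access = c(rep("structured-url", 4L), "local-structured-information"),
    interface = c("entrez", "entrez", "malacards", "biomodels", "local"),
    endpoint = NA_character_,
    stringsAsFactors = FALSE
  )
  reg$endpoint[reg$name == "PUBMED"] <- unname(config[["ENTREZ"]])
  reg$endpoint[reg$name == "PMC"] <- unname(config[["ENTREZ"]])
  reg$endpoint[reg$name == "MALA_CARDS"] <- unname(config[["MALA_CARDS"]])
  reg$endpoint[reg$name == "BIOMODELS"] <- unname(config[["BIOMODELS"]])
  reg
}

#' @rdname default_registry
#' @param registry an existing registry data frame.
#' @param name,wire,access,interface,endpoint fields of the new entry.
#' @export
register_database <- function(registry, name, wire,
                              access = "structured-url",
                              interface = "entrez",
                              endpoint = NA_character_) {
  stopifnot(is.data.frame(registry))
  if (name %in% registry$name)
    stop_schema(paste0("database '", name, "' already registered"))
  if (wire %in% registry$wire)
    stop_schema(paste0("wire name '", wire, "' already in use"))
  rbind(registry, data.frame(
    name = name, wire = wire, access = access,
    interface = interface, endpoint = endpoint,
    stringsAsFactors = FALSE
  ))
}

registry_entry <- function(registry, name) {
  i <- match(name, registry$name)
  if (is.na(i))
    stop_biocurate(
      "biocurate_unsupported_repository",
      paste0("repository '", name, "' is not registered")
    )
  registry[i, , drop = FALSE]
}

#' Read an endpoint configuration file
#'
#' Endpoint templates live in a plain-text `KEY=value` file so deployments can
#' repoint the framework (for example at the https Entrez mirror) without
#' touching code. Blank lines and lines starting with `#` are ignored.
#'
#' @param path path to the configuration file; defaults to the file shipped
#'   in `inst/extdata/endpoints.conf`.
#' @return Named character vector of templates.
#' @export
read_endpoint_config <- function(path = system.file("extdata", "endpoints.conf",
                                                    package = "biocurate")) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0)) stop_parse(paste0("malformed config line: ", lines[eq < 0][1]))
  setNames(substring(lines, eq + 1L), substring(lines, 1L, eq - 1L))
}

#' Search-field vocabulary for advanced Entrez queries
#'
#' Maps symbolic field names to the Entrez field tags appended to search terms
#' (for example `science[journal]`). The mapping is data: pass `extra` to
#' extend it with further tags.
#'
#' @param extra optional named character vector of additional
#'   `symbolic name = tag` pairs.
#' @return A named character vector, names are symbolic field names.
#' @examples
#' search_field_table()[["JOURNAL"]]
#' @export
search_field_table <- function(extra = NULL) {
  tab <- c(
    JOURNAL = "journal",
    PUBLICATION_DATA = "pdat",
    AUTHOR = "au",
    TITLE = "ti"
  )
  if (!is.null(extra)) {
    stopifnot(is.character(extra), !is.null(names(extra)), all(nzchar(extra)))
    tab <- c(tab[setdiff(names(tab), names(extra))], extra)
  }
  tab
}
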