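# Record parsers: syntactic analysis of retrieved documents into typed
# entities. Parsers never mutate their input; optional elements that are
# absent map onto the typed unknown marker (NA), never the empty string.

as_xml_payload <- function(document) {
  if (inherits(document, "xml_document")) return(document)
  if (is.raw(document)) document <- rawToChar(document)
  tryCatch(
    xml2::read_xml(document),
    error = function(e) stop_parse(paste0("malformed XML: ",
                                          conditionMessage(e)))
  )
}

xml_text_or_na <- function(node, xpath) {
  hit <- xml2::xml_find_first(node, xpath)
  if (inherits(hit, "xml_missing")) return(NA_character_)
  txt <- trimws(xml2::xml_text(hit))
  if (nzchar(txt)) txt else NA_character_
}

#' Parse a PubMed efetch article set
#'
#' Maps each `PubmedArticle` element of an efetch XML document onto an
#' [article()], in document order. All authors are retained; missing optional
#' elements (volume, issue, year, DOI, abstract) become `NA`. The DOI is
#' taken from `ELocationID[@EIdType="doi"]`, falling back to the
#' `ArticleIdList`.
#'
#' @param document efetch XML as raw bytes, a string, or an `xml_document`.
#' @return List of [article()] records (possibly empty).
#' @examples
#' doc <- generate_fixture(fixture_spec("pubmed-xml", demo_articles()))
#' parse_pubmed_articles(doc)[[1]]$title
#' @export
parse_pubmed_articles <- function(document) {
  doc <- as_xml_payload(document)
  if (xml2::xml_name(doc) != "PubmedArticleSet")
    stop_parse(paste0("not a PubMed article set (root element <",
                      xml2::xml_name(doc), ">)"))
  nodes <- xml2::xml_find_all(doc, ".//PubmedArticle")
  lapply(nodes, function(node) {
    pmid <- xml_text_or_na(node, ".//MedlineCitation/PMID")
    if (is.na(pmid))
      stop_parse("PubmedArticle without a PMID")
    authors <- lapply(
      xml2::xml_find_all(node, ".//AuthorList/Author"),
      function(a) list(last = xml_text_or_na(a, "./LastName"),
                       first = {
                         f <- xml_text_or_na(a, "./ForeName")
                         if (is.na(f)) xml_text_or_na(a, "./Initials") else f
                       })
    )
    doi <- xml_text_or_na(node, ".//Article/ELocationID[@EIdType='doi']")
    if (is.na(doi))
      doi <- xml_text_or_na(node, ".//ArticleIdList/ArticleId[@IdType='doi']")
    year <- xml_text_or_na(node, ".//Journal/JournalIssue/PubDate/Year")
    article(
      pmid = pmid,
      title = xml_text_or_na(node, ".//Article/ArticleTitle"),
      authors = authors,
      journal = xml_text_or_na(node, ".//Journal/Title"),
      volume = xml_text_or_na(node, ".//JournalIssue/Volume"),
      issue = xml_text_or_na(node, ".//JournalIssue/Issue"),
      year = if (is.na(year)) NA_integer_ else as.integer(year),
      doi = doi,
      abstract = xml_text_or_na(node, ".//Abstract/AbstractText")
    )
  })
}

#' Parse a MalaCards search-results page
#'
#' Scrapes disease entries from an HTML results page: every anchor whose
#' `href` is a relative card path of the form `/card/<slug>?search=<term>`
#' yields one [disease()], named by the anchor text, in page order. Anchors
#' outside `/card/` are ignored. The tree builder is lenient, so malformed
#' markup does not abort the scrape.
#'
#' @param document HTML as raw bytes, a string, or an `xml_document`.
#' @param query optional query object; when given, only anchors whose
#'   `search=` parameter equals its first term are kept.
#' @return List of [disease()] records (possibly empty).
#' @export
parse_malacards_diseases <- function(document, query = NULL) {
  if (is.raw(document)) document <- rawToChar(document)
  doc <- if (inherits(document, "xml_document")) document else tryCatch(
    xml2::read_html(document),
    error = function(e) stop_parse(paste0("payload is not HTML: ",
                                          conditionMessage(e)))
  )
  anchors <- xml2::xml_find_all(doc, "//a[@href]")
  hrefs <- xml2::xml_attr(anchors, "href")
  keep <- grepl("^/card/[^/?]+\\?search=", hrefs)
  if (!is.null(query)) {
    stopifnot(inherits(query, "biocurate_query"))
    term <- URLencode(query$terms[[1]], reserved = TRUE)
    keep <- keep & endsWith(hrefs, paste0("?search=", term))
  }
  mapply(function(a, href) disease(trimws(xml2::xml_text(a)), href),
         anchors[keep], hrefs[keep], SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Parse a BioModels XML record
#'
#' Extracts the model accession and its textual description (the notes
#' element, whitespace-trimmed) and retains the full XML payload opaquely —
#' no SBML semantics are interpreted.
#'
#' @param document model XML as raw bytes, a string, or an `xml_document`.
#' @return A [biomodel()].
#' @export
parse_biomodels <- function(document) {
  if (is.raw(document)) document <- rawToChar(document)
  payload <- if (inherits(document, "xml_document"))
    as.character(document) else document
  doc <- as_xml_payload(document)
  model <- xml2::xml_find_first(doc, "//*[local-name()='model']")
  if (inherits(model, "xml_missing"))
    stop_parse("document has no model element")
  id <- xml2::xml_attr(model, "id")
  if (is.na(id) || !nzchar(id))
    stop_parse("model element carries no id")
  notes <- xml2::xml_find_first(model, ".//*[local-name()='notes']")
  description <- if (inherits(notes, "xml_missing")) NA_character_ else {
    txt <- trimws(xml2::xml_text(notes))
    if (nzchar(txt)) txt else NA_character_
  }
  biomodel(model_id = id, description = description, document = payload)
}

#' Parse a clinical table of aneurysm cases
#'
#' Reads a comma-delimited table (header row mandatory, UTF-8) through a
#' [column_manifest()] that maps case fields onto source columns and decodes
#' coded values. A missing mandatory column aborts before any row is read.
#' Rows violating the case invariants (bad sex/type/status code, negative
#' age) are rejected individually: valid rows are still returned, and the
#' row-numbered diagnostics are attached as the `"rejections"` attribute.
#'
#' @param table delimited text (string, raw bytes, or path to a CSV file).
#' @param manifest a [column_manifest()]; defaults to the fixture layout.
#' @return List of [aneurysm_case()] records with attribute `rejections`,
#'   a character vector of diagnostics for rejected rows.
#' @export
parse_aneurisk_clinical <- function(table, manifest = default_manifest()) {
  stopifnot(inherits(manifest, "column_manifest"))
  if (is.raw(table)) table <- rawToChar(table)
  df <- if (length(table) == 1L && file.exists(table))
    read.csv(table, stringsAsFactors = FALSE, colClasses = "character")
  else
    read.csv(text = table, stringsAsFactors = FALSE,
             colClasses = "character")
  missing <- setdiff(unname(manifest$columns), names(df))
  if (length(missing))
    stop_schema(paste0("table lacks column(s) required by the manifest: ",
                       paste(missing, collapse = ", ")))
  decode <- function(field, value) {
    dec <- manifest$decoders[[field]]
    if (is.null(dec)) value else dec(value)
  }
  cases <- list()
  rejections <- character()
  for (i in seq_len(nrow(df))) {
    res <- tryCatch({
      get_val <- function(field) decode(field, df[i, manifest$columns[[field]]])
      args <- lapply(setNames(nm = names(manifest$columns)), get_val)
      do.call(aneurysm_case, args)
    }, biocurate_error = function(e) e)
    if (inherits(res, "aneurysm_case")) {
      cases[[length(cases) + 1L]] <- res
    } else {
      rejections <- c(rejections,
                      sprintf("row %d: %s", i, conditionMessage(res)))
    }
  }
  attr(cases, "rejections") <- rejections
  cases
}
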