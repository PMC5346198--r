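# Entity records. Unknown optional values are typed absent (NA) internally;
# the "?" marker appears only when a record is rendered.

#' Literature record
#'
#' @param pmid PubMed identifier, digits only.
#' @param title article title.
#' @param authors list of `list(last =, first =)` entries in byline order; the
#'   first author is the one rendered on record cards.
#' @param journal journal title.
#' @param volume,issue volume and issue as printed (may be non-numeric, e.g.
#'   `"194 (Pt 1)"`); `NA` when unknown.
#' @param year publication year, integer or `NA`.
#' @param doi DOI string or `NA`.
#' @param abstract abstract text or `NA`.
#' @return An object of class `article`.
#' @export
article <- function(pmid, title, authors = list(), journal = NA_character_,
                    volume = NA_character_, issue = NA_character_,
                    year = NA_integer_, doi = NA_character_,
                    abstract = NA_character_) {
  if (!is.character(pmid) || length(pmid) != 1L || !grepl("^[0-9]+$", pmid))
    stop_schema("pmid must be a non-empty string of digits")
  stopifnot(is.list(authors))
  structure(
    list(pmid = pmid, title = as.character(title), authors = authors,
         journal = as.character(journal), volume = as.character(volume),
         issue = as.character(issue), year = as.integer(year),
         doi = as.character(doi), abstract = as.character(abstract)),
    class = c("article", "biocurate_entity")
  )
}

#' Disease record scraped from a MalaCards results page
#'
#' @param name disease name (anchor text).
#' @param card_link relative path to the disease card; must start `"/card/"`.
#' @return An object of class `disease`.
#' @export
disease <- function(name, card_link) {
  if (!is.character(card_link) || !startsWith(card_link, "/card/"))
    stop_schema("card_link must start with \"/card/\"")
  structure(list(name = as.character(name), card_link = card_link),
            class = c("disease", "biocurate_entity"))
}

#' Mathematical model record from the BioModels repository
#'
#' The XML payload is retained opaquely; no SBML semantics are interpreted.
#'
#' @param model_id accession, `BIOMD` followed by 10 digits.
#' @param description free-text model description, `NA` when absent.
#' @param document raw XML payload as a string, `NA` when not retained.
#' @return An object of class `biomodel`.
#' @export
biomodel <- function(model_id, description = NA_character_,
                     document = NA_character_) {
  if (!is.character(model_id) || !grepl("^BIOMD[0-9]{10}$", model_id))
    stop_schema("model_id must match BIOMD + 10 digits")
  structure(
    list(model_id = model_id, description = as.character(description),
         document = as.character(document)),
    class = c("biomodel", "biocurate_entity")
  )
}

#' Clinical aneurysm case
#'
#' The hub entity of the demonstration schema: one patient's aneurysm with
#' clinical codes, an optional reference to surface geometry (a path to an
#' STL-derived mesh; geometry lives beside the store, not inside relational
#' rows), an optional externally computed rupture-risk score, and association
#' sets linking the case to articles, diseases and models.
#'
#' @param patient_id case identifier, e.g. `"C0004"`.
#' @param sex `"F"` or `"M"`.
#' @param age age in years, non-negative integer.
#' @param aneurysm_type `"TER"` (terminal) or `"LAT"` (lateral).
#' @param location vessel code, e.g. `"ICA"`, `"ACA"`.
#' @param status rupture status, `"U"` (unruptured) or `"R"` (ruptured).
#' @param geometry path/key of the associated mesh, or `NA`.
#' @param risk_score finite rupture-risk scalar, or `NA`.
#' @return An object of class `aneurysm_case`.
#' @export
aneurysm_case <- function(patient_id, sex, age, aneurysm_type, location,
                          status, geometry = NA_character_,
                          risk_score = NA_real_) {
  if (!is.character(patient_id) || !nzchar(patient_id))
    stop_schema("patient_id must be a non-empty string")
  if (!sex %in% c("F", "M"))
    stop_schema(paste0("sex must be F or M, got '", sex, "'"))
  age <- suppressWarnings(as.integer(age))
  if (is.na(age) || age < 0L)
    stop_schema("age must be a non-negative integer")
  if (!aneurysm_type %in% c("TER", "LAT"))
    stop_schema(paste0("aneurysm_type must be TER or LAT, got '",
                       aneurysm_type, "'"))
  if (!status %in% c("U", "R"))
    stop_schema(paste0("status must be U or R, got '", status, "'"))
  risk_score <- suppressWarnings(as.numeric(risk_score))
  if (length(risk_score) != 1L || is.nan(risk_score) ||
      (!is.na(risk_score) && !is.finite(risk_score)))
    stop_biocurate("biocurate_value_error", "risk_score must be finite")
  structure(
    list(patient_id = patient_id, sex = sex, age = age,
         aneurysm_type = aneurysm_type, location = as.character(location),
         status = status, geometry = as.character(geometry),
         risk_score = as.numeric(risk_score),
         articles = list(), diseases = list(), models = list()),
    class = c("aneurysm_case", "biocurate_entity")
  )
}

# Natural key used for persistence upserts and association de-duplication.
entity_key <- function(entity) UseMethod("entity_key")
#' @export
entity_key.article <- function(entity) entity$pmid
#' @export
entity_key.disease <- function(entity) entity$card_link
#' @export
entity_key.biomodel <- function(entity) entity$model_id
#' @export
entity_key.aneurysm_case <- function(entity) entity$patient_id

#' The entity schema of the aneurysm database
#'
#' Registers the four entity kinds with their persistable fields, natural
#' keys, and association labels. Kind names are the ones accepted by the
#' SQL-like query language; the case kind is registered under the name
#' `"Aneurysm"` with query field `patientID`, so patient-centric statements
#' read naturally. Registration order is irrelevant: kinds are kept sorted by
#' name.
#'
#' @return An object of class `entity_schema`: a named list of kind
#'   descriptors (`table`, `key`, `fields`, `ql_fields`) plus an
#'   `associations` table mapping labels to endpoint kinds.
#' @export
entity_schema <- function() {
  kinds <- list(
    Article = list(
      table = "article", key = "pmid", class = "article",
      fields = c("pmid", "title", "authors", "journal", "volume", "issue",
                 "year", "doi", "abstract"),
      ql_fields = c(pmid = "pmid", title = "title", journal = "journal",
                    volume = "volume", issue = "issue", year = "year",
                    doi = "doi")
    ),
    Disease = list(
      table = "disease", key = "card_link", class = "disease",
      fields = c("card_link", "name"),
      ql_fields = c(name = "name", cardLink = "card_link")
    ),
    BioModel = list(
      table = "biomodel", key = "model_id", class = "biomodel",
      fields = c("model_id", "description", "document"),
      ql_fields = c(modelId = "model_id", description = "description")
    ),
    Aneurysm = list(
      table = "aneurysm", key = "patient_id", class = "aneurysm_case",
      fields = c("patient_id", "sex", "age", "aneurysm_type", "location",
                 "status", "geometry", "risk_score"),
      ql_fields = c(patientID = "patient_id", sex = "sex", age = "age",
                    aneurysmType = "aneurysm_type", location = "location",
                    status = "status", riskScore = "risk_score")
    )
  )
  kinds <- kinds[sort(names(kinds))]
  assoc <- data.frame(
    label = c("case-article", "case-disease", "case-model"),
    source = "Aneurysm",
    target = c("Article", "Disease", "BioModel"),
    slot = c("articles", "diseases", "models"),
    table = c("case_article", "case_disease", "case_model"),
    stringsAsFactors = FALSE
  )
  structure(list(kinds = kinds, associations = assoc),
            class = "entity_schema")
}

schema_kind_for_class <- function(schema, cls) {
  for (nm in names(schema$kinds))
    if (schema$kinds[[nm]]$class %in% cls) return(nm)
  NULL
}

#' Associate a record with an aneurysm case
#'
#' Association sets are unordered and de-duplicated by the target's natural
#' key: associating the same record twice is a no-op. The label must match
#' the target's kind (`case-article` for articles, `case-disease` for
#' diseases, `case-model` for models); a mismatch is a schema error.
#'
#' @param case an [aneurysm_case()].
#' @param target an [article()], [disease()] or [biomodel()].
#' @param label relation label.
#' @param schema the [entity_schema()].
#' @return The updated case.
#' @examples
#' cs <- demo_cases()[[1]]
#' cs <- associate(cs, demo_articles()[[1]], "case-article")
#' length(cs$articles)
#' @export
associate <- function(case, target, label, schema = entity_schema()) {
  stopifnot(inherits(case, "aneurysm_case"))
  row <- schema$associations[schema$associations$label == label, , drop = FALSE]
  if (nrow(row) == 0L)
    stop_schema(paste0("unknown association label '", label, "'"))
  expected <- schema$kinds[[row$target]]$class
  if (!inherits(target, expected))
    stop_schema(paste0("label '", label, "' expects a ", row$target,
                       " target, got ", class(target)[[1]]))
  if (identical(entity_key(target), entity_key(case)))
    stop_schema("an entity cannot be associated with itself")
  slot <- row$slot
  keys <- vapply(case[[slot]], entity_key, character(1))
  if (!entity_key(target) %in% keys)
    case[[slot]] <- c(case[[slot]], list(target))
  case
}

#' Attach an externally computed rupture-risk score to a case
#'
#' The risk criterion itself (a fluid-dynamics model published separately) is
#' not part of this framework; only its scalar output is stored as a case
#' attribute. Any prior value is overwritten.
#'
#' @param case an [aneurysm_case()].
#' @param score finite numeric scalar.
#' @return The updated case.
#' @export
attach_risk_score <- function(case, score) {
  stopifnot(inherits(case, "aneurysm_case"))
  if (!is.numeric(score) || length(score) != 1L || !is.finite(score))
    stop_biocurate("biocurate_value_error",
                   "risk score must be a finite numeric scalar")
  case$risk_score <- as.numeric(score)
  case
}

#' Column manifest for clinical tables
#'
#' The structured information interface to a local repository: maps the
#' mandatory case fields onto the source table's column names and supplies
#' value decoders for coded columns (each decoder is a function applied to
#' the raw column value before validation).
#'
#' @param columns named character vector; names must include `patient_id`,
#'   `sex`, `age`, `aneurysm_type`, `location`, `status` (optionally
#'   `geometry`, `risk_score`), values are source column names.
#' @param decoders named list of functions keyed by case field name.
#' @return An object of class `column_manifest`.
#' @export
column_manifest <- function(columns, decoders = list()) {
  mandatory <- c("patient_id", "sex", "age", "aneurysm_type", "location",
                 "status")
  missing <- setdiff(mandatory, names(columns))
  if (length(missing))
    stop_schema(paste0("manifest lacks mandatory field(s): ",
                       paste(missing, collapse = ", ")))
  stopifnot(is.list(decoders))
  structure(list(columns = columns, decoders = decoders),
            class = "column_manifest")
}

#' @rdname column_manifest
#' @details `default_manifest()` is the manifest matching the clinical table
#'   layout emitted by the fixture generator (`aneurisk-csv`).
#' @export
default_manifest <- function() {
  column_manifest(c(
    patient_id = "patientId", sex = "sex", age = "age",
    aneurysm_type = "aneurysmType", location = "location",
    status = "ruptureStatus"
  ))
}
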