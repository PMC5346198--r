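# The persistent agent: object-relational mapping of the entity schema onto
# an embedded SQLite store, plus the SQL-like query subset. One table per
# entity kind, one table per association label; a monotone `seq` column makes
# result order (insertion order) deterministic across upserts.

store_ddl <- c(
  "CREATE TABLE IF NOT EXISTS article (
     pmid TEXT PRIMARY KEY, seq INTEGER NOT NULL, title TEXT, authors TEXT,
     journal TEXT, volume TEXT, issue TEXT, year INTEGER, doi TEXT,
     abstract TEXT)",
  "CREATE TABLE IF NOT EXISTS disease (
     card_link TEXT PRIMARY KEY, seq INTEGER NOT NULL, name TEXT)",
  "CREATE TABLE IF NOT EXISTS biomodel (
     model_id TEXT PRIMARY KEY, seq INTEGER NOT NULL, description TEXT,
     document TEXT)",
  "CREATE TABLE IF NOT EXISTS aneurysm (
     patient_id TEXT PRIMARY KEY, seq INTEGER NOT NULL, sex TEXT, age INTEGER,
     aneurysm_type TEXT, location TEXT, status TEXT, geometry TEXT,
     risk_score REAL)",
  "CREATE TABLE IF NOT EXISTS case_article (
     patient_id TEXT NOT NULL REFERENCES aneurysm(patient_id),
     pmid TEXT NOT NULL REFERENCES article(pmid),
     UNIQUE(patient_id, pmid))",
  "CREATE TABLE IF NOT EXISTS case_disease (
     patient_id TEXT NOT NULL REFERENCES aneurysm(patient_id),
     card_link TEXT NOT NULL REFERENCES disease(card_link),
     UNIQUE(patient_id, card_link))",
  "CREATE TABLE IF NOT EXISTS case_model (
     patient_id TEXT NOT NULL REFERENCES aneurysm(patient_id),
     model_id TEXT NOT NULL REFERENCES biomodel(model_id),
     UNIQUE(patient_id, model_id))"
)

#' Open (or create) an entity store
#'
#' An entity store is a single-file embedded SQLite database holding the
#' relational image of the entity schema. Opening a path that already holds a
#' store reattaches to it, so contents survive close/reopen.
#'
#' @param path database file path, or `":memory:"` for a transient store.
#' @param schema the [entity_schema()].
#' @return An object of class `entity_store`.
#' @examples
#' st <- entity_store()
#' persist(st, demo_articles()[[1]])
#' run_query(st, parse_ql("SELECT a FROM Article a"))
#' store_close(st)
#' @export
entity_store <- function(path = ":memory:", schema = entity_schema()) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  for (ddl in store_ddl) DBI::dbExecute(con, ddl)
  structure(
    local({
      e <- new.env(parent = emptyenv())
      e$con <- con
      e$path <- path
      e$schema <- schema
      e
    }),
    class = "entity_store"
  )
}

#' @rdname entity_store
#' @param store an entity store.
#' @export
store_close <- function(store) {
  stopifnot(inherits(store, "entity_store"))
  if (DBI::dbIsValid(store$con)) DBI::dbDisconnect(store$con)
  invisible(store)
}

#' @rdname entity_store
#' @export
store_is_open <- function(store) {
  inherits(store, "entity_store") && DBI::dbIsValid(store$con)
}

#' @export
print.entity_store <- function(x, ...) {
  state <- if (store_is_open(x)) "open" else "closed"
  cat("<entity_store>", x$path, paste0("(", state, ")"), "\n")
  if (store_is_open(x))
    for (kind in names(x$schema$kinds))
      cat(sprintf("  %-9s %d\n", kind, store_count(x, kind)))
  invisible(x)
}

require_open <- function(store) {
  if (!store_is_open(store))
    stop_biocurate("biocurate_store_closed", "the entity store is closed")
}

#' Number of persisted entities of a kind
#' @param store an open [entity_store()].
#' @param kind entity kind name (e.g. `"Article"`, `"Aneurysm"`).
#' @export
store_count <- function(store, kind) {
  require_open(store)
  desc <- store$schema$kinds[[kind]]
  if (is.null(desc)) stop_schema(paste0("unknown entity kind '", kind, "'"))
  DBI::dbGetQuery(store$con,
                  paste0("SELECT COUNT(*) AS n FROM ", desc$table))$n
}

authors_to_json <- function(authors) {
  as.character(jsonlite::toJSON(authors, auto_unbox = TRUE, null = "null",
                                na = "null", digits = NA))
}

authors_from_json <- function(json) {
  if (is.na(json) || !nzchar(json)) return(list())
  lapply(jsonlite::fromJSON(json, simplifyVector = FALSE), function(a)
    list(last = if (is.null(a$last)) NA_character_ else a$last,
         first = if (is.null(a$first)) NA_character_ else a$first))
}

upsert <- function(store, table, key_col, values) {
  cols <- names(values)
  sql <- paste0(
    "INSERT INTO ", table, " (", paste(cols, collapse = ", "), ", seq) ",
    "VALUES (", paste0(":", cols, collapse = ", "),
    ", (SELECT COALESCE(MAX(seq), 0) + 1 FROM ", table, ")) ",
    "ON CONFLICT(", key_col, ") DO UPDATE SET ",
    paste0(setdiff(cols, key_col), " = excluded.",
           setdiff(cols, key_col), collapse = ", ")
  )
  DBI::dbExecute(store$con, sql, params = values)
  values[[key_col]]
}

#' Persist an entity
#'
#' Durably stores an entity (and, for a case, its whole association closure)
#' in the entity store. Persisting an entity whose natural key is already
#' present updates the stored row in place (upsert), so the operation is
#' idempotent. Associated articles, diseases and models of a case are
#' persisted transitively before the association rows are written, keeping
#' referential integrity by construction.
#'
#' @param store an open [entity_store()].
#' @param entity an [article()], [disease()], [biomodel()] or
#'   [aneurysm_case()].
#' @return The stored natural key, invisibly.
#' @export
persist <- function(store, entity) {
  require_open(store)
  UseMethod("persist", entity)
}

#' @export
persist.article <- function(store, entity) {
  invisible(upsert(store, "article", "pmid", list(
    pmid = entity$pmid, title = entity$title,
    authors = authors_to_json(entity$authors), journal = entity$journal,
    volume = entity$volume, issue = entity$issue, year = entity$year,
    doi = entity$doi, abstract = entity$abstract
  )))
}

#' @export
persist.disease <- function(store, entity) {
  invisible(upsert(store, "disease", "card_link",
                   list(card_link = entity$card_link, name = entity$name)))
}

#' @export
persist.biomodel <- function(store, entity) {
  invisible(upsert(store, "biomodel", "model_id", list(
    model_id = entity$model_id, description = entity$description,
    document = entity$document
  )))
}

#' @export
persist.aneurysm_case <- function(store, entity) {
  upsert(store, "aneurysm", "patient_id", list(
    patient_id = entity$patient_id, sex = entity$sex, age = entity$age,
    aneurysm_type = entity$aneurysm_type, location = entity$location,
    status = entity$status, geometry = entity$geometry,
    risk_score = entity$risk_score
  ))
  link <- function(targets, table, col) {
    for (t in targets) {
      persist(store, t)
      DBI::dbExecute(
        store$con,
        paste0("INSERT OR IGNORE INTO ", table,
               " (patient_id, ", col, ") VALUES (:pid, :key)"),
        params = list(pid = entity$patient_id, key = entity_key(t))
      )
    }
  }
  link(entity$articles, "case_article", "pmid")
  link(entity$diseases, "case_disease", "card_link")
  link(entity$models, "case_model", "model_id")
  invisible(entity$patient_id)
}

#' @export
persist.default <- function(store, entity) {
  stop_schema(paste0("no persistence mapping for class ",
                     class(entity)[[1]]))
}

na_chr <- function(x) if (is.null(x) || is.na(x)) NA_character_ else as.character(x)

row_to_entity <- function(store, kind, row) {
  switch(kind,
    Article = article(
      pmid = row$pmid, title = na_chr(row$title),
      authors = authors_from_json(row$authors),
      journal = na_chr(row$journal), volume = na_chr(row$volume),
      issue = na_chr(row$issue),
      year = if (is.na(row$year)) NA_integer_ else as.integer(row$year),
      doi = na_chr(row$doi), abstract = na_chr(row$abstract)
    ),
    Disease = disease(na_chr(row$name), row$card_link),
    BioModel = biomodel(row$model_id, na_chr(row$description),
                        na_chr(row$document)),
    Aneurysm = load_case(store, row),
    stop_schema(paste0("unknown entity kind '", kind, "'"))
  )
}

load_case <- function(store, row) {
  cs <- aneurysm_case(
    patient_id = row$patient_id, sex = row$sex, age = row$age,
    aneurysm_type = row$aneurysm_type, location = row$location,
    status = row$status, geometry = na_chr(row$geometry),
    risk_score = if (is.na(row$risk_score)) NA_real_ else row$risk_score
  )
  fetch <- function(sql, kind) {
    rows <- DBI::dbGetQuery(store$con, sql,
                            params = list(pid = row$patient_id))
    lapply(seq_len(nrow(rows)), function(i)
      row_to_entity(store, kind, rows[i, , drop = FALSE]))
  }
  cs$articles <- fetch(
    "SELECT a.* FROM article a JOIN case_article ca ON ca.pmid = a.pmid
     WHERE ca.patient_id = :pid ORDER BY ca.rowid", "Article")
  cs$diseases <- fetch(
    "SELECT d.* FROM disease d JOIN case_disease cd
     ON cd.card_link = d.card_link
     WHERE cd.patient_id = :pid ORDER BY cd.rowid", "Disease")
  cs$models <- fetch(
    "SELECT b.* FROM biomodel b JOIN case_model cm
     ON cm.model_id = b.model_id
     WHERE cm.patient_id = :pid ORDER BY cm.rowid", "BioModel")
  cs
}

#' Parse an SQL-like entity query
#'
#' The query language is the subset
#' `SELECT <alias> FROM <Kind> <alias> [WHERE <alias>.<field> = :<param>]`:
#' a single entity kind, an optional single equality predicate bound to a
#' named parameter, no joins (association traversal replaces them). Keywords
#' are case-insensitive; aliases are case-sensitive and must match between
#' the SELECT and FROM clauses. Errors report the character offset of the
#' offending token.
#'
#' @param text statement text, e.g.
#'   `"SELECT p FROM Aneurysm p WHERE p.patientID = :patientID"`.
#' @param schema the [entity_schema()].
#' @return An object of class `query_plan` with elements `kind`, `alias`,
#'   `field`, `column`, `param` (the latter three `NULL` without a WHERE
#'   clause).
#' @export
parse_ql <- function(text, schema = entity_schema()) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- gregexpr("[^[:space:]]+", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  offsets <- as.integer(m)
  fail <- function(msg, i) {
    off <- if (i <= length(offsets)) offsets[[i]] else nchar(text) + 1L
    stop_biocurate("biocurate_ql_error",
                   sprintf("%s (at offset %d)", msg, off), offset = off)
  }
  need <- function(i, what) {
    if (i > length(tokens)) fail(paste0("expected ", what), i)
    tokens[[i]]
  }
  is_kw <- function(tok, kw) toupper(tok) == kw
  alias_re <- "^[A-Za-z_][A-Za-z0-9_]*$"

  if (!is_kw(need(1L, "SELECT"), "SELECT")) fail("expected SELECT", 1L)
  alias <- need(2L, "an alias")
  if (!grepl(alias_re, alias)) fail("invalid alias", 2L)
  if (!is_kw(need(3L, "FROM"), "FROM")) fail("expected FROM", 3L)
  kind <- need(4L, "an entity kind")
  if (!kind %in% names(schema$kinds))
    fail(paste0("unknown entity kind '", kind, "'"), 4L)
  alias2 <- need(5L, "the bound alias")
  if (!identical(alias2, alias))
    fail(paste0("alias mismatch: SELECT uses '", alias,
                "' but FROM binds '", alias2, "'"), 5L)

  plan <- structure(list(kind = kind, alias = alias, field = NULL,
                         column = NULL, param = NULL),
                    class = "query_plan")
  if (length(tokens) == 5L) return(plan)

  if (!is_kw(need(6L, "WHERE"), "WHERE")) fail("expected WHERE", 6L)
  if (length(tokens) < 7L) fail("expected a predicate", 7L)
  pred <- paste(tokens[seq.int(7L, length(tokens))], collapse = "")
  pm <- regmatches(pred,
                   regexec("^([A-Za-z_][A-Za-z0-9_]*)\\.([A-Za-z_][A-Za-z0-9_]*)=:([A-Za-z_][A-Za-z0-9_]*)$",
                           pred))[[1]]
  if (length(pm) != 4L)
    fail("predicate must have the form <alias>.<field> = :<param>", 7L)
  if (!identical(pm[[2]], alias))
    fail(paste0("predicate alias '", pm[[2]], "' does not match '",
                alias, "'"), 7L)
  ql_fields <- schema$kinds[[kind]]$ql_fields
  if (!pm[[3]] %in% names(ql_fields))
    fail(paste0("kind ", kind, " has no field '", pm[[3]], "'"), 7L)
  plan$field <- pm[[3]]
  plan$column <- unname(ql_fields[[pm[[3]]]])
  plan$param <- pm[[4]]
  plan
}

#' Run a query plan against the store
#'
#' Returns all persisted entities of the plan's kind that satisfy its
#' predicate (all of them when there is none), in insertion order. Case
#' results come back with their associated articles, diseases and models
#' attached, so everything known about a patient is reachable from the
#' returned object.
#'
#' @param store an open [entity_store()].
#' @param plan a [parse_ql()] plan.
#' @param params named list binding every named parameter of the plan.
#' @return List of entity records.
#' @export
run_query <- function(store, plan, params = list()) {
  require_open(store)
  stopifnot(inherits(plan, "query_plan"))
  desc <- store$schema$kinds[[plan$kind]]
  if (is.null(plan$param)) {
    rows <- DBI::dbGetQuery(store$con,
                            paste0("SELECT * FROM ", desc$table,
                                   " ORDER BY seq"))
  } else {
    if (!plan$param %in% names(params))
      stop_biocurate("biocurate_ql_error",
                     paste0("unbound parameter :", plan$param))
    rows <- DBI::dbGetQuery(
      store$con,
      paste0("SELECT * FROM ", desc$table, " WHERE ", plan$column,
             " = :value ORDER BY seq"),
      params = list(value = params[[plan$param]])
    )
  }
  lapply(seq_len(nrow(rows)), function(i)
    row_to_entity(store, plan$kind, rows[i, , drop = FALSE]))
}

#' Check referential integrity of the association tables
#'
#' Verifies that every association row references an existing entity row on
#' both ends (an invariant the cascade persist maintains by construction).
#'
#' @param store an open [entity_store()].
#' @return `TRUE` when intact; otherwise a character vector describing each
#'   dangling reference.
#' @export
store_integrity <- function(store) {
  require_open(store)
  checks <- list(
    c("case_article", "patient_id", "aneurysm"),
    c("case_article", "pmid", "article"),
    c("case_disease", "patient_id", "aneurysm"),
    c("case_disease", "card_link", "disease"),
    c("case_model", "patient_id", "aneurysm"),
    c("case_model", "model_id", "biomodel")
  )
  problems <- character()
  for (chk in checks) {
    key <- store$schema$kinds[[
      schema_kind_for_table(store$schema, chk[[3]])]]$key
    n <- DBI::dbGetQuery(store$con, paste0(
      "SELECT COUNT(*) AS n FROM ", chk[[1]], " t LEFT JOIN ", chk[[3]],
      " e ON t.", chk[[2]], " = e.", key, " WHERE e.", key, " IS NULL"
    ))$n
    if (n > 0)
      problems <- c(problems, sprintf("%s.%s: %d dangling reference(s)",
                                      chk[[1]], chk[[2]], n))
  }
  if (length(problems)) problems else TRUE
}

schema_kind_for_table <- function(schema, table) {
  for (nm in names(schema$kinds))
    if (schema$kinds[[nm]]$table == table) return(nm)
  stop_schema(paste0("no kind mapped to table '", table, "'"))
}
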