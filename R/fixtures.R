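# Fixture generator: emits synthetic documents in every format the parsers
# read (PubMed-dialect XML, results-page HTML, model XML, clinical CSV, STL
# in both dialects), so the whole framework runs with no download. The
# dialects are minimal but structurally faithful; the binding contract is the
# round trip parse(generate(spec)) == records.

fixture_kinds <- c("pubmed-xml", "malacards-html", "biomodels-xml",
                   "aneurisk-csv", "stl-ascii", "stl-binary")

#' Describe a fixture document
#'
#' A fixture spec names a document format and the typed records to encode in
#' it. When `records` is omitted, a seeded synthetic payload of `n` records
#' is generated ([random_entities()]); the same spec and seed always render
#' to byte-identical output.
#'
#' @param kind one of `"pubmed-xml"`, `"malacards-html"`, `"biomodels-xml"`,
#'   `"aneurisk-csv"`, `"stl-ascii"`, `"stl-binary"`.
#' @param records entities to encode: a list of records, or a single
#'   [tri_mesh()] for the STL kinds. `NULL` generates a random payload.
#' @param n number of records to generate when `records` is `NULL` (facet
#'   count for STL kinds).
#' @param seed seed for the generated payload.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(kind, records = NULL, n = 3L, seed = 1L) {
  if (!kind %in% fixture_kinds)
    stop_schema(paste0("unknown fixture kind '", kind, "'"))
  if (is.null(records)) records <- random_entities(kind, n, seed)
  if (inherits(records, "biocurate_entity") || inherits(records, "tri_mesh"))
    records <- list(records)
  structure(list(kind = kind, records = records, seed = seed),
            class = "fixture_spec")
}

xesc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Render a fixture document
#'
#' Deterministically renders a [fixture_spec()] to document bytes. The
#' output parses back to the spec's records under the corresponding
#' record-parser operation.
#'
#' @param spec a [fixture_spec()].
#' @return Raw vector of document bytes.
#' @examples
#' doc <- generate_fixture(fixture_spec("malacards-html", demo_diseases()))
#' length(parse_malacards_diseases(doc))
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  out <- switch(spec$kind,
    "pubmed-xml" = emit_pubmed_xml(spec$records),
    "malacards-html" = emit_malacards_html(spec$records),
    "biomodels-xml" = emit_biomodels_xml(spec$records),
    "aneurisk-csv" = emit_aneurisk_csv(spec$records),
    "stl-ascii" = write_stl_ascii(spec$records[[1]]),
    "stl-binary" = write_stl_binary(spec$records[[1]])
  )
  if (is.raw(out)) out else charToRaw(out)
}

emit_pubmed_xml <- function(articles) {
  tag <- function(name, value, attrs = "") {
    if (is.na(value)) return(NULL)
    paste0("<", name, attrs, ">", xesc(value), "</", name, ">")
  }
  body <- vapply(articles, function(a) {
    stopifnot(inherits(a, "article"))
    authors <- vapply(a$authors, function(au) paste0(
      "<Author>",
      paste0(c(tag("LastName", au$last), tag("ForeName", au$first)),
             collapse = ""),
      "</Author>"), character(1))
    paste0(
      "<PubmedArticle><MedlineCitation>",
      tag("PMID", a$pmid),
      "<Article>",
      "<Journal>",
      tag("Title", a$journal),
      "<JournalIssue>",
      tag("Volume", a$volume),
      tag("Issue", a$issue),
      if (!is.na(a$year)) paste0("<PubDate>", tag("Year", as.character(a$year)),
                                 "</PubDate>"),
      "</JournalIssue>",
      "</Journal>",
      tag("ArticleTitle", a$title),
      if (length(a$authors))
        paste0("<AuthorList>", paste0(authors, collapse = ""), "</AuthorList>"),
      tag("ELocationID", a$doi, " EIdType=\"doi\""),
      if (!is.na(a$abstract))
        paste0("<Abstract>", tag("AbstractText", a$abstract), "</Abstract>"),
      "</Article>",
      "</MedlineCitation></PubmedArticle>"
    )
  }, character(1))
  paste0("<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n<PubmedArticleSet>",
         paste0(body, collapse = ""), "</PubmedArticleSet>\n")
}

emit_malacards_html <- function(diseases) {
  items <- vapply(diseases, function(d) {
    stopifnot(inherits(d, "disease"))
    paste0("<li class=\"searchResultTitle\"><a href=\"", xesc(d$card_link),
           "\">", xesc(d$name), "</a></li>")
  }, character(1))
  paste0(
    "<!DOCTYPE html>\n<html><head><title>Search results</title></head><body>\n",
    "<div id=\"header\"><a href=\"/\">Home</a> <a href=\"/about\">About</a></div>\n",
    "<ul class=\"searchResults\">\n",
    paste0(items, collapse = "\n"),
    "\n</ul>\n<div id=\"footer\"><a href=\"/contact\">Contact</a></div>\n",
    "</body></html>\n"
  )
}

emit_biomodels_xml <- function(models) {
  m <- models[[1]]
  stopifnot(inherits(m, "biomodel"))
  notes <- if (is.na(m$description)) "" else paste0(
    "<notes><body xmlns=\"http://www.w3.org/1999/xhtml\"><p>",
    xesc(m$description), "</p></body></notes>"
  )
  paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<sbml xmlns=\"http://www.sbml.org/sbml/level2/version4\" level=\"2\" version=\"4\">",
    "<model id=\"", m$model_id, "\" name=\"", m$model_id, "\">",
    notes,
    "<listOfSpecies/>",
    "</model></sbml>\n"
  )
}

emit_aneurisk_csv <- function(cases) {
  header <- "patientId,sex,age,aneurysmType,location,ruptureStatus"
  rows <- vapply(cases, function(cs) {
    stopifnot(inherits(cs, "aneurysm_case"))
    paste(cs$patient_id, cs$sex, cs$age, cs$aneurysm_type, cs$location,
          cs$status, sep = ",")
  }, character(1))
  paste0(paste(c(header, rows), collapse = "\n"), "\n")
}

# Run code under a private, seeded RNG stream without disturbing the
# session's generator state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

fixture_words <- c(
  "aneurysm", "vascular", "arterial", "retinal", "cerebral", "rupture",
  "hemodynamic", "geometry", "threshold", "pressure", "sac", "vessel",
  "model", "analysis", "clinical", "patient", "flow", "stress", "wall",
  "dynamics", "risk", "criterion", "dimensional", "carotid", "basilar",
  "microaneurysm", "treatment", "oscillation", "calcium", "binding",
  "kinetic", "pathology", "imaging", "segmentation", "morphology", "study"
)

rand_words <- function(n, capitalize = FALSE) {
  w <- sample(fixture_words, n, replace = TRUE)
  if (capitalize)
    w <- paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w)))
  paste(w, collapse = " ")
}

maybe_na <- function(value, p_na = 0.3) {
  if (runif(1) < p_na) NA_character_ else value
}

#' Generate random entity payloads
#'
#' Seeded synthetic records for property testing and fixture generation:
#' free text is drawn from a fixed word list, identifiers are sampled without
#' replacement, optional fields are sometimes absent, and STL payloads are
#' perturbed unit spheres. Deterministic for a given `(kind, n, seed)`.
#'
#' @param kind fixture kind (see [fixture_spec()]).
#' @param n number of records (facet count for STL kinds).
#' @param seed RNG seed.
#' @return List of entities, or a [tri_mesh()] for the STL kinds.
#' @export
random_entities <- function(kind, n = 3L, seed = 1L) {
  if (!kind %in% fixture_kinds)
    stop_schema(paste0("unknown fixture kind '", kind, "'"))
  with_seed(seed, switch(kind,
    "pubmed-xml" = {
      pmids <- as.character(sample.int(9999999L, n))
      lapply(seq_len(n), function(i) {
        n_auth <- sample(1:3, 1)
        authors <- lapply(seq_len(n_auth), function(j)
          list(last = rand_words(1, capitalize = TRUE),
               first = rand_words(1, capitalize = TRUE)))
        article(
          pmid = pmids[[i]],
          title = paste0(rand_words(sample(4:8, 1), capitalize = TRUE), "."),
          authors = authors,
          journal = rand_words(sample(2:4, 1), capitalize = TRUE),
          volume = as.character(sample.int(200L, 1)),
          issue = maybe_na(as.character(sample.int(12L, 1))),
          year = sample(1990:2020, 1),
          doi = maybe_na(sprintf("10.%04d/j%07d", sample.int(9999L, 1),
                                 sample.int(9999999L, 1))),
          abstract = maybe_na(rand_words(sample(10:25, 1)))
        )
      })
    },
    "malacards-html" = {
      lapply(seq_len(n), function(i) {
        name <- paste0(rand_words(sample(2:5, 1), capitalize = TRUE),
                       " ", i)
        slug <- gsub("[^a-z0-9]+", "_", tolower(name))
        disease(name, paste0("/card/", slug, "?search=aneurysm"))
      })
    },
    "biomodels-xml" = {
      lapply(seq_len(n), function(i) biomodel(
        model_id = sprintf("BIOMD%010d", sample.int(999999L, 1)),
        description = maybe_na(rand_words(sample(8:20, 1)), p_na = 0.2)
      ))
    },
    "aneurisk-csv" = {
      ids <- sprintf("C%04d", sample.int(9999L, n))
      lapply(seq_len(n), function(i) aneurysm_case(
        patient_id = ids[[i]],
        sex = sample(c("F", "M"), 1),
        age = sample(0:95, 1),
        aneurysm_type = sample(c("TER", "LAT"), 1),
        location = sample(c("ICA", "ACA", "MCA", "BAS", "PCA"), 1),
        status = sample(c("U", "R"), 1)
      ))
    },
    "stl-ascii" = random_mesh(n),
    "stl-binary" = random_mesh(n)
  ))
}

# Triangles with vertices on a jittered unit sphere; coordinates rounded so
# both STL dialects (text vs float32) carry them losslessly.
random_mesh <- function(n_facets) {
  pt <- function() {
    v <- rnorm(3L)
    round(v / sqrt(sum(v^2)) * runif(1, 0.9, 1.1), 4L)
  }
  v1 <- t(vapply(seq_len(n_facets), function(i) pt(), numeric(3)))
  v2 <- t(vapply(seq_len(n_facets), function(i) pt(), numeric(3)))
  v3 <- t(vapply(seq_len(n_facets), function(i) pt(), numeric(3)))
  tri_mesh(v1, v2, v3)
}

#' Demonstration records of the aneurysm specialized database
#'
#' Small bundled record sets used across examples, fixtures and tests: two
#' retinal-microaneurysm articles, the first seven aneurysm-associated
#' diseases of a MalaCards search, two calcium/bilirubin BioModels entries
#' (descriptions completed synthetically beyond their catalogue prefixes),
#' and five clinical cases (C0004–C0008) in the Aneurisk coding scheme.
#'
#' @return A list of entity records.
#' @export
demo_articles <- function() {
  list(
    article(
      pmid = "23371018",
      title = "Non-dimensional analysis of retinal microaneurysms: critical threshold for treatment.",
      authors = list(list(last = "Ezra", first = "Elishai")),
      journal = "Integrative biology : quantitative biosciences from nano to macro",
      volume = "5", issue = "3", year = 2013L, doi = "10.1039/c3ib20259c",
      abstract = "A non-dimensional fluid-dynamics criterion sets a critical geometric threshold for microaneurysm treatment."
    ),
    article(
      pmid = "10227670",
      title = "Three dimensional analysis of microaneurysms in the human diabetic retina.",
      authors = list(list(last = "Moore", first = "JJ")),
      journal = "Journal of anatomy",
      volume = "194 (Pt 1)", issue = NA_character_, year = 1999L,
      doi = NA_character_
    )
  )
}

#' @rdname demo_articles
#' @export
demo_diseases <- function() {
  entries <- list(
    c("Familial Thoracic Aortic Aneurysm and Dissection",
      "familial_thoracic_aortic_aneurysm_and_dissection"),
    c("Coronary Aneurysm", "coronary_aneurysm"),
    c("Angiopathy, Hereditary, with Nephropathy, Aneurysms, and Muscle Cramps",
      "angiopathy_hereditary_with_nephropathy_aneurysms_and_muscle_cramps"),
    c("Aneurysmal Bone Cysts", "aneurysmal_bone_cysts"),
    c("Intracranial Berry Aneurysm", "intracranial_berry_aneurysm"),
    c("Cerebral Aneurysms", "cerebral_aneurysms"),
    c("Loeys-Dietz Syndrome", "loeys_dietz_syndrome")
  )
  lapply(entries, function(e)
    disease(e[[1]], paste0("/card/", e[[2]], "?search=aneurysm")))
}

#' @rdname demo_articles
#' @export
demo_biomodels <- function() {
  list(
    biomodel(
      "BIOMD0000000058",
      paste("The model reproduces the same amplitude antiphase calcium",
            "oscillations of coupled cells, with intercellular coupling",
            "parameters chosen for the demonstration payload (synthetic",
            "completion of the catalogue prefix).")
    ),
    biomodel(
      "BIOMD0000000291",
      paste("adsorption of albumin-bilirubin complex to the surface of",
            "carbon pyropolymer, described by a kinetic binding scheme",
            "(synthetic completion of the catalogue prefix).")
    )
  )
}

#' @rdname demo_articles
#' @export
demo_cases <- function() {
  rows <- list(
    list("C0004", "F", 60L, "TER", "ICA", "U"),
    list("C0005", "F", 26L, "LAT", "ICA", "R"),
    list("C0006", "F", 45L, "LAT", "ICA", "U"),
    list("C0007", "F", 44L, "LAT", "ICA", "U"),
    list("C0008", "M", 68L, "TER", "ACA", "R")
  )
  lapply(rows, function(r)
    aneurysm_case(r[[1]], r[[2]], r[[3]], r[[4]], r[[5]], r[[6]]))
}
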