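efetch_demo_url <- paste0(
  "http://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
  "?db=pubmed&id=23371018,10227670&retmode=xml"
)

test_that("efetch URLs follow the eUtils grammar", {
  q <- add_id(add_id(query("PUBMED", "FETCH"), "23371018"), "10227670")
  req <- build_entrez_url(q)
  expect_s3_class(req, "structured_request")
  expect_identical(req$url, efetch_demo_url)
  expect_identical(req$expected_payload, "xml")

  one <- build_entrez_url(add_id(query("PUBMED", "FETCH"), "1"))
  expect_match(one$url, "efetch\\.fcgi\\?db=pubmed&id=1&retmode=xml$")
})

test_that("esearch URLs put field constraints before terms and join with the connector", {
  q <- query("PUBMED", "SEARCH")
  q <- add_term(add_term(q, "breast"), "cancer")
  q <- add_field(q, "JOURNAL", "science")
  q <- add_field(q, "PUBLICATION_DATA", "2009")
  expect_identical(
    build_entrez_url(q)$url,
    paste0("http://eutils.ncbi.nlm.nih.gov/entrez/eutils/esearch.fcgi",
           "?db=pubmed&term=science[journal]+2009[pdat]+breast+AND+cancer",
           "&retmode=xml&rettype=uilist")
  )

  disj <- add_term(add_term(query("PUBMED", connector = "OR"), "breast"),
                   "cancer")
  expect_match(build_entrez_url(disj)$url, "term=breast+OR+cancer",
               fixed = TRUE)

  spaced <- add_field(query("PUBMED"), "JOURNAL", "plos one")
  expect_match(build_entrez_url(spaced)$url, "term=plos+one[journal]",
               fixed = TRUE)
})

test_that("URL generation is deterministic and fails typed on bad input", {
  q <- add_term(query("PUBMED"), "aneurysm")
  expect_identical(build_entrez_url(q)$url, build_entrez_url(q)$url)

  err <- tryCatch(build_entrez_url(query("PUBMED", "FETCH")),
                  biocurate_validation_error = identity)
  expect_s3_class(err, "biocurate_validation_error")
  expect_match(err$violations, "at least one id", all = FALSE)

  expect_error(build_entrez_url(add_term(query("MALA_CARDS"), "aneurysm")),
               class = "biocurate_unsupported_repository")
})

test_that("generated Entrez URLs round-trip back to the query", {
  set.seed(421)
  for (i in 1:60) {
    q <- random_entrez_query()
    back <- parse_entrez_url(build_entrez_url(q)$url)
    expect_identical(back$db, "pubmed")
    expect_identical(back$search_type, q$search_type)
    expect_identical(back$ids, q$ids)
    expect_identical(back$terms, q$terms)
    expect_identical(back$fields$field, q$fields$field)
    expect_identical(back$fields$value, q$fields$value)
    if (length(q$terms) >= 2L)
      expect_identical(back$connector, q$connector)
  }
})

test_that("MalaCards URLs substitute the encoded first term into the template", {
  q <- add_term(query("MALA_CARDS"), "aneurysm")
  req <- build_malacards_url(q)
  expect_identical(req$expected_payload, "html")
  expect_match(req$url, "/search/results/aneurysm$")

  spaced <- add_term(query("MALA_CARDS"), "berry aneurysm")
  expect_match(build_malacards_url(spaced)$url,
               "/search/results/berry%20aneurysm$")

  expect_error(build_malacards_url(query("MALA_CARDS")),
               class = "biocurate_validation_error")
})

test_that("BioModels requests carry the accession and reject malformed ids", {
  for (id in c("BIOMD0000000058", "BIOMD0000000291")) {
    req <- build_biomodels_request(add_id(query("BIOMODELS", "FETCH"), id))
    expect_match(req$url, id, fixed = TRUE)
  }
  expect_error(
    build_biomodels_request(add_id(query("BIOMODELS", "FETCH"), "BIOMD123")),
    class = "biocurate_malformed_id"
  )
})

test_that("execute_request passes fixture payloads through verbatim", {
  payload <- generate_fixture(fixture_spec("pubmed-xml", demo_articles()))
  tr <- fixture_transport(setNames(list(payload), efetch_demo_url))
  req <- structured_request(efetch_demo_url)
  expect_identical(execute_request(req, tr), payload)
  expect_identical(execute_request(req, tr), execute_request(req, tr))

  err <- tryCatch(
    execute_request(structured_request("http://example.org/other"), tr),
    biocurate_retrieval_error = identity
  )
  expect_s3_class(err, "biocurate_retrieval_error")
  expect_identical(err$url, "http://example.org/other")

  # a transport that dies surfaces as a retrieval error, not a crash
  broken <- function(request) stop("connection refused")
  expect_error(execute_request(req, broken),
               class = "biocurate_retrieval_error")
  # as does an empty payload
  empty <- function(request) raw()
  expect_error(execute_request(req, empty),
               class = "biocurate_retrieval_error")
})
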