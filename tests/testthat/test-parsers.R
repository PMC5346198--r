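test_that("PubMed article parsing recovers the demo records field-for-field", {
  doc <- generate_fixture(fixture_spec("pubmed-xml", demo_articles()))
  arts <- parse_pubmed_articles(doc)
  expect_length(arts, 2L)

  a1 <- arts[[1]]
  expect_identical(a1$pmid, "23371018")
  expect_identical(a1$title,
    "Non-dimensional analysis of retinal microaneurysms: critical threshold for treatment.")
  expect_identical(a1$authors[[1]], list(last = "Ezra", first = "Elishai"))
  expect_identical(a1$journal,
    "Integrative biology : quantitative biosciences from nano to macro")
  expect_identical(a1$volume, "5")
  expect_identical(a1$issue, "3")
  expect_identical(a1$year, 2013L)
  expect_identical(a1$doi, "10.1039/c3ib20259c")

  # the 1999 record: issue and DOI are typed unknowns, not empty strings
  a2 <- arts[[2]]
  expect_identical(a2$volume, "194 (Pt 1)")
  expect_true(is.na(a2$issue))
  expect_true(is.na(a2$doi))
  expect_identical(a2$year, 1999L)
})

test_that("PubMed parsing handles empty sets and rejects foreign dialects", {
  empty <- generate_fixture(fixture_spec("pubmed-xml", list()))
  expect_identical(parse_pubmed_articles(empty), list())
  expect_error(parse_pubmed_articles("<NotArticles/>"),
               class = "biocurate_parse_error")
  expect_error(parse_pubmed_articles("<unclosed"),
               class = "biocurate_parse_error")
})

test_that("parsers are pure: reparsing an unchanged payload gives equal records", {
  payload <- generate_fixture(fixture_spec("pubmed-xml", n = 4L, seed = 77L))
  before <- payload
  first <- parse_pubmed_articles(payload)
  second <- parse_pubmed_articles(payload)
  expect_identical(payload, before)
  expect_identical(first, second)
})

test_that("MalaCards scraping keeps only card anchors, in page order", {
  page <- generate_fixture(fixture_spec("malacards-html", demo_diseases()))
  ds <- parse_malacards_diseases(page)
  expect_length(ds, 7L)
  expect_identical(ds[[1]]$name,
                   "Familial Thoracic Aortic Aneurysm and Dissection")
  expect_identical(
    ds[[1]]$card_link,
    "/card/familial_thoracic_aortic_aneurysm_and_dissection?search=aneurysm"
  )
  expect_identical(vapply(ds, `[[`, character(1), "name"),
                   vapply(demo_diseases(), `[[`, character(1), "name"))

  # navigation anchors outside /card/ are not diseases
  decoys <- paste0(
    "<html><body><a href=\"/about\">About</a>",
    "<a href=\"/card/coronary_aneurysm?search=aneurysm\">Coronary Aneurysm</a>",
    "<a href=\"https://example.org/card/x?search=aneurysm\">offsite</a>",
    "</body></html>"
  )
  kept <- parse_malacards_diseases(decoys)
  expect_length(kept, 1L)
  expect_identical(kept[[1]]$name, "Coronary Aneurysm")

  expect_identical(parse_malacards_diseases("<html><body></body></html>"),
                   list())
})

test_that("MalaCards scraping can filter by the query's search term", {
  page <- paste0(
    "<html><body>",
    "<a href=\"/card/coronary_aneurysm?search=aneurysm\">Coronary Aneurysm</a>",
    "<a href=\"/card/cerebritis?search=cerebritis\">Cerebritis</a>",
    "</body></html>"
  )
  q <- add_term(query("MALA_CARDS"), "aneurysm")
  ds <- parse_malacards_diseases(page, q)
  expect_length(ds, 1L)
  expect_identical(ds[[1]]$card_link, "/card/coronary_aneurysm?search=aneurysm")
})

test_that("BioModels parsing extracts accession and description, keeping the payload", {
  for (m in demo_biomodels()) {
    doc <- generate_fixture(fixture_spec("biomodels-xml", list(m)))
    got <- parse_biomodels(doc)
    expect_identical(got$model_id, m$model_id)
    expect_identical(got$description, m$description)
    expect_identical(got$document, rawToChar(doc))
  }
  expect_true(startsWith(
    parse_biomodels(generate_fixture(
      fixture_spec("biomodels-xml", demo_biomodels()[1])))$description,
    "The model reproduces the same amplitude antiphase calcium oscillations of coupled"
  ))

  nodesc <- "<sbml><model id=\"BIOMD0000000001\"><notes></notes></model></sbml>"
  expect_true(is.na(parse_biomodels(nodesc)$description))
  expect_error(parse_biomodels("<sbml><model/></sbml>"),
               class = "biocurate_parse_error")
})

test_that("clinical table parsing decodes the demo patients through the manifest", {
  tab <- rawToChar(generate_fixture(fixture_spec("aneurisk-csv", demo_cases())))
  cases <- parse_aneurisk_clinical(tab)
  expect_length(cases, 5L)

  c5 <- cases[[2]]
  expect_identical(c5$patient_id, "C0005")
  expect_identical(c5$sex, "F")
  expect_identical(c5$age, 26L)
  expect_identical(c5$aneurysm_type, "LAT")
  expect_identical(c5$location, "ICA")
  expect_identical(c5$status, "R")

  c8 <- cases[[5]]
  expect_identical(c8$patient_id, "C0008")
  expect_identical(c8$sex, "M")
  expect_identical(c8$location, "ACA")
  expect_identical(c8$status, "R")
})

test_that("invalid clinical rows are rejected with diagnostics, valid rows kept", {
  tab <- paste(
    "patientId,sex,age,aneurysmType,location,ruptureStatus",
    "C0004,F,60,TER,ICA,U",
    "C9999,F,30,TER,ICA,X",
    "C9998,Q,30,TER,ICA,U",
    sep = "\n"
  )
  cases <- parse_aneurisk_clinical(tab)
  expect_length(cases, 1L)
  rej <- attr(cases, "rejections")
  expect_length(rej, 2L)
  expect_match(rej[[1]], "^row 2: .*status must be U or R")
  expect_match(rej[[2]], "^row 3: .*sex must be F or M")
})

test_that("a manifest column missing from the header aborts before any row", {
  tab <- "patientId,sex,age\nC0004,F,60"
  expect_error(parse_aneurisk_clinical(tab),
               class = "biocurate_schema_error")
  expect_error(column_manifest(c(patient_id = "p", sex = "s")),
               class = "biocurate_schema_error")
})

test_that("manifest decoders translate coded columns", {
  tab <- paste(
    "case,gender,years,shape,vessel,broke",
    "C0004,female,60,terminal,ICA,no",
    sep = "\n"
  )
  manifest <- column_manifest(
    c(patient_id = "case", sex = "gender", age = "years",
      aneurysm_type = "shape", location = "vessel", status = "broke"),
    decoders = list(
      sex = function(x) c(female = "F", male = "M")[[x]],
      aneurysm_type = function(x) c(terminal = "TER", lateral = "LAT")[[x]],
      status = function(x) c(no = "U", yes = "R")[[x]]
    )
  )
  cases <- parse_aneurisk_clinical(tab, manifest)
  expect_length(cases, 1L)
  expect_identical(cases[[1]]$sex, "F")
  expect_identical(cases[[1]]$aneurysm_type, "TER")
  expect_identical(cases[[1]]$status, "U")
})

test_that("record counts always match an independent element/row count", {
  set.seed(99)
  for (i in 1:10) {
    n <- sample(0:6, 1)
    doc <- generate_fixture(fixture_spec("pubmed-xml", n = n, seed = i))
    n_elements <- length(gregexpr("<PubmedArticle>", rawToChar(doc),
                                  fixed = TRUE)[[1]])
    if (n == 0L) n_elements <- 0L  # gregexpr reports one no-match entry
    expect_length(parse_pubmed_articles(doc), n_elements)
    expect_identical(n_elements, n)
  }
})
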