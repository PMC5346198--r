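# Field-for-field record comparison helpers shared across the suite.

expect_article_equal <- function(got, want) {
  expect_s3_class(got, "article")
  for (f in c("pmid", "title", "journal", "volume", "issue", "year", "doi",
              "abstract"))
    expect_identical(got[[f]], want[[f]], label = paste0("article$", f))
  expect_identical(got$authors, want$authors)
}

expect_case_equal <- function(got, want, check_assoc = FALSE) {
  expect_s3_class(got, "aneurysm_case")
  for (f in c("patient_id", "sex", "age", "aneurysm_type", "location",
              "status", "geometry"))
    expect_identical(got[[f]], want[[f]], label = paste0("case$", f))
  if (is.na(want$risk_score)) {
    expect_true(is.na(got$risk_score))
  } else {
    expect_equal(got$risk_score, want$risk_score, tolerance = 1e-12)
  }
  if (check_assoc) {
    expect_identical(vapply(got$articles, entity_key, character(1)),
                     vapply(want$articles, entity_key, character(1)))
    expect_identical(vapply(got$diseases, entity_key, character(1)),
                     vapply(want$diseases, entity_key, character(1)))
    expect_identical(vapply(got$models, entity_key, character(1)),
                     vapply(want$models, entity_key, character(1)))
  }
}

expect_mesh_equal <- function(got, want, tol = 1e-9) {
  expect_s3_class(got, "tri_mesh")
  expect_identical(n_facets(got), n_facets(want))
  for (f in c("v1", "v2", "v3"))
    expect_lt(max(abs(got[[f]] - want[[f]]), 0), tol)
}

# A valid random Entrez query for round-trip property tests. Terms and field
# values are single words so the "+" separator stays unambiguous.
random_entrez_query <- function() {
  if (runif(1) < 0.5) {
    q <- query("PUBMED", "FETCH")
    for (id in as.character(sample.int(99999999L, sample(1:5, 1))))
      q <- add_id(q, id)
  } else {
    q <- query("PUBMED", "SEARCH",
               connector = sample(c("AND", "OR"), 1))
    for (t in sample(c("breast", "cancer", "aneurysm", "retina", "stress"),
                     sample(1:3, 1)))
      q <- add_term(q, t)
    if (runif(1) < 0.7) {
      fields <- sample(names(search_field_table()), sample(1:2, 1))
      for (f in fields) q <- add_field(q, f, sample(c("science", "2009",
                                                      "nature"), 1))
    }
  }
  q
}
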