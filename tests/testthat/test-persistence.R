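test_that("persist is an upsert: repeats update in place, counts match rows", {
  st <- entity_store()
  on.exit(store_close(st))
  for (a in demo_articles()) persist(st, a)
  expect_identical(store_count(st, "Article"), 2L)

  persist(st, demo_articles()[[1]])
  expect_identical(store_count(st, "Article"), 2L)

  # an update is visible after re-persisting a modified record
  a <- demo_articles()[[1]]
  a$journal <- "Renamed Journal"
  persist(st, a)
  got <- run_query(st, parse_ql("SELECT a FROM Article a"))
  expect_identical(got[[1]]$journal, "Renamed Journal")
  expect_identical(store_count(st, "Article"), 2L)
})

test_that("every entity kind round-trips through the store field-for-field", {
  st <- entity_store()
  on.exit(store_close(st))

  arts <- demo_articles()
  for (a in arts) persist(st, a)
  back <- run_query(st, parse_ql("SELECT a FROM Article a"))
  for (i in seq_along(arts)) expect_article_equal(back[[i]], arts[[i]])

  d <- demo_diseases()[[3]]  # name with commas survives
  persist(st, d)
  got_d <- run_query(st, parse_ql("SELECT d FROM Disease d"))[[1]]
  expect_identical(got_d$name, d$name)
  expect_identical(got_d$card_link, d$card_link)

  m <- parse_biomodels(generate_fixture(
    fixture_spec("biomodels-xml", demo_biomodels()[1])))
  persist(st, m)
  got_m <- run_query(st, parse_ql("SELECT m FROM BioModel m"))[[1]]
  expect_identical(got_m$description, m$description)
  expect_identical(got_m$document, m$document)

  cs <- attach_risk_score(demo_cases()[[1]], 0.7310585786300049)
  persist(st, cs)
  got_c <- run_query(st, parse_ql("SELECT p FROM Aneurysm p"))[[1]]
  expect_case_equal(got_c, cs)
})

test_that("persisting a case cascades to unpersisted associated records", {
  st <- entity_store()
  on.exit(store_close(st))
  cs <- demo_cases()[[1]]
  cs <- associate(cs, demo_articles()[[1]], "case-article")
  cs <- associate(cs, demo_articles()[[2]], "case-article")
  cs <- associate(cs, demo_diseases()[[2]], "case-disease")
  cs <- associate(cs, demo_biomodels()[[1]], "case-model")
  persist(st, cs)

  expect_identical(store_count(st, "Article"), 2L)
  expect_identical(store_count(st, "Disease"), 1L)
  expect_identical(store_count(st, "BioModel"), 1L)
  expect_true(isTRUE(store_integrity(st)))

  plan <- parse_ql("SELECT p FROM Aneurysm p WHERE p.patientID = :patientID")
  got <- run_query(st, plan, list(patientID = "C0004"))
  expect_length(got, 1L)
  expect_case_equal(got[[1]], cs, check_assoc = TRUE)
})

test_that("referential integrity holds after arbitrary persist sequences", {
  set.seed(7)
  st <- entity_store()
  on.exit(store_close(st))
  arts <- random_entities("pubmed-xml", 5L, seed = 1L)
  cases <- random_entities("aneurisk-csv", 8L, seed = 2L)
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    for (a in sample(arts, sample(0:3, 1)))
      cs <- associate(cs, a, "case-article")
    persist(st, cs)
    if (runif(1) < 0.5) persist(st, cs)  # repeat persists are harmless
  }
  expect_true(isTRUE(store_integrity(st)))
})

test_that("store contents survive close and reopen", {
  path <- tempfile(fileext = ".sqlite")
  on.exit(unlink(path))
  st <- entity_store(path)
  cs <- associate(attach_risk_score(demo_cases()[[2]], 1.25),
                  demo_articles()[[1]], "case-article")
  persist(st, cs)
  for (d in demo_diseases()) persist(st, d)
  store_close(st)
  expect_false(store_is_open(st))
  expect_error(store_count(st, "Disease"), class = "biocurate_store_closed")

  st2 <- entity_store(path)
  on.exit(store_close(st2), add = TRUE)
  expect_identical(store_count(st2, "Disease"), 7L)
  got <- run_query(st2,
                   parse_ql("SELECT p FROM Aneurysm p WHERE p.patientID = :patientID"),
                   list(patientID = "C0005"))
  expect_length(got, 1L)
  expect_case_equal(got[[1]], cs, check_assoc = TRUE)
})

test_that("the SQL-like grammar parses the supported subset and only it", {
  plan <- parse_ql("SELECT a FROM Article a")
  expect_identical(plan$kind, "Article")
  expect_identical(plan$alias, "a")
  expect_null(plan$param)

  plan <- parse_ql("SELECT p FROM Aneurysm p WHERE p.patientID = :patientID")
  expect_identical(plan$kind, "Aneurysm")
  expect_identical(plan$field, "patientID")
  expect_identical(plan$column, "patient_id")
  expect_identical(plan$param, "patientID")

  # keywords are case-insensitive, aliases are not
  expect_identical(parse_ql("select a from Article a")$kind, "Article")
  expect_error(parse_ql("SELECT x FROM Article a"),
               class = "biocurate_ql_error")
  expect_error(parse_ql("SELECT A FROM Article a"),
               class = "biocurate_ql_error")

  expect_error(parse_ql("SELECT a FROM Protein a"),
               class = "biocurate_ql_error")
  expect_error(parse_ql("SELECT a FROM Article a WHERE a.color = :c"),
               class = "biocurate_ql_error")
  expect_error(parse_ql("SELECT a FROM Article a WHERE b.pmid = :p"),
               class = "biocurate_ql_error")
  expect_error(parse_ql("DELETE FROM Article"),
               class = "biocurate_ql_error")

  # parse errors carry the character offset of the offending token
  err <- tryCatch(parse_ql("SELECT x FROM Article a"),
                  biocurate_ql_error = identity)
  expect_identical(err$offset, 23L)
})

test_that("predicate queries equal a linear scan over the full store", {
  st <- entity_store()
  on.exit(store_close(st))
  cases <- random_entities("aneurisk-csv", 60L, seed = 11L)
  for (cs in cases) persist(st, cs)

  all_cases <- run_query(st, parse_ql("SELECT p FROM Aneurysm p"))
  expect_length(all_cases, length(unique(
    vapply(cases, entity_key, character(1)))))

  plan <- parse_ql("SELECT p FROM Aneurysm p WHERE p.patientID = :patientID")
  for (target in sample(vapply(cases, entity_key, character(1)), 10L)) {
    got <- run_query(st, plan, list(patientID = target))
    oracle <- Filter(function(cs) cs$patient_id == target, all_cases)
    expect_identical(length(got), length(oracle))
    expect_case_equal(got[[1]], oracle[[1]])
  }

  # unmatched parameter: analytically empty, not an error
  expect_identical(run_query(st, plan, list(patientID = "CD0985674")), list())
  # unbound parameter is an error
  expect_error(run_query(st, plan), class = "biocurate_ql_error")
})

test_that("results come back in insertion order", {
  st <- entity_store()
  on.exit(store_close(st))
  arts <- random_entities("pubmed-xml", 6L, seed = 5L)
  for (a in arts) persist(st, a)
  got <- run_query(st, parse_ql("SELECT a FROM Article a"))
  expect_identical(vapply(got, entity_key, character(1)),
                   vapply(arts, entity_key, character(1)))
})
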