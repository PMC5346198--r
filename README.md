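# biocurate

A framework for rapid curation of **specialized biological databases** —
curated datasets that serve one research community by mixing newly generated
data with records derived from established repositories.

Researchers building such databases keep re-solving the same four problems.
biocurate packages them as composable layers:

1. **Query model** — a declarative search intent: repository, search type
   (`SEARCH` for term-based identifier discovery, `FETCH` for record
   retrieval by identifier), free-text terms, field constraints, ids.
2. **Structured URL interfaces** — deterministic translation of a query
   into a repository's fixed URL syntax (NCBI Entrez eUtils
   `esearch`/`efetch`, MalaCards, BioModels), executed through a pluggable
   transport so live HTTP and offline fixtures are interchangeable.
3. **Record parsers** — typed syntactic analysis of the retrieved or local
   documents: PubMed efetch XML → `article`, disease-card HTML →
   `disease`, model XML → `biomodel`, clinical CSV (through a column
   manifest with value decoders) → `aneurysm_case`, and STL surface meshes
   (ASCII and binary, auto-detected) → `tri_mesh`.
4. **Persistent agent** — an object-relational mapping of the user-defined
   entity schema onto an embedded SQLite store, answering a small SQL-like
   query language:

   ```
   SELECT <alias> FROM <Kind> <alias> [WHERE <alias>.<field> = :<param>]
   ```

The demonstration schema is an aneurysm database: clinical cases associated
many-to-many with articles, diseases and mathematical models, plus a
geometry reference and an externally computed rupture-risk score per case.
A fixture generator emulates every document format, so the entire pipeline
runs and is tested without network access.

## Worked example

Fetch two articles by PMID, persist them, and query them back — here served
from a fixture so the example is reproducible offline:

```r
library(biocurate)

q <- query("PUBMED", "FETCH")
q <- add_id(q, "23371018")
q <- add_id(q, "10227670")
req <- build_entrez_url(q)
req$url
#> [1] "http://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi?db=pubmed&id=23371018,10227670&retmode=xml"

transport <- fixture_transport(setNames(
  list(fixture_spec("pubmed-xml", demo_articles())), req$url))
articles <- parse_pubmed_articles(execute_request(req, transport))

st <- entity_store()                       # ":memory:"; pass a path for durability
for (a in articles) persist(st, a)
found <- run_query(st, parse_ql("SELECT a FROM Article a"))
cat(render_cards(found))
#> ---------------------------------------
#> ID: 23371018
#> TITLE: Non-dimensional analysis of retinal microaneurysms: critical threshold for treatment.
#> AUTHOR: Ezra Elishai
#> JOURNAL: Integrative biology : quantitative biosciences from nano to macro 5(3), 2013, DOI: 10.1039/c3ib20259c
#> ---------------------------------------
#> ID: 10227670
#> TITLE: Three dimensional analysis of microaneurysms in the human diabetic retina.
#> AUTHOR: Moore JJ
#> JOURNAL: Journal of anatomy 194 (Pt 1)(?), 1999, DOI: ?
#> ---------------------------------------
```

The second card shows the unknown marker: the 1999 record has no issue or
DOI, stored internally as typed absent values and rendered as `?`.

Patient-centric retrieval pulls a case together with everything associated
to it:

```r
cs <- demo_cases()[[1]]                          # C0004: F, 60, TER/ICA, unruptured
cs <- associate(cs, articles[[1]], "case-article")
cs <- attach_risk_score(cs, 0.73)
persist(st, cs)                                  # cascades to associated records

hit <- run_query(st,
  parse_ql("SELECT p FROM Aneurysm p WHERE p.patientID = :patientID"),
  list(patientID = "C0004"))
hit[[1]]$risk_score       #> [1] 0.73
length(hit[[1]]$articles) #> [1] 1
store_close(st)
```

A shell interface with the same capabilities is installed as
`exec/biocurate` (`search`, `persist`, `query`, `render`, `fixtures`
subcommands); run it without arguments for usage.

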