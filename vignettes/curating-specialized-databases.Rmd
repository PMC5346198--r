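---
title: "Curating a specialized biological database with biocurate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating a specialized biological database with biocurate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biocurate)
```

## The problem

Specialized databases — curated datasets serving one research community —
mix newly generated data with records derived from established repositories.
Building one means repeatedly solving the same four problems: expressing
searches against heterogeneous repositories, parsing the documents they
return, modelling the relations between the resulting entities, and storing
the whole schema somewhere durable and queryable. biocurate packages those
four layers and demonstrates them end to end on an aneurysm database: a
clinical case hub linked to literature, associated human diseases,
mathematical models, 3-D sac geometry and an externally computed
rupture-risk score.

## The query model and structured URL interfaces

A search intent is a value of class `biocurate_query`: a target repository
(from a user-extensible registry), a search type (`SEARCH` discovers record
identifiers from terms; `FETCH` retrieves full records for known
identifiers), free-text terms, field-constrained terms, and identifiers.
`validate_query()` returns invariant violations as data — a fetch query must
carry ids and nothing else; a search query needs at least one term or field
constraint; ids are unique, non-empty strings.

Repositories with a fixed URL syntax are driven through translators. For
the Entrez eUtils grammar:

```{r entrez}
q <- query("PUBMED", "FETCH")
q <- add_id(q, "23371018")
q <- add_id(q, "10227670")
build_entrez_url(q)$url
```

Search URLs put field constraints (rendered `value[tag]`, joined by `+`)
before free-text terms (joined by `+AND+`, or `+OR+` when the query's
connector is OR):

```{r esearch}
s <- add_field(add_field(add_term(add_term(query("PUBMED"),
  "breast"), "cancer"), "JOURNAL", "science"), "PUBLICATION_DATA", "2009")
build_entrez_url(s)$url
```

Three encoding decisions are deliberate. Brackets and `+` separators are
emitted literally rather than percent-encoded, matching the eUtils house
style; spaces inside values become `+`, which makes the encoding lossy (a
two-word term and two one-word terms can collide), so the URL round-trip
guarantee — `parse_entrez_url()` recovering the query — is stated for
single-word terms; and the connector is only recoverable from a URL when at
least two terms are present. The Entrez base URL defaults to the classic
`http://eutils.ncbi.nlm.nih.gov/entrez/eutils` form and, like the MalaCards
and BioModels templates, is a plain-text configuration entry
(`inst/extdata/endpoints.conf`) because those services relocate more often
than their grammars change. `NOT` is not offered as a connector; the
supported language is the conjunctive/disjunctive core that covers
identifier fetches and fielded searches.

The core never opens a socket. A *transport* is any function from a
`structured_request` to payload bytes; `http_transport()` is the live
implementation and `fixture_transport()` serves an in-memory URL map, which
is what every example and test in this package uses.

## Record parsers

Each parser does syntactic analysis only and maps missing optional elements
to a typed unknown (`NA`), never an empty string; the `?` seen on rendered
cards is applied at render time.

* `parse_pubmed_articles()` reads the efetch article dialect with xml2. All
  authors are kept; the DOI is taken from `ELocationID[@EIdType="doi"]`
  with a fallback to the article id list. MeSH terms, grants and chemical
  lists are out of scope.
* `parse_malacards_diseases()` scrapes anchors whose `href` matches the
  relative card pattern `/card/<slug>?search=<term>` from a lenient
  (libxml2 HTML) tree, preserving page order — scraped pages are not
  guaranteed well-formed, and the anchor pattern is the asserted interface
  since the page structure itself is not a published contract.
* `parse_biomodels()` extracts the accession and the notes text and keeps
  the XML payload opaque; SBML semantics are deliberately not interpreted.
* `parse_aneurisk_clinical()` reads a comma-delimited, headered, UTF-8
  table through a `column_manifest()` that maps case fields to source
  columns and decodes coded values. A missing mandatory column fails before
  any row is read; a row violating the clinical code vocabulary (sex F/M,
  type TER/LAT, status U/R, non-negative age) is rejected with a
  row-numbered diagnostic while valid rows are still returned — curation
  input is dirty, and silently dropping or silently keeping bad rows are
  both wrong.
* `load_stl()` reads both STL dialects. Detection is structural: a payload
  starting with `solid` and containing no NUL byte is ASCII, anything else
  is binary (80-byte header, little-endian `uint32` facet count, 50 bytes
  per facet). A binary count inconsistent with the payload length is
  reported as truncation rather than silently clipped. Meshes are triangle
  soups; repair, decimation and geometric measures are out of scope.

## The entity schema and persistent agent

The demonstration schema registers four kinds — `Article`, `Disease`,
`BioModel` and the case kind, registered under the query name `Aneurysm`
with field `patientID` — and three association labels (`case-article`,
`case-disease`, `case-model`). Associations are many-to-many relation
records: the natural cardinality when one article can discuss many cases.
They are unordered sets per label, de-duplicated by natural key, and
kind-checked at `associate()` time. Geometry is linked by reference (a
stored path), not embedded in rows; the risk score is an externally supplied
finite scalar, since the underlying fluid-dynamics criterion is published
separately and is not re-implemented here.

`entity_store()` maps the schema onto an embedded single-file SQLite
database — one table per kind, one per association label, with foreign keys
enforced. `persist()` is an upsert on the natural key, and persisting a case
cascades to its associated records before the relation rows are written, so
referential integrity holds by construction (`store_integrity()` verifies it
from the tables directly). A monotone `seq` column, untouched by updates,
fixes result order to insertion order; SQLite guarantees none, and
deterministic order keeps both tests and user-facing listings stable.

The query language is deliberately the demonstrated subset and nothing
more:

```
SELECT <alias> FROM <Kind> <alias> [WHERE <alias>.<field> = :<param>]
```

Keywords are case-insensitive, aliases case-sensitive, string comparison
exact and case-sensitive, and parse errors carry the character offset of the
offending token. There are no joins or ordering clauses: association
traversal replaces joins, because a case returned by `run_query()` comes
back with its articles, diseases and models attached.

```{r store}
st <- entity_store()
cs <- associate(demo_cases()[[1]], demo_articles()[[1]], "case-article")
persist(st, attach_risk_score(cs, 0.73))
hit <- run_query(st,
  parse_ql("SELECT p FROM Aneurysm p WHERE p.patientID = :patientID"),
  list(patientID = "C0004"))
length(hit[[1]]$articles)
store_close(st)
```

## Rendering and the command line

`render_card()` produces the dashed record cards (separator fixed at 39
hyphens, matching the terminal listings this layout comes from). Rendering
is pure — no store access, and every printed value is recoverable from the
entity. Model descriptions are stored in full and truncated only at render
time, at a configurable 80 characters with a trailing ellipsis; the source
catalogue prints truncated descriptions without stating a limit, so the
length is a knob rather than a contract. The `exec/biocurate` script exposes
the layers as `search`, `persist`, `query`, `render` and `fixtures`
subcommands; it is a thin wrapper over `cli_main()`, so the whole interface
is exercised in-process by the test suite.

## The fixture generator

`generate_fixture()` emits synthetic documents in all six supported formats
(PubMed-dialect XML, results-page HTML, model XML, clinical CSV, ASCII and
binary STL). The dialects are minimal but structurally faithful — the
element names and nesting a real consumer would see — and the binding
contract is the round trip: `parse(generate(spec))` recovers the records.
Random payloads draw free text from a fixed word list and geometry from
jittered unit-sphere triangles, under a private seeded RNG stream, so equal
specs render byte-identically and generation never disturbs the session
generator. Mesh coordinates are rounded to four decimals so text (`%.9g`)
and binary (float32) serializations carry them losslessly.

What the fixtures do not emulate matters for interpreting green tests: no
eUtils error payloads, pagination or history sessions; no real MalaCards
page chrome beyond decoy navigation anchors; no SBML model internals; and
clinical tables with exactly the manifest's columns. Passing the suite shows
the machinery is correct against the documented dialects, not that any live
service still serves them — live retrieval goes through the same
`execute_request()` path with `http_transport()` and inherits its typed
failure contract.

## Demonstration payloads and problem sizes

The bundled demonstration records (`demo_articles()`, `demo_diseases()`,
`demo_biomodels()`, `demo_cases()`) are the worked example the package is
documented around: two retinal-microaneurysm articles (one with unknown
issue and DOI, exercising the unknown marker), seven aneurysm-associated
diseases, two BioModels entries whose descriptions are completed
synthetically beyond their catalogue prefixes, and five clinical cases
C0004–C0008. The property suite runs 200 randomized payloads per document
format, persistence oracles on stores of up to 100 entities, and 100
randomized URL round trips — sizes chosen so the full suite stays
interactive (under a minute) while each property sees all the optional-field
and dialect branches many times over.

## Known limitations

Single-process use only: no transactions or concurrency guarantees beyond
SQLite's own. No schema migration; the entity kinds are fixed at
registration. The SQL-like subset has one predicate and no joins by design.
The MalaCards interface is an asserted anchor pattern, not a published API,
and will drift with the site. Live Entrez use beyond trivial volumes would
need API keys and rate limiting, which are out of scope.
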