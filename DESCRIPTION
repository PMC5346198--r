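Package: biocurate
Title: Rapid Curation of Specialized Biological Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for rapid development of specialized biological
    databases. Search intents are expressed as query objects and translated
    into the structured URL syntaxes of remote repositories (NCBI Entrez
    eUtils, MalaCards, BioModels); typed parsers turn the retrieved or local
    documents (PubMed article XML, disease-card HTML, model XML, clinical CSV
    tables, STL surface meshes) into entity records; a user-defined entity
    schema links aneurysm cases to articles, diseases, models, geometry and
    risk scores; and a persistent agent maps the schema onto an embedded
    relational store queryable with a small SQL-like language. A fixture
    generator emulates every supported document format so the whole pipeline
    runs and is tested without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    DBI,
    RSQLite,
    xml2,
    jsonlite
Suggests:
    curl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
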