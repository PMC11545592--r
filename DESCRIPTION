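Package: fecaldiet
Title: Diet Analysis from Faecal DNA Metabarcoding Read Counts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for predator diet studies based on faecal DNA
    metabarcoding. Provides quality filtering of OTU read-count tables
    (relative read-count threshold, BLAST identity threshold, host and
    contaminant exclusion), harmonisation of taxonomic assignments against
    field-survey species lists, genus-level prey tables, dietary metrics
    (frequency of occurrence, relative read abundance), Costello graphical
    feeding-strategy analysis via prey-specific abundance, Jacobs's prey
    selectivity index against field availability, Mann-Whitney U comparison
    of prey groups, rarefaction curves, and a Dirichlet-multinomial
    simulator of faecal metabarcoding datasets with known truth.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
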