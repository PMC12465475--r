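Package: rxnemap
Title: Map a National Drug Terminology to OMOP RxNorm/RxNorm Extension Concepts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semiautomated mapping of a national drug product terminology
    (products with ingredients, strengths, ATC references, dose forms, brands
    and pack quantities) to standardized OMOP RxNorm and RxNorm Extension
    concepts at the finest attainable concept class. Provides an indexed
    OMOP-vocabulary concept store with hierarchy traversal and
    finest-common-ancestor queries, five ingredient-mapping strategies
    (ATC lateral links, exact and translated name matching, CAS registry
    bridging, brand-derived mapping), probabilistic dose-form voting,
    tokenized brand prefix search, strength/quantity/box-size refinement along
    the drug concept hierarchy, Usagi-style CSV and HL7 FHIR ConceptMap
    (R4B/R5) interchange, a common-ancestor cross-validation comparator, and a
    deterministic synthetic fixture-world generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
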