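Package: i2b2fhir
Title: FHIR Search Layer over an i2b2 Clinical Data Warehouse
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exposes the diagnosis and medication-order content of an i2b2
    star-schema clinical data warehouse as FHIR DSTU2 resources. Loads the
    five targeted i2b2 tables (observation_fact plus the patient, visit,
    concept and provider dimensions) from CSV, answers FHIR search URLs for
    DiagnosticReport and MedicationOrder with simple and chained search
    parameters and '_include' directives, packages referenced Patient,
    Encounter and Medication resources as contained or external Bundle
    entries, and serializes searchset Bundles to FHIR JSON and XML. Medication
    codings are enriched from CIP (the French medication presentation code) to
    ATC through a crosswalk table. A seeded synthetic-warehouse generator with
    a ground-truth manifest supports testing every query without hospital
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    httpuv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
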