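# i2b2fhir

A FHIR search layer over an i2b2 clinical data warehouse, in R.

Hospital data warehouses built on i2b2 keep everything in a star schema: one
central `observation_fact` table in entity–attribute–value form, surrounded
by patient, visit, concept and provider dimensions. That layout is excellent
for warehouse queries and useless for interoperable clients, which expect
standardised resources over HTTP. This package implements the bridge for the
diagnosis and medication-order slice of such a warehouse: it loads the five
targeted i2b2 tables, maps fact rows to FHIR DSTU2 resources, and answers
FHIR search URLs — simple parameters (`DiagnosticReport?code=M321`), chained
parameters through a referenced resource
(`MedicationOrder?medication.code=3400893219874`), `_include` directives,
JSON or XML — with searchset Bundles. It is aimed at health-informatics
developers who need a queryable FHIR facade over i2b2-shaped data, and at
anyone testing FHIR clients against a deterministic synthetic warehouse.

## The model

Five resources are served. Each matching fact row becomes one match entry —
the granularity is per fact, not per patient:

| i2b2 source                          | FHIR resource       |
|--------------------------------------|---------------------|
| `patient_dimension` row              | `Patient` (id `pat-<patient_num>`) |
| `visit_dimension` row                | `Encounter` (id `enc-<encounter_num>`) |
| CIP concept in `concept_dimension`   | `Medication` (id `med-<cip>`) |
| fact with `concept_cd = CIP:<code>`  | `MedicationOrder` |
| fact with `concept_cd = ICD10:<code>`| `DiagnosticReport` |

Terminology lives in three systems: ICD-10 for diagnoses
(`http://hl7.org/fhir/sid/icd-10`), CIP — the French 13-digit medication
presentation code — under a hospital-local system URI, and ATC
(`http://www.whocc.no/atc`). Facts are stored at CIP granularity; a
CIP→ATC crosswalk enriches every covered Medication with its ATC class
coding and lets an ATC-valued search expand to the union of the class's CIP
presentations.

Reference packaging follows the served presentation: with `_include`
requested, Patient and Encounter are embedded in each match's `contained`
list and referenced locally (`#pat-36`), while Medication is emitted once
per distinct drug as an external include entry referenced literally
(`Medication/med-3400893219874`).

## Worked example

```r
library(i2b2fhir)

fx <- cdw_generate(cdw_config(n_patients = 50, seed = 7))
h  <- cdw_load(fx$tables, fx$crosswalk)
h
#> <cdw> i2b2 star-schema warehouse
#>   observation_fact     384 rows
#>   patient_dimension    50 rows
#>   visit_dimension      129 rows
#>   concept_dimension    10 rows
#>   provider_dimension   8 rows
#>   cip_atc crosswalk    5 rows

fhir_search(h, "DiagnosticReport?code=M321&_include=DiagnosticReport:subject&_include=DiagnosticReport:encounter")
#> <Bundle searchset> total=19 (19 match, 0 include entries)

fhir_search(h, "MedicationOrder?medication.code=3400893219874&_include=MedicationOrder:patient&_include=MedicationOrder:encounter&_include=MedicationOrder:medication")
#> <Bundle searchset> total=35 (35 match, 1 include entries)
```

The first Bundle holds 19 DiagnosticReports — one per `ICD10:M321` fact in
the generated warehouse — each containing its Patient and Encounter. The
second holds 35 MedicationOrders for the requested CIP presentation plus a
single external Medication carrying both its CIP and ATC codings.
`to_wire(b, "xml")` / `to_wire(b, "json")` serialize a Bundle;
`handle_request()` / `fhir_app()` expose the same searches as HTTP
responses, and `serve()` runs them on a socket. A thin command-line front
end lives at `inst/cli/cdw.R` (`generate`, `stats`, `query`, `serve`).

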