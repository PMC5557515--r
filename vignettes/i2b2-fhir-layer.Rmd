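---
title: "Serving an i2b2 warehouse as FHIR resources: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serving an i2b2 warehouse as FHIR resources: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(i2b2fhir)
```

## The problem and the shape of the solution

An i2b2 clinical data warehouse stores every observation as one row of a
central fact table — who (`patient_num`), in which encounter
(`encounter_num`), which concept (`concept_cd`), recorded by whom, over
which time range — surrounded by dimension tables for patients, visits,
concepts and providers. Concepts follow the entity–attribute–value pattern:
a diagnosis and a drug order are both just fact rows whose `concept_cd`
points into different terminology branches.

This package exposes the diagnosis/medication-order slice of such a
warehouse through the FHIR DSTU2 search interface. The pipeline has four
stages, each a module with its own surface:

1. **Store** (`cdw_load()`, `find_observations_by_*()`): an in-memory
   relational representation of the five targeted tables. All referential
   integrity is validated at load time, so the query layer can assume clean
   joins. The three find operations — by ICD-10 code, by CIP code, by ATC
   class — return fact rows star-joined to their dimensions in a fixed
   order.
2. **Mapping** (`to_patient()` and friends): the field-level transform to
   FHIR. One fact row yields one DiagnosticReport or one MedicationOrder;
   patients, encounters and medications are derived from the joined
   dimension columns.
3. **Search** (`parse_search_request()`, `execute_search()`,
   `package_references()`): FHIR URL parsing, filter dispatch, and Bundle
   assembly with `_include` packaging.
4. **Serialization** (`to_wire()`, `from_wire()`): dual JSON/XML wire
   formats with exact round-trips.

A fifth module, the synthetic generator (`cdw_generate()`), stands in for a
hospital warehouse so that every behaviour above is testable end to end.

## Conventions the mapping relies on

**Concept namespaces.** `concept_cd` values are prefixed with their
terminology: `ICD10:M321`, `CIP:3400893219874`. Production i2b2 sites each
have their own local prefixes; a fixed convention is needed to dispatch a
search value to the right terminology, and the colon-separated form is the
simplest that keeps the raw code recoverable.

**Deterministic ids.** Resource ids are pure functions of source keys:
`pat-<patient_num>`, `enc-<encounter_num>`, `med-<cip>`, and for the two
fact-level resources a composite of the full fact key
(`dr-<patient>-<encounter>-<code>-<yyyymmdd>-<instance>`). This makes
repeated queries byte-stable, makes the read interaction
(`GET /DiagnosticReport/<id>`) a key lookup rather than a search, and gives
Bundle-level deduplication a meaningful identity.

**Per-fact granularity.** Result counts in this kind of layer are fact
counts, not patient counts — a patient with three lupus diagnoses on record
produces three DiagnosticReports. No aggregation rule is applied; the
distinct-patient count is always recoverable from the subject references
and is what the tests compare against ground truth.

**DiagnosticReport for diagnoses.** Diagnoses ride on DiagnosticReport
(with exactly one ICD-10 coding), not on Condition. This mirrors the
serving convention of the i2b2 FHIR deployments this package models; it is
nonstandard FHIR practice but preserved deliberately, since the point of
the layer is fidelity to that presentation.

**Effective dates.** A report's `effectiveDateTime` and an order's
`dateWritten` are the fact's `start_date`, not the visit's period. The
fact date is the clinically precise one; the visit period is still
available on the contained Encounter. Missing end dates (open encounters,
point-event facts) are simply omitted — never serialized as null.

**Gender.** `M`/`F`/`U` map to `male`/`female`/`unknown`; anything else
degrades to `unknown` rather than erroring, because a search across a
dirty dimension table must not fail on one malformed row.

## Search semantics

Two resource types are searchable. `DiagnosticReport?code=` is a *simple*
parameter: it filters on a field of the sought resource itself.
`MedicationOrder?medication.code=` is a *chained* parameter (one hop): it
filters on the code of the Medication the order references.

The chained value needs a terminology dispatch rule, since both CIP
presentations and ATC classes are legitimate medication codes: a value of
13 digits is treated as CIP, a value matching the ATC pattern
(letter, two digits, two letters, two digits) as ATC, and an explicit
`system|code` prefix overrides the shape rule. An ATC search expands
through the crosswalk to all CIP presentations of the class and returns
their union. A value matching neither shape is a valid search that matches
nothing — FHIR search semantics make "no such code" an empty Bundle, not an
error — while an *empty* value is a 400-class error.

Parsing is strict: unknown resource types are 404-class, unknown or
repeated parameters 400-class, and `_include` directives must name the
searched type and one of its reference parameters. FHIR permits lenient
servers; strictness was chosen so that client mistakes surface as errors
instead of silently ignored filters.

`_count` caps the returned matches after the deterministic ordering
(`patient_num`, `encounter_num`, `start_date`, `instance_num`); there is no
pagination, and `total` always equals the number of match entries actually
in the Bundle.

## Reference packaging

With `_include` requested, two different mechanisms are used on purpose:

- Patient and Encounter are **contained**: embedded in each match's
  `contained` list and referenced locally (`subject = "#pat-36"`). When
  both are contained, the Encounter's own patient reference is rewritten to
  the sibling's local id, keeping the match self-contained.
- Medication is **external**: emitted once per distinct drug as a Bundle
  include entry at the end, referenced literally
  (`Medication/med-3400893219874`) from every order of that drug.

This asymmetry reproduces the presentation this layer models (containment
duplicates the Patient into every match; the shared Medication is
deduplicated instead). A `fhir_config(packaging = "external")` switch turns
containment off for clients that prefer everything as include entries.
Includes are honored strictly: related resources that were not requested
stay as literal references and are not shipped.

## Serialization

JSON uses the DSTU2 field names with a `resourceType` discriminator; XML
uses the FHIR namespace with value attributes, contained resources nested
before the parent's own data elements. Absent fields are omitted entirely
in both formats, field order is fixed by the constructors, and
pretty-printing is off by default, so repeated GETs are byte-identical.
`from_wire()` rebuilds objects through the same constructors, which is what
makes `from_wire(to_wire(r, f))` structurally identical to `r` for both
formats and makes the two formats parse back to equal structures. An
invalid resource is refused at serialization time with its validation
violations; full XSD/schematron validation is out of scope because the
served resources are a deliberately trimmed profile of DSTU2.

## The synthetic warehouse

`cdw_generate()` emulates the served slice of a hospital warehouse at desk
scale. Defaults (all overridable through `cdw_config()`):

- 200 patients, 70% of them aged 75–95 at the window start (the layer's
  motivating client targets medication surveillance in the elderly; the
  skew affects only birth dates), the rest 18–74; sex `M`/`F`/`U` at
  48/48/4%.
- 1–4 encounters per patient, starting uniformly in a 2014–2016 window;
  lengths of 1–30 days with a geometric tail (most stays short, a few
  long); 5% of encounters left open (no end date).
- 1–5 facts per encounter, half diagnoses and half drug orders; codes drawn
  from weighted pools of five ICD-10 codes and five CIP presentations
  (two of which share the ATC class C07AB07, so class-level queries have a
  genuine union to return). The pools include ICD-10 `M321` and CIP
  `3400893219874` so the canonical search URLs run verbatim against any
  fixture.
- Fact dates uniform within the encounter period (within 14 days of
  admission for open encounters); repeated same-day orders are
  disambiguated by `instance_num`, as in standard i2b2 practice.

None of these distributions is calibrated to a real case mix — the
generator's job is referential integrity, temporal consistency and known
ground truth, not epidemiology. The manifest (`ground_truth`) records
per-table row counts and, for every code and every ATC class, the fact and
distinct-patient counts obtained by a full scan of the emitted table; the
tests recount independently.

`fixed_counts` pins a code to an exact shape — *n* facts over exactly *m*
distinct patients — by giving each selected patient one anchor fact and
spreading the remainder inside the selection, while removing the pinned
code from the random pools. This is how the canonical two-query scenario
(503 orders / 290 patients, 80 reports / 36 patients) is replayed: the
fixture, not any hospital, defines the ground truth, and the layer must
reproduce it exactly.

Passing tests on this generator show that the query, mapping, packaging and
serialization machinery is exact on schema-conformant data. They do not
show robustness to the messiness of a production warehouse — multi-valued
local prefixes, modifier codes, numeric lab values, free-text reports and
encoding noise are all outside the generated (and served) scope.

## Verification approach and problem sizes

The package is validated the way such a layer is validated in the field:
every served search is compared against an independent brute-force
scan-filter-join of the raw tables (the in-package equivalent of checking
the server against ad-hoc SQL). The test suite runs this oracle comparison
over twenty 1,000-patient warehouses (roughly 7,000–8,000 facts each, every
generated code, both search forms), replays the pinned two-query scenario,
walks every reference in over 10,000 packaged resources, and round-trips
1,000 generated resources through both wire formats; these sizes keep the
whole suite in the low minutes on a single core while exercising result
sets in the hundreds of matches. `scripts/acceptance.R` re-runs the same
computations from scratch and writes the headline numbers as JSON.

## Known limitations

- Read-only: search and read interactions only; no write, history,
  versioning or transaction Bundles.
- Two searchable types; Patient, Encounter and Medication are served as
  referenced/contained resources and by direct read, not by search.
- No pagination, no `_sort`, no token modifiers; `_count` is a cap.
- No security layer (authentication/authorization are deployment concerns
  outside this package).
- Terminology enrichment covers CIP→ATC only; display labels come from the
  concept dimension, not from a terminology service.
- The provider dimension is loaded and validated but not served as a FHIR
  Practitioner.
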