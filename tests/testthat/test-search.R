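# URL parsing, search execution and reference packaging.

URL_Q1 <- "DiagnosticReport?code=M321&_include=DiagnosticReport:subject&_include=DiagnosticReport:encounter"
URL_Q2 <- "MedicationOrder?medication.code=3400893219874&_include=MedicationOrder:patient&_include=MedicationOrder:encounter&_include=MedicationOrder:medication"

test_that("the two canonical search URLs parse into the expected queries", {
  q1 <- parse_search_request(URL_Q1)
  expect_equal(q1$resource_type, "DiagnosticReport")
  expect_equal(q1$filters, c(code = "M321"))
  expect_setequal(q1$includes, c("subject", "encounter"))
  expect_equal(q1$format, "json")

  q2 <- parse_search_request("/fhir/base/MedicationOrder",
                             sub("^MedicationOrder\\?", "", URL_Q2))
  expect_equal(q2$resource_type, "MedicationOrder")
  expect_equal(q2$filters, c(medication.code = CIP_A))
  expect_setequal(q2$includes, c("patient", "encounter", "medication"))
})

test_that("parsing is strict: unknown types 404, unknown or bad parameters 400", {
  expect_error(parse_search_request("/Observation?code=x"),
               class = "fhir_error_404")
  expect_error(parse_search_request("/DiagnosticReport?subject=36"),
               class = "fhir_error_400", regexp = "subject")
  expect_error(parse_search_request("/DiagnosticReport?code="),
               class = "fhir_error_400", regexp = "empty")
  expect_error(parse_search_request("/DiagnosticReport?_include=MedicationOrder:patient"),
               class = "fhir_error_400")
  expect_error(parse_search_request("/DiagnosticReport?_format=yaml"),
               class = "fhir_error_400")
  expect_error(parse_search_request("/MedicationOrder?code=M321"),
               class = "fhir_error_400")
})

test_that("simple code search returns one match per fact with the right totals", {
  h <- mini_cdw()
  b <- fhir_search(h, URL_Q1)
  expect_equal(b$total, 3L)
  want <- oracle_tuples(oracle_scan(mini_tables(), "ICD10", "M321"))
  expect_same_multiset(bundle_tuples(b), want)

  b0 <- fhir_search(h, "DiagnosticReport?code=Z999")
  expect_equal(b0$total, 0L)
  expect_length(b0$entry, 0L)
})

test_that("matched reports contain exactly their Patient and Encounter when both includes are requested", {
  h <- mini_cdw()
  b <- fhir_search(h, URL_Q1)
  for (e in Filter(function(e) e$search$mode == "match", b$entry)) {
    r <- e$resource
    types <- vapply(r$contained, `[[`, character(1), "resourceType")
    expect_setequal(types, c("Patient", "Encounter"))
    expect_length(r$contained, 2L)
    expect_true(startsWith(r$subject$reference, "#"))
    expect_true(startsWith(r$encounter$reference, "#"))
    expect_equal(resolve_reference(r, r$subject)$resourceType, "Patient")
    expect_equal(resolve_reference(r, r$encounter)$resourceType, "Encounter")
  }
})

test_that("chained medication search packages one external Medication per distinct drug", {
  h <- mini_cdw()
  b <- fhir_search(h, URL_Q2)
  expect_equal(b$total, 2L)
  incs <- Filter(function(e) e$search$mode == "include", b$entry)
  expect_length(incs, 1L)
  expect_equal(incs[[1]]$resource$resourceType, "Medication")
  for (e in Filter(function(e) e$search$mode == "match", b$entry)) {
    ref <- e$resource$medicationReference$reference
    expect_match(ref, "^Medication/")
    expect_equal(resolve_reference(b, ref)$id, incs[[1]]$resource$id)
  }
  # ATC value expands through the crosswalk to the union of its CIP children
  b_atc <- fhir_search(h, "MedicationOrder?medication.code=C07AB07&_include=MedicationOrder:medication")
  expect_equal(b_atc$total, 3L)
  incs_atc <- Filter(function(e) e$search$mode == "include", b_atc$entry)
  expect_length(incs_atc, 2L) # two distinct presentations in the class
})

test_that("explicit system|code syntax overrides the shape dispatch", {
  h <- mini_cdw()
  via_uri <- fhir_search(h, paste0(
    "MedicationOrder?medication.code=",
    utils::URLencode("http://www.whocc.no/atc|C07AB07", reserved = TRUE)))
  expect_equal(via_uri$total, 3L)
  via_cip <- fhir_search(h, paste0(
    "MedicationOrder?medication.code=",
    utils::URLencode(paste0("http://cip.hegp.fr|", CIP_A), reserved = TRUE)))
  expect_equal(via_cip$total, 2L)
  expect_error(
    fhir_search(h, "MedicationOrder?medication.code=http://nowhere|X"),
    class = "fhir_error_400")
})

test_that("no includes requested: empty contained lists and literal references", {
  h <- mini_cdw()
  b <- fhir_search(h, "DiagnosticReport?code=M321")
  expect_length(Filter(function(e) e$search$mode == "include", b$entry), 0L)
  for (e in b$entry) {
    expect_null(e$resource$contained)
    expect_match(e$resource$subject$reference, "^Patient/")
    expect_match(e$resource$encounter$reference, "^Encounter/")
  }
})

test_that("all-external packaging emits deduplicated include entries instead of containment", {
  h <- mini_cdw()
  b <- fhir_search(h, URL_Q1, config = fhir_config(packaging = "external"))
  expect_equal(b$total, 3L)
  incs <- Filter(function(e) e$search$mode == "include", b$entry)
  # three matches over one patient and two encounters
  expect_setequal(vapply(incs, function(e) e$resource$id, character(1)),
                  c("pat-36", "enc-501", "enc-502"))
  for (e in Filter(function(e) e$search$mode == "match", b$entry)) {
    expect_null(e$resource$contained)
  }
  expect_identical(validate_resource(b), character(0))
})

test_that("_count caps the result after deterministic ordering and total tracks the entries", {
  h <- mini_cdw()
  b <- fhir_search(h, "DiagnosticReport?code=M321&_count=2")
  expect_equal(b$total, 2L)
  full <- fhir_search(h, "DiagnosticReport?code=M321")
  first_two <- lapply(Filter(function(e) e$search$mode == "match", full$entry)[1:2],
                      `[[`, "resource")
  expect_identical(lapply(Filter(function(e) e$search$mode == "match", b$entry),
                          `[[`, "resource"),
                   first_two)
  capped <- fhir_search(h, "DiagnosticReport?code=M321",
                        config = fhir_config(count_cap = 1))
  expect_equal(capped$total, 1L)
})

test_that("repeating a search yields a byte-identical serialized body", {
  h <- mini_cdw()
  b1 <- to_wire(fhir_search(h, URL_Q2), "json")$body
  b2 <- to_wire(fhir_search(h, URL_Q2), "json")$body
  expect_identical(b1, b2)
  x1 <- to_wire(fhir_search(h, URL_Q1), "xml")$body
  x2 <- to_wire(fhir_search(h, URL_Q1), "xml")$body
  expect_identical(x1, x2)
})
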