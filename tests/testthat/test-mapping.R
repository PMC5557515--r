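# The i2b2-to-FHIR field transform.

ctx <- terminology_context(mini_crosswalk())

test_that("sex codes map onto the administrative-gender ValueSet, degrading to unknown", {
  expect_equal(map_gender(c("M", "F", "U", "", "X", NA)),
               c("male", "female", "unknown", "unknown", "unknown", "unknown"))
})

test_that("patient mapping transcribes demographics with a deterministic id", {
  p <- list(patient_num = 36L, birth_date = "1941-03-02", sex_cd = "F")
  r <- to_patient(p, ctx)
  expect_equal(r$id, "pat-36")
  expect_equal(r$gender, "female")
  expect_equal(r$birthDate, "1941-03-02")
  expect_equal(r$identifier$code, "36")
  expect_identical(validate_resource(r), character(0))
  expect_identical(to_patient(p, ctx), r)

  r2 <- to_patient(list(patient_num = 1L, birth_date = "2000-01-01",
                        sex_cd = "X"), ctx)
  expect_equal(r2$gender, "unknown")
})

test_that("encounter mapping keeps the period exact and omits an absent end", {
  v <- list(encounter_num = 502L, patient_num = 36L,
            start_date = "2015-09-10", end_date = NA_character_)
  r <- to_encounter(v, ctx)
  expect_equal(r$id, "enc-502")
  expect_equal(r$period$start, "2015-09-10")
  expect_false("end" %in% names(r$period))
  expect_equal(r$patient$reference, "Patient/pat-36")

  closed <- to_encounter(list(encounter_num = 501L, patient_num = 36L,
                              start_date = "2015-06-01", end_date = "2015-06-08"),
                         ctx)
  expect_equal(closed$period$end, "2015-06-08")
  expect_identical(validate_resource(closed), character(0))
})

test_that("medication coding carries CIP always, ATC iff the crosswalk covers it", {
  r <- to_medication(list(concept_cd = paste0("CIP:", CIP_A),
                          name_char = "BISOPROLOL BGR 1.25MG CPR"), ctx)
  expect_length(r$code$coding, 2L)
  expect_equal(r$code$coding[[1]]$system, "http://cip.hegp.fr")
  expect_equal(r$code$coding[[1]]$code, CIP_A)
  expect_equal(r$code$coding[[1]]$display, "BISOPROLOL BGR 1.25MG CPR")
  expect_equal(r$code$coding[[2]]$system, "http://www.whocc.no/atc")
  expect_equal(r$code$coding[[2]]$code, "C07AB07")

  uncovered <- to_medication(list(concept_cd = "CIP:9999999999999",
                                  name_char = "MYSTERY DRUG"), ctx)
  expect_length(uncovered$code$coding, 1L)

  expect_error(to_medication(list(concept_cd = "ICD10:M321", name_char = "x"), ctx),
               class = "cdw_argument_error")
})

test_that("diagnostic-report mapping is a per-fact transcription", {
  j <- list(patient_num = 36L, encounter_num = 501L, concept_cd = "ICD10:M321",
            start_date = "2015-06-01", instance_num = 1L,
            name_char = "Systemic lupus erythematosus")
  r <- to_diagnostic_report(j, ctx)
  expect_equal(r$code$coding[[1]]$code, "M321")
  expect_equal(r$effectiveDateTime, "2015-06-01")
  expect_equal(r$subject$reference, "Patient/pat-36")
  expect_equal(r$encounter$reference, "Encounter/enc-501")
  expect_identical(validate_resource(r), character(0))

  # two facts with the same code but different dates give two distinct reports
  j2 <- j; j2$start_date <- "2015-09-12"; j2$encounter_num <- 502L
  expect_false(identical(to_diagnostic_report(j2, ctx)$id, r$id))

  j3 <- j; j3$concept_cd <- paste0("CIP:", CIP_A)
  expect_error(to_diagnostic_report(j3, ctx), class = "cdw_argument_error")
})

test_that("medication-order mapping shares one Medication across facts of one drug", {
  j1 <- list(patient_num = 36L, encounter_num = 501L,
             concept_cd = paste0("CIP:", CIP_A), start_date = "2015-06-02",
             instance_num = 1L, name_char = "BISOPROLOL BGR 1.25MG CPR")
  j2 <- j1; j2$encounter_num <- 502L; j2$start_date <- "2015-09-11"
  m1 <- to_medication_order(j1, ctx)
  m2 <- to_medication_order(j2, ctx)
  expect_false(identical(m1$order$id, m2$order$id))
  expect_identical(m1$medication$id, m2$medication$id)
  expect_equal(m1$order$medicationReference$reference,
               paste0("Medication/", m1$medication$id))
  expect_equal(m1$order$dateWritten, "2015-06-02")
  expect_identical(validate_resource(m1$order), character(0))

  expect_error(to_medication_order(
    list(patient_num = 1L, encounter_num = 1L, concept_cd = "ICD10:M321",
         start_date = "2015-01-01", instance_num = 1L, name_char = "x"), ctx),
    class = "cdw_argument_error")
})

test_that("every resource mapped from a generated warehouse validates cleanly", {
  fx <- cdw_generate(cdw_config(n_patients = 25L, seed = 5L))
  h <- cdw_load(fx$tables, fx$crosswalk)
  hctx <- terminology_context_from(h)
  rows <- find_observations_by_atc(h, "C07AB07")
  for (i in seq_len(min(nrow(rows), 20L))) {
    j <- i2b2fhir:::joined_row(rows, i)
    pair <- to_medication_order(j, hctx)
    expect_identical(validate_resource(pair$order), character(0))
    expect_identical(validate_resource(pair$medication), character(0))
    expect_identical(validate_resource(to_patient(j, hctx)), character(0))
    expect_identical(validate_resource(to_encounter(j, hctx)), character(0))
  }
})
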