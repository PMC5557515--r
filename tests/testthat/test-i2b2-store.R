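# Loading and the three find-observations query operations.

test_that("empty streams load to a handle with all counts zero", {
  h <- cdw_load(empty_tables())
  expect_s3_class(h, "cdw")
  expect_true(all(cdw_counts(h) == 0L))
  expect_equal(nrow(find_observations_by_icd10(h, "M321")), 0L)
})

test_that("load validates referential integrity and cites the offender", {
  tabs <- mini_tables()
  expect_error(cdw_load(tabs[names(tabs) != "observation_fact"]),
               class = "cdw_load_error", regexp = "observation_fact")

  bad <- tabs
  bad$observation_fact$patient_num[3] <- 999L
  expect_error(cdw_load(bad), class = "cdw_load_error",
               regexp = "patient_num '999'")

  bad <- tabs
  bad$visit_dimension$start_date[2] <- "10/06/2015"
  expect_error(cdw_load(bad), class = "cdw_load_error",
               regexp = "row 2.*10/06/2015")

  bad <- tabs
  bad$observation_fact$concept_cd[8] <- "CIP:0000000000000"
  expect_error(cdw_load(bad), class = "cdw_load_error", regexp = "concept_cd")

  bad <- tabs
  bad$patient_dimension$birth_date[1] <- "2016-01-01"
  expect_error(cdw_load(bad), class = "cdw_load_error", regexp = "birth date")

  bad <- tabs
  bad$observation_fact$instance_num[2] <- 1L # collides with row 1
  expect_error(cdw_load(bad), class = "cdw_load_error", regexp = "duplicate")
})

test_that("loaded counts equal the generator's manifest", {
  fx <- cdw_generate(cdw_config(n_patients = 40L, seed = 42L))
  h <- cdw_load(fx$tables, fx$crosswalk)
  expect_equal(unname(cdw_counts(h)[names(fx$ground_truth$table_counts)]),
               unname(fx$ground_truth$table_counts))
})

test_that("icd10 lookup returns exactly the joined matching facts, in stable order", {
  h <- mini_cdw()
  got <- find_observations_by_icd10(h, "M321")
  want <- oracle_scan(mini_tables(), "ICD10", "M321")
  expect_equal(nrow(got), 3L)
  expect_equal(length(unique(got$patient_num)), 1L)
  expect_equal(got[, c("patient_num", "encounter_num", "concept_cd",
                       "start_date", "instance_num")],
               want[, c("patient_num", "encounter_num", "concept_cd",
                        "start_date", "instance_num")])
  # joined dimension columns are transcribed, not recomputed
  expect_equal(unique(got$birth_date), "1941-03-02")
  expect_equal(got$visit_start_date[got$encounter_num == 501][1], "2015-06-01")
  # absent code and empty code
  expect_equal(nrow(find_observations_by_icd10(h, "Z999")), 0L)
  expect_error(find_observations_by_icd10(h, ""), class = "cdw_argument_error")
})

test_that("cip lookup matches per-fact: two encounters with the drug give two rows, one patient", {
  h <- mini_cdw()
  got <- find_observations_by_cip(h, CIP_A)
  expect_equal(nrow(got), 2L)
  expect_equal(unique(got$patient_num), 36L)
  expect_equal(sort(got$encounter_num), c(501L, 502L))
  expect_equal(nrow(find_observations_by_cip(h, "9999999999999")), 0L)
  expect_error(find_observations_by_cip(h, ""), class = "cdw_argument_error")
})

test_that("atc lookup is the crosswalk expansion: union of the CIP children", {
  h <- mini_cdw()
  got <- find_observations_by_atc(h, "C07AB07")
  want <- rbind(find_observations_by_cip(h, CIP_A),
                find_observations_by_cip(h, CIP_B))
  expect_equal(nrow(got), 3L)
  expect_setequal(
    paste(got$patient_num, got$encounter_num, got$concept_cd, got$start_date),
    paste(want$patient_num, want$encounter_num, want$concept_cd, want$start_date))
  expect_equal(nrow(find_observations_by_atc(h, "Z00ZZ00")), 0L)
  expect_error(find_observations_by_atc(h, ""), class = "cdw_argument_error")

  # a one-pair crosswalk with one matching fact yields exactly that row
  tabs <- mini_tables()
  h1 <- cdw_load(tabs, data.frame(cip_code = CIP_C, atc_code = "N02BE01"))
  expect_equal(nrow(find_observations_by_atc(h1, "N02BE01")), 1L)
})

test_that("each find operation agrees with the brute-force scan on generated warehouses", {
  for (seed in c(11L, 12L)) {
    fx <- cdw_generate(cdw_config(n_patients = 60L, seed = seed))
    h <- cdw_load(fx$tables, fx$crosswalk)
    for (cd in fx$ground_truth$codes$concept_cd) {
      ns <- sub(":.*$", "", cd)
      code <- sub("^[A-Z0-9]+:", "", cd)
      got <- if (ns == "ICD10") find_observations_by_icd10(h, code)
             else find_observations_by_cip(h, code)
      want <- oracle_scan(fx$tables, ns, code)
      expect_same_multiset(oracle_tuples(got), oracle_tuples(want))
      expect_lte(length(unique(got$patient_num)), nrow(got))
    }
    for (atc in fx$ground_truth$atc$atc_code) {
      got <- find_observations_by_atc(h, atc)
      want <- oracle_scan(fx$tables, "ATC", atc, fx$crosswalk)
      expect_same_multiset(oracle_tuples(got), oracle_tuples(want))
    }
  }
})

test_that("adding a non-matching fact leaves a query unchanged; a matching fact grows it by one", {
  tabs <- mini_tables()
  base <- nrow(find_observations_by_icd10(cdw_load(tabs, mini_crosswalk()), "M321"))

  plus_other <- tabs
  plus_other$observation_fact <- rbind(plus_other$observation_fact, data.frame(
    patient_num = 38L, encounter_num = 504L, concept_cd = "ICD10:I10",
    provider_id = "prov-1", start_date = "2016-02-22", end_date = NA_character_,
    instance_num = 1L, stringsAsFactors = FALSE))
  expect_equal(nrow(find_observations_by_icd10(cdw_load(plus_other, mini_crosswalk()), "M321")),
               base)

  plus_match <- tabs
  plus_match$observation_fact <- rbind(plus_match$observation_fact, data.frame(
    patient_num = 38L, encounter_num = 504L, concept_cd = "ICD10:M321",
    provider_id = "prov-1", start_date = "2016-02-22", end_date = NA_character_,
    instance_num = 1L, stringsAsFactors = FALSE))
  expect_equal(nrow(find_observations_by_icd10(cdw_load(plus_match, mini_crosswalk()), "M321")),
               base + 1L)
})

test_that("loading the same streams twice yields identical query answers", {
  h1 <- cdw_load(mini_tables(), mini_crosswalk())
  h2 <- cdw_load(mini_tables(), mini_crosswalk())
  expect_identical(find_observations_by_icd10(h1, "M321"),
                   find_observations_by_icd10(h2, "M321"))
  expect_identical(find_observations_by_atc(h1, "C07AB07"),
                   find_observations_by_atc(h2, "C07AB07"))
})

test_that("CSV round trip through a directory preserves every query answer", {
  fx <- cdw_generate(cdw_config(n_patients = 30L, seed = 3L))
  dir <- withr::local_tempdir()
  cdw_write_fixture(fx, dir)
  h_mem <- cdw_load(fx$tables, fx$crosswalk)
  h_csv <- cdw_load_dir(dir)
  expect_identical(cdw_counts(h_mem), cdw_counts(h_csv))
  expect_identical(find_observations_by_icd10(h_mem, "M321"),
                   find_observations_by_icd10(h_csv, "M321"))
})
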