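# Hand-laid miniature warehouse used across unit tests, plus the independent
# brute-force oracle: a merge-based full scan of the fact table that shares
# no code with the package's index-lookup query path.

CIP_A <- "3400893219874" # bisoprolol 1.25mg, ATC C07AB07
CIP_B <- "3400891942341" # bisoprolol 2.5mg, ATC C07AB07
CIP_C <- "3400935955838" # paracetamol, ATC N02BE01

mini_tables <- function() {
  list(
    patient_dimension = data.frame(
      patient_num = c(36L, 37L, 38L),
      birth_date = c("1941-03-02", "1950-07-15", "1989-11-30"),
      sex_cd = c("F", "M", "U"),
      stringsAsFactors = FALSE),
    visit_dimension = data.frame(
      encounter_num = c(501L, 502L, 503L, 504L),
      patient_num = c(36L, 36L, 37L, 38L),
      start_date = c("2015-06-01", "2015-09-10", "2016-01-05", "2016-02-20"),
      end_date = c("2015-06-08", NA, "2016-01-09", "2016-02-25"),
      stringsAsFactors = FALSE),
    concept_dimension = data.frame(
      concept_cd = c("ICD10:M321", "ICD10:I10",
                     paste0("CIP:", c(CIP_A, CIP_B, CIP_C))),
      concept_path = c("\\Diagnoses\\ICD10\\M321\\", "\\Diagnoses\\ICD10\\I10\\",
                       paste0("\\Medications\\CIP\\", c(CIP_A, CIP_B, CIP_C), "\\")),
      name_char = c("Systemic lupus erythematosus", "Essential hypertension",
                    "BISOPROLOL BGR 1.25MG CPR", "BISOPROLOL BGR 2.50MG CPR",
                    "PARACETAMOL BGR 500MG CPR"),
      stringsAsFactors = FALSE),
    provider_dimension = data.frame(
      provider_id = c("prov-1", "prov-2"),
      name_char = c("Provider 1", "Provider 2"),
      stringsAsFactors = FALSE),
    observation_fact = data.frame(
      patient_num = c(36L, 36L, 36L, 37L, 36L, 36L, 37L, 38L),
      encounter_num = c(501L, 501L, 502L, 503L, 501L, 502L, 503L, 504L),
      concept_cd = c("ICD10:M321", "ICD10:M321", "ICD10:M321", "ICD10:I10",
                     paste0("CIP:", CIP_A), paste0("CIP:", CIP_A),
                     paste0("CIP:", CIP_B), paste0("CIP:", CIP_C)),
      provider_id = c("prov-1", "prov-1", "prov-2", "prov-1",
                      "prov-2", "prov-2", "prov-1", "prov-2"),
      start_date = c("2015-06-01", "2015-06-01", "2015-09-12", "2016-01-06",
                     "2015-06-02", "2015-09-11", "2016-01-07", "2016-02-21"),
      end_date = NA_character_,
      instance_num = c(1L, 2L, 1L, 1L, 1L, 1L, 1L, 1L),
      stringsAsFactors = FALSE)
  )
}

mini_crosswalk <- function() {
  data.frame(cip_code = c(CIP_A, CIP_B, CIP_C),
             atc_code = c("C07AB07", "C07AB07", "N02BE01"),
             stringsAsFactors = FALSE)
}

mini_cdw <- function() cdw_load(mini_tables(), mini_crosswalk())

empty_tables <- function() {
  tabs <- mini_tables()
  lapply(tabs, function(df) df[0, , drop = FALSE])
}

# ---- independent oracle ---------------------------------------------------

# full scan + filter + merge over the raw tables; namespace "ATC" expands to
# the crosswalk's CIP children first
oracle_scan <- function(tables, namespace, code, crosswalk = NULL) {
  cds <- if (namespace == "ATC") {
    paste0("CIP:", crosswalk$cip_code[crosswalk$atc_code == code])
  } else {
    paste0(namespace, ":", code)
  }
  f <- tables$observation_fact
  sel <- f[f$concept_cd %in% cds, , drop = FALSE]
  sel <- merge(sel, tables$patient_dimension, by = "patient_num")
  sel <- merge(sel, tables$visit_dimension, by = "encounter_num",
               suffixes = c("", "_visit"))
  sel <- sel[order(sel$patient_num, sel$encounter_num, sel$start_date,
                   sel$instance_num, sel$concept_cd), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

oracle_tuples <- function(scan) {
  data.frame(patient_num = scan$patient_num,
             encounter_num = scan$encounter_num,
             code = sub("^[A-Z0-9]+:", "", scan$concept_cd),
             date = scan$start_date,
             stringsAsFactors = FALSE)
}

# ---- bundle introspection -------------------------------------------------

ref_tail <- function(ref) {
  stopifnot(!is.null(ref$reference))
  sub("^#", "", sub("^[A-Za-z]+/", "", ref$reference))
}

# (patient, encounter, code, date) tuple of each match entry
bundle_tuples <- function(b) {
  matches <- Filter(function(e) e$search$mode == "match", b$entry)
  rows <- lapply(matches, function(e) {
    r <- e$resource
    if (r$resourceType == "DiagnosticReport") {
      data.frame(patient_num = as.integer(sub("pat-", "", ref_tail(r$subject))),
                 encounter_num = as.integer(sub("enc-", "", ref_tail(r$encounter))),
                 code = r$code$coding[[1]]$code,
                 date = r$effectiveDateTime, stringsAsFactors = FALSE)
    } else {
      data.frame(patient_num = as.integer(sub("pat-", "", ref_tail(r$patient))),
                 encounter_num = as.integer(sub("enc-", "", ref_tail(r$encounter))),
                 code = sub("med-", "", ref_tail(r$medicationReference)),
                 date = r$dateWritten, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, c(rows, list(data.frame(
    patient_num = integer(), encounter_num = integer(),
    code = character(), date = character(), stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

sort_tuples <- function(df) {
  df <- df[order(df$patient_num, df$encounter_num, df$code, df$date), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

expect_same_multiset <- function(got, want) {
  expect_equal(sort_tuples(got), sort_tuples(want))
}

# every reference of every entry (including inside contained resources)
# resolves within the bundle; returns the number of references checked
check_bundle_closure <- function(b) {
  refs_checked <- 0L
  for (e in b$entry) {
    r <- e$resource
    scopes <- c(list(r), r$contained)
    for (s in scopes) {
      for (f in c("patient", "encounter", "subject", "medicationReference")) {
        ref <- s[[f]]
        if (is.null(ref)) next
        container <- if (startsWith(ref$reference, "#")) r else b
        resolved <- resolve_reference(container, ref)
        expect_false(is.null(resolved$resourceType))
        refs_checked <- refs_checked + 1L
      }
    }
  }
  refs_checked
}

count_bundle_resources <- function(b) {
  sum(vapply(b$entry, function(e) 1L + length(e$resource$contained), integer(1)))
}
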