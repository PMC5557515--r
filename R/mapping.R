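# The transform layer: joined i2b2 observations become FHIR resources.
# One resource per fact row; Patient/Encounter/Medication are derived from
# the dimension columns carried by the join. Ids are deterministic functions
# of the source keys so repeated queries are bit-stable.

DEFAULT_SYSTEM_URIS <- c(
  ICD10 = "http://hl7.org/fhir/sid/icd-10",
  ATC = "http://www.whocc.no/atc",
  CIP = "http://cip.hegp.fr",
  patient_id = "http://patient-id.hegp.fr",
  encounter_id = "http://encounter-id.hegp.fr"
)

#' Terminology context for the i2b2-to-FHIR mapping
#'
#' Bundles everything the mapping layer needs to code resources: the
#' CIP-to-ATC crosswalk used to enrich Medication codings, the system URI of
#' each terminology namespace, and optional display labels per code. Local
#' code systems are identified by hospital-local URLs
#' (`http://<codename>.hegp.fr` by default), international ones by their
#' canonical URIs (`http://hl7.org/fhir/sid/icd-10`, `http://www.whocc.no/atc`).
#'
#' @param crosswalk Data frame with columns `cip_code`, `atc_code`
#'   (many-to-one); may be empty.
#' @param system_uris Named character vector with entries `ICD10`, `ATC`,
#'   `CIP`, `patient_id`, `encounter_id`; defaults above.
#' @param display_labels Optional named character vector mapping codes to
#'   display text (usually unnecessary: displays are taken from
#'   `concept_dimension.name_char` carried by the join).
#' @return An object of class `terminology_context`.
#' @export
terminology_context <- function(crosswalk = NULL,
                                system_uris = DEFAULT_SYSTEM_URIS,
                                display_labels = NULL) {
  if (is.null(crosswalk)) {
    crosswalk <- data.frame(cip_code = character(), atc_code = character(),
                            stringsAsFactors = FALSE)
  }
  stopifnot(all(c("cip_code", "atc_code") %in% names(crosswalk)))
  if (anyDuplicated(crosswalk$cip_code)) {
    stop("crosswalk must be many-to-one: each cip_code maps to one atc_code")
  }
  missing_uris <- setdiff(names(DEFAULT_SYSTEM_URIS), names(system_uris))
  if (length(missing_uris) > 0L) {
    stop("system_uris lacks entries: ", paste(missing_uris, collapse = ", "))
  }
  cip_to_atc <- stats::setNames(as.character(crosswalk$atc_code),
                                as.character(crosswalk$cip_code))
  structure(list(cip_to_atc = cip_to_atc, system_uris = system_uris,
                 display_labels = display_labels),
            class = "terminology_context")
}

#' @rdname terminology_context
#' @param h A `cdw` handle; its loaded crosswalk becomes the context's.
#' @export
terminology_context_from <- function(h, system_uris = DEFAULT_SYSTEM_URIS) {
  stopifnot(inherits(h, "cdw"))
  terminology_context(h$crosswalk, system_uris)
}

split_concept_cd <- function(concept_cd) {
  parts <- regmatches(concept_cd, regexec("^([A-Z0-9]+):(.+)$", concept_cd))[[1]]
  if (length(parts) != 3L) {
    cdw_argument_error(sprintf("concept_cd '%s' has no terminology namespace prefix",
                               concept_cd))
  }
  list(namespace = parts[2], code = parts[3])
}

#' Map an i2b2 sex code to the FHIR administrative-gender ValueSet
#'
#' `M` maps to `male`, `F` to `female`, `U` to `unknown`; any other value
#' (including empty or missing) degrades to `unknown` rather than failing, so
#' queries never error on dirty dimension data.
#'
#' @param sex_cd Character vector of i2b2 sex codes.
#' @return Character vector of administrative-gender codes.
#' @export
map_gender <- function(sex_cd) {
  out <- c(M = "male", F = "female", U = "unknown")[as.character(sex_cd)]
  out[is.na(out)] <- "unknown"
  unname(out)
}

patient_id_of <- function(patient_num) paste0("pat-", patient_num)
encounter_id_of <- function(encounter_num) paste0("enc-", encounter_num)
medication_id_of <- function(cip_code) paste0("med-", cip_code)

# Fact-level resource ids encode the full fact key so a single fact can be
# read back by id: <prefix>-<patient>-<encounter>-<code>-<yyyymmdd>-<instance>
fact_id_of <- function(prefix, j) {
  paste(prefix, j$patient_num, j$encounter_num,
        split_concept_cd(j$concept_cd)$code,
        gsub("-", "", j$start_date, fixed = TRUE), j$instance_num, sep = "-")
}

#' Map i2b2 records to FHIR resources
#'
#' The field-level transform between the i2b2 star schema and the served
#' resources. Each function takes one record — a named list or one-row slice
#' of a joined-observation data frame — and returns the corresponding
#' resource. References are constructed in their literal `Type/id` form;
#' rewriting them to contained `#id` form is the search layer's packaging
#' step.
#'
#' @param p Patient record with `patient_num`, `birth_date`, `sex_cd`.
#' @param ctx A [terminology_context()].
#' @return The corresponding `fhir_*` resource. `to_medication_order()`
#'   returns `list(order = , medication = )`, since the order's medication
#'   reference points at a Medication resource derived from the same concept.
#' @examples
#' ctx <- terminology_context()
#' to_patient(list(patient_num = 36, birth_date = "1941-03-02", sex_cd = "F"), ctx)
#' @export
to_patient <- function(p, ctx) {
  fhir_patient(
    id = patient_id_of(p$patient_num),
    identifier = fhir_coding(ctx$system_uris[["patient_id"]], p$patient_num),
    birth_date = p$birth_date,
    gender = map_gender(p$sex_cd))
}

#' @rdname to_patient
#' @param v Visit record with `encounter_num`, `patient_num`, `start_date`
#'   and optional `end_date` (fields named `visit_start_date` /
#'   `visit_end_date` in a joined observation are also understood).
#' @export
to_encounter <- function(v, ctx) {
  # joined observations carry the visit period as visit_*; prefer it over the
  # fact's own start/end columns
  start <- v$visit_start_date %||% v$start_date
  end <- v$visit_end_date %||% v$end_date
  fhir_encounter(
    id = encounter_id_of(v$encounter_num),
    identifier = fhir_coding(ctx$system_uris[["encounter_id"]], v$encounter_num),
    patient = fhir_reference(paste0("Patient/", patient_id_of(v$patient_num))),
    period_start = start,
    period_end = if (!is.null(end) && !is.na(end)) end)
}

#' @rdname to_patient
#' @param con Concept record with `concept_cd` in the CIP namespace and
#'   display label `name_char`.
#' @export
to_medication <- function(con, ctx) {
  cc <- split_concept_cd(con$concept_cd)
  if (cc$namespace != "CIP") {
    cdw_argument_error(sprintf(
      "to_medication requires a CIP concept, got namespace '%s'", cc$namespace))
  }
  display <- con$name_char
  if (is.null(display) || is.na(display) || !nzchar(display)) display <- NULL
  codings <- list(fhir_coding(ctx$system_uris[["CIP"]], cc$code, display))
  atc <- ctx$cip_to_atc[cc$code]
  if (!is.na(atc)) {
    codings <- c(codings, list(fhir_coding(ctx$system_uris[["ATC"]],
                                           unname(atc))))
  }
  fhir_medication(id = medication_id_of(cc$code),
                  code = fhir_codeable_concept(codings, text = display))
}

#' @rdname to_patient
#' @param j A joined observation (fact row plus its patient, visit and
#'   concept columns), as returned by the `find_observations_*` queries.
#' @export
to_diagnostic_report <- function(j, ctx) {
  cc <- split_concept_cd(j$concept_cd)
  if (cc$namespace != "ICD10") {
    cdw_argument_error(sprintf(
      "to_diagnostic_report requires an ICD10 concept, got namespace '%s'",
      cc$namespace))
  }
  display <- j$name_char
  if (is.null(display) || is.na(display) || !nzchar(display)) display <- NULL
  fhir_diagnostic_report(
    id = fact_id_of("dr", j),
    code = fhir_codeable_concept(list(
      fhir_coding(ctx$system_uris[["ICD10"]], cc$code, display)), text = display),
    subject = fhir_reference(paste0("Patient/", patient_id_of(j$patient_num))),
    encounter = fhir_reference(paste0("Encounter/", encounter_id_of(j$encounter_num))),
    effective_date = j$start_date)
}

#' @rdname to_patient
#' @export
to_medication_order <- function(j, ctx) {
  cc <- split_concept_cd(j$concept_cd)
  if (cc$namespace != "CIP") {
    cdw_argument_error(sprintf(
      "to_medication_order requires a CIP concept, got namespace '%s'",
      cc$namespace))
  }
  med <- to_medication(list(concept_cd = j$concept_cd, name_char = j$name_char),
                       ctx)
  order <- fhir_medication_order(
    id = fact_id_of("mo", j),
    date_written = j$start_date,
    patient = fhir_reference(paste0("Patient/", patient_id_of(j$patient_num))),
    encounter = fhir_reference(paste0("Encounter/", encounter_id_of(j$encounter_num))),
    medication = fhir_reference(paste0("Medication/", med$id)))
  list(order = order, medication = med)
}

# row i of a joined-observation data frame as a plain list
joined_row <- function(rows, i) {
  list(patient_num = rows$patient_num[i],
       encounter_num = rows$encounter_num[i],
       concept_cd = rows$concept_cd[i],
       provider_id = rows$provider_id[i],
       start_date = rows$start_date[i],
       end_date = rows$end_date[i],
       instance_num = rows$instance_num[i],
       birth_date = rows$birth_date[i],
       sex_cd = rows$sex_cd[i],
       visit_start_date = rows$visit_start_date[i],
       visit_end_date = rows$visit_end_date[i],
       name_char = rows$name_char[i])
}
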