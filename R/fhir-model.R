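# In-memory model of the five served FHIR DSTU2 resources (Patient,
# Encounter, Medication, MedicationOrder, DiagnosticReport) and their
# substructures. Resources are named lists using the DSTU2 wire field names,
# with absent fields dropped entirely, so serialization is mechanical and
# round-trips are exact.

FHIR_SERVED_TYPES <- c("Patient", "Encounter", "Medication",
                       "MedicationOrder", "DiagnosticReport")

FHIR_GENDERS <- c("male", "female", "other", "unknown")

fhir_error <- function(status, msg) {
  stop(errorCondition(msg, status = status,
                      class = c(paste0("fhir_error_", status),
                                "fhir_error", "error")))
}

drop_null <- function(x) x[!vapply(x, is.null, logical(1))]

as_date_chr <- function(x) {
  if (inherits(x, "Date")) format(x, "%Y-%m-%d") else as.character(x)
}

#' Construct FHIR datatype substructures
#'
#' Minimal constructors for the DSTU2 datatypes the served resources use:
#' `Coding` (a code from a terminology system), `CodeableConcept` (one or more
#' codings plus optional text) and `Reference` (a pointer to another resource,
#' either a local `#id` into the enclosing resource's `contained` list or a
#' relative literal `Type/id`).
#'
#' @param system Terminology system URI (non-empty).
#' @param code Code within the system (non-empty).
#' @param display Optional human-readable label.
#' @return A classed named list; absent fields are omitted, not set to NULL.
#' @export
fhir_coding <- function(system, code, display = NULL) {
  structure(drop_null(list(system = system, code = as.character(code),
                           display = display)),
            class = "fhir_coding")
}

#' @rdname fhir_coding
#' @param coding List of [fhir_coding()] objects (at least one).
#' @param text Optional free-text rendering of the concept.
#' @export
fhir_codeable_concept <- function(coding, text = NULL) {
  if (inherits(coding, "fhir_coding")) coding <- list(coding)
  structure(drop_null(list(coding = coding, text = text)),
            class = "fhir_codeable_concept")
}

#' @rdname fhir_coding
#' @param reference Reference target: `"#<id>"` (contained) or `"<Type>/<id>"`.
#' @export
fhir_reference <- function(reference, display = NULL) {
  structure(drop_null(list(reference = reference, display = display)),
            class = "fhir_reference")
}

new_resource <- function(type, fields) {
  structure(c(list(resourceType = type), drop_null(fields)),
            class = c(paste0("fhir_", tolower(type)), "fhir_resource"))
}

#' Construct the served FHIR resources
#'
#' Constructors for the five resources the server exposes, trimmed to the
#' fields the i2b2 mapping populates. Ids are plain strings; dates are
#' ISO-8601 strings (a `Date` is accepted and formatted). `contained` holds
#' locally embedded resources addressed by `#id` references.
#'
#' @param id Resource id, unique within a Bundle for its type.
#' @param identifier [fhir_coding()] carrying the source-system identifier
#'   (hospital patient number, encounter number).
#' @param birth_date,gender Patient demographics; `gender` must come from the
#'   administrative-gender ValueSet (`male`, `female`, `other`, `unknown`).
#' @return A classed named list with `resourceType` first.
#' @export
fhir_patient <- function(id, identifier, birth_date, gender) {
  new_resource("Patient", list(id = id, identifier = identifier,
                               gender = gender,
                               birthDate = as_date_chr(birth_date)))
}

#' @rdname fhir_patient
#' @param patient [fhir_reference()] to the subject Patient.
#' @param period_start,period_end Encounter period bounds; `period_end` may be
#'   NULL for an open encounter.
#' @export
fhir_encounter <- function(id, identifier, patient, period_start,
                           period_end = NULL) {
  period <- drop_null(list(start = as_date_chr(period_start),
                           end = if (!is.null(period_end) && !is.na(period_end))
                             as_date_chr(period_end)))
  new_resource("Encounter", list(id = id, identifier = identifier,
                                 patient = patient, period = period))
}

#' @rdname fhir_patient
#' @param code [fhir_codeable_concept()]; for Medication the CIP coding plus,
#'   when the crosswalk covers the presentation, its ATC class coding.
#' @export
fhir_medication <- function(id, code) {
  new_resource("Medication", list(id = id, code = code))
}

#' @rdname fhir_patient
#' @param encounter,medication [fhir_reference()]s to the order's Encounter
#'   and Medication.
#' @param date_written Date the order was written (the source fact's start
#'   date).
#' @param contained List of locally embedded resources (may be empty).
#' @export
fhir_medication_order <- function(id, date_written, patient, encounter,
                                  medication, contained = list()) {
  new_resource("MedicationOrder", list(
    id = id,
    contained = if (length(contained) > 0L) contained,
    dateWritten = as_date_chr(date_written),
    patient = patient,
    encounter = encounter,
    medicationReference = medication))
}

#' @rdname fhir_patient
#' @param subject [fhir_reference()] to the report's Patient.
#' @param effective_date Clinically relevant date of the report (the source
#'   fact's start date).
#' @export
fhir_diagnostic_report <- function(id, code, subject, encounter,
                                   effective_date, contained = list()) {
  new_resource("DiagnosticReport", list(
    id = id,
    contained = if (length(contained) > 0L) contained,
    code = code,
    subject = subject,
    encounter = encounter,
    effectiveDateTime = as_date_chr(effective_date)))
}

#' Assemble a searchset Bundle
#'
#' @param matches List of resources matched by the search.
#' @param includes List of resources returned because a match references them
#'   (`_include` directives), appended after the matches.
#' @return A `fhir_bundle`: `type` fixed to `"searchset"`, `total` equal to
#'   the number of match entries, one entry per resource tagged with its
#'   search mode.
#' @export
fhir_bundle <- function(matches = list(), includes = list()) {
  entry <- c(
    lapply(matches, function(r) list(resource = r, search = list(mode = "match"))),
    lapply(includes, function(r) list(resource = r, search = list(mode = "include")))
  )
  structure(list(resourceType = "Bundle", type = "searchset",
                 total = length(matches), entry = entry),
            class = c("fhir_bundle", "fhir_resource"))
}

#' Extract the resources of a Bundle's entries
#'
#' @param b A [fhir_bundle()].
#' @param mode Optional filter: `"match"` or `"include"`.
#' @return List of resources in entry order.
#' @export
bundle_resources <- function(b, mode = NULL) {
  entries <- b$entry
  if (!is.null(mode)) {
    entries <- Filter(function(e) e$search$mode == mode, entries)
  }
  lapply(entries, `[[`, "resource")
}

#' @export
print.fhir_resource <- function(x, ...) {
  cat(sprintf("<%s>", x$resourceType))
  if (!is.null(x$id)) cat(sprintf(" id=%s", x$id))
  cat("\n")
  utils::str(unclass_deep(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' @export
print.fhir_bundle <- function(x, ...) {
  modes <- vapply(x$entry, function(e) e$search$mode, character(1))
  cat(sprintf("<Bundle searchset> total=%d (%d match, %d include entries)\n",
              x$total, sum(modes == "match"), sum(modes == "include")))
  invisible(x)
}

# ---- validation -----------------------------------------------------------

validate_coding <- function(x, field) {
  v <- character()
  if (!inherits(x, "fhir_coding")) {
    return(sprintf("%s: not a Coding", field))
  }
  if (is.null(x$system) || !nzchar(x$system)) {
    v <- c(v, sprintf("%s.system: must be a non-empty URI", field))
  }
  if (is.null(x$code) || !nzchar(x$code)) {
    v <- c(v, sprintf("%s.code: must be non-empty", field))
  }
  v
}

validate_concept <- function(x, field) {
  if (!inherits(x, "fhir_codeable_concept")) {
    return(sprintf("%s: not a CodeableConcept", field))
  }
  v <- character()
  if (length(x$coding) == 0L) {
    v <- c(v, sprintf("%s.coding: must contain at least one Coding", field))
  }
  for (i in seq_along(x$coding)) {
    v <- c(v, validate_coding(x$coding[[i]], sprintf("%s.coding[%d]", field, i)))
  }
  keys <- vapply(x$coding, function(cd)
    paste0(cd$system %||% "", "|", cd$code %||% ""), character(1))
  if (anyDuplicated(keys)) {
    v <- c(v, sprintf("%s.coding: duplicate (system, code) pair '%s'",
                      field, keys[duplicated(keys)][1L]))
  }
  v
}

validate_ref <- function(x, field, contained_ids) {
  if (!inherits(x, "fhir_reference")) {
    return(sprintf("%s: not a Reference", field))
  }
  ref <- x$reference
  if (is.null(ref) || !nzchar(ref)) {
    return(sprintf("%s.reference: must be non-empty", field))
  }
  if (startsWith(ref, "#")) {
    if (!(substring(ref, 2L) %in% contained_ids)) {
      return(sprintf(
        "%s.reference: local reference '%s' does not resolve in the contained list",
        field, ref))
    }
  } else {
    parts <- strsplit(ref, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !(parts[1] %in% FHIR_SERVED_TYPES) || !nzchar(parts[2])) {
      return(sprintf(
        "%s.reference: literal reference '%s' must be '<ServedType>/<id>'",
        field, ref))
    }
  }
  character()
}

contained_ids_of <- function(r) {
  vapply(r$contained %||% list(), function(cr) cr$id %||% "", character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check a resource or Bundle against the model invariants
#'
#' Total function: never throws, returns a character vector of violation
#' descriptions (empty when the object is valid). Each violation names the
#' offending field and the rule it breaks. For a Bundle, entry resources are
#' validated recursively and the Bundle-level rules are checked: `total`
#' equals the number of match entries, no two entries share a (type, id)
#' pair, and every include entry is referenced by at least one match.
#'
#' @param r A resource built by the `fhir_*()` constructors, or a
#'   [fhir_bundle()].
#' @return Character vector of violations, `character(0)` if valid.
#' @export
validate_resource <- function(r) {
  validate_resource_in(r, character())
}

# scope_ids: contained ids of the enclosing resource, visible to contained
# children so sibling resources may reference each other locally
validate_resource_in <- function(r, scope_ids) {
  if (inherits(r, "fhir_bundle")) return(validate_bundle(r))
  if (!inherits(r, "fhir_resource") || is.null(r$resourceType)) {
    return("resourceType: missing or not a FHIR resource")
  }
  v <- character()
  if (is.null(r$id) || !nzchar(r$id)) v <- c(v, "id: must be non-empty")
  cids <- union(contained_ids_of(r), scope_ids)
  for (cr in r$contained %||% list()) v <- c(v, validate_resource_in(cr, cids))
  switch(r$resourceType,
    Patient = {
      v <- c(v, validate_coding(r$identifier, "identifier"))
      if (is.null(r$gender) || !(r$gender %in% FHIR_GENDERS)) {
        v <- c(v, sprintf(
          "gender: '%s' is not in the administrative-gender ValueSet (male|female|other|unknown)",
          r$gender %||% ""))
      }
      if (is.null(r$birthDate) || !is_iso_date(r$birthDate)) {
        v <- c(v, "birthDate: must be an ISO-8601 date")
      }
    },
    Encounter = {
      v <- c(v, validate_coding(r$identifier, "identifier"))
      v <- c(v, validate_ref(r$patient, "patient", cids))
      if (is.null(r$period$start) || !is_iso_date(r$period$start)) {
        v <- c(v, "period.start: must be an ISO-8601 date")
      } else if (!is.null(r$period$end) && r$period$end < r$period$start) {
        v <- c(v, "period.end: must not precede period.start")
      }
    },
    Medication = {
      v <- c(v, validate_concept(r$code, "code"))
    },
    MedicationOrder = {
      v <- c(v, validate_ref(r$patient, "patient", cids))
      v <- c(v, validate_ref(r$encounter, "encounter", cids))
      v <- c(v, validate_ref(r$medicationReference, "medicationReference", cids))
      if (is.null(r$dateWritten) || !is_iso_date(r$dateWritten)) {
        v <- c(v, "dateWritten: must be an ISO-8601 date")
      }
    },
    DiagnosticReport = {
      v <- c(v, validate_concept(r$code, "code"))
      if (inherits(r$code, "fhir_codeable_concept") && length(r$code$coding) != 1L) {
        v <- c(v, "code.coding: a DiagnosticReport carries exactly one ICD-10 coding")
      }
      v <- c(v, validate_ref(r$subject, "subject", cids))
      v <- c(v, validate_ref(r$encounter, "encounter", cids))
      if (is.null(r$effectiveDateTime) || !is_iso_date(r$effectiveDateTime)) {
        v <- c(v, "effectiveDateTime: must be an ISO-8601 date")
      }
    },
    v <- c(v, sprintf("resourceType: '%s' is not a served type", r$resourceType))
  )
  v
}

validate_bundle <- function(b) {
  v <- character()
  if (!identical(b$type, "searchset")) v <- c(v, "type: must be 'searchset'")
  modes <- vapply(b$entry, function(e) e$search$mode %||% "", character(1))
  if (!all(modes %in% c("match", "include"))) {
    v <- c(v, "entry.search.mode: must be 'match' or 'include'")
  }
  if (!identical(as.integer(b$total), sum(modes == "match"))) {
    v <- c(v, sprintf("total: %s does not equal the number of match entries (%d)",
                      b$total, sum(modes == "match")))
  }
  keys <- vapply(b$entry, function(e)
    paste0(e$resource$resourceType %||% "", "/", e$resource$id %||% ""),
    character(1))
  if (anyDuplicated(keys)) {
    v <- c(v, sprintf("entry: duplicate (resource type, id) '%s'",
                      keys[duplicated(keys)][1L]))
  }
  for (e in b$entry) v <- c(v, validate_resource(e$resource))
  # every include entry must be reachable from some match entry
  inc_keys <- keys[modes == "include"]
  if (length(inc_keys) > 0L) {
    referenced <- unlist(lapply(bundle_resources(b, "match"), literal_refs_of))
    orphan <- setdiff(inc_keys, referenced)
    if (length(orphan) > 0L) {
      v <- c(v, sprintf("entry: include entry '%s' is referenced by no match entry",
                        orphan[1L]))
    }
  }
  v
}

# literal Type/id references carried by a resource (not its contained ones)
literal_refs_of <- function(r) {
  refs <- character()
  for (f in c("patient", "encounter", "subject", "medicationReference")) {
    ref <- r[[f]]$reference
    if (!is.null(ref) && !startsWith(ref, "#")) refs <- c(refs, ref)
  }
  refs
}

all_refs_of <- function(r) {
  refs <- character()
  for (f in c("patient", "encounter", "subject", "medicationReference")) {
    if (!is.null(r[[f]]$reference)) refs <- c(refs, r[[f]]$reference)
  }
  refs
}

#' Resolve a Reference within a resource or Bundle
#'
#' Local `"#<id>"` references are looked up in the containing resource's
#' `contained` list; relative literal `"<Type>/<id>"` references are looked up
#' among a Bundle's entries.
#'
#' @param container The enclosing resource (for local references) or Bundle
#'   (for literal references).
#' @param ref A [fhir_reference()] or its target string.
#' @return The referenced resource; unresolvable references raise a
#'   `fhir_resolution_error` naming the reference.
#' @export
resolve_reference <- function(container, ref) {
  target <- if (inherits(ref, "fhir_reference")) ref$reference else ref
  if (is.null(target) || !nzchar(target)) {
    stop(errorCondition("empty reference",
                        class = c("fhir_resolution_error", "error")))
  }
  if (startsWith(target, "#")) {
    id <- substring(target, 2L)
    for (cr in container$contained %||% list()) {
      if (identical(cr$id, id)) return(cr)
    }
  } else if (inherits(container, "fhir_bundle")) {
    parts <- strsplit(target, "/", fixed = TRUE)[[1]]
    if (length(parts) == 2L) {
      for (e in container$entry) {
        if (identical(e$resource$resourceType, parts[1]) &&
            identical(e$resource$id, parts[2])) {
          return(e$resource)
        }
      }
    }
  }
  stop(errorCondition(sprintf("reference '%s' does not resolve", target),
                      class = c("fhir_resolution_error", "error")))
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_deep)
    attributes(x) <- list(names = names(x))
  }
  x
}
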