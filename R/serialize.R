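# Dual JSON/XML wire formats for the served resources and Bundles, DSTU2
# conventions: JSON carries a resourceType discriminator; XML uses the FHIR
# namespace with value attributes, contained resources nested before the
# parent's own data elements. Field order is deterministic (constructor
# order), absent fields are omitted entirely, so both formats round-trip to
# structurally identical objects.

FHIR_XMLNS <- "http://hl7.org/fhir"

FHIR_MEDIA_TYPES <- c(json = "application/json+fhir", xml = "application/xml+fhir")

fhir_parse_error <- function(msg) {
  stop(errorCondition(msg, class = c("fhir_parse_error", "error")))
}

#' Serialize a resource or Bundle to its wire form
#'
#' Refuses to serialize an invalid object: if [validate_resource()] reports
#' violations they are raised as a `fhir_serialization_error`.
#'
#' @param r A `fhir_*` resource or [fhir_bundle()].
#' @param format `"json"` or `"xml"`.
#' @param pretty Pretty-print the body (off by default for byte-stable
#'   responses).
#' @return An object of class `fhir_wire` with fields `media_type`
#'   (`application/json+fhir` or `application/xml+fhir`) and `body` (a
#'   single string).
#' @seealso [from_wire()] for the inverse.
#' @export
to_wire <- function(r, format = c("json", "xml"), pretty = FALSE) {
  format <- match.arg(format)
  violations <- validate_resource(r)
  if (length(violations) > 0L) {
    stop(errorCondition(
      paste0("refusing to serialize an invalid ", r$resourceType %||% "object",
             ":\n  ", paste(violations, collapse = "\n  ")),
      violations = violations,
      class = c("fhir_serialization_error", "error")))
  }
  body <- if (format == "json") {
    as.character(jsonlite::toJSON(unclass_deep(r), auto_unbox = TRUE,
                                  digits = NA, pretty = pretty))
  } else {
    doc <- xml2::xml_new_root(r$resourceType, xmlns = FHIR_XMLNS)
    xml_write_fields(doc, r)
    xml_to_string(doc, pretty)
  }
  structure(list(media_type = unname(FHIR_MEDIA_TYPES[format]), body = body),
            class = "fhir_wire")
}

# xml2 emits an XML declaration line; kept, it is part of the document
xml_to_string <- function(doc, pretty) {
  as.character(doc, options = if (pretty) c("format", "as_xml") else "as_xml")
}

# Write a resource's fields (everything but resourceType) onto an XML node.
xml_write_fields <- function(node, r) {
  for (name in setdiff(names(r), "resourceType")) {
    value <- r[[name]]
    if (name == "contained") {
      for (cr in value) {
        wrap <- xml2::xml_add_child(node, "contained")
        child <- xml2::xml_add_child(wrap, cr$resourceType)
        xml_write_fields(child, cr)
      }
    } else if (name == "entry") {
      for (e in value) {
        entry <- xml2::xml_add_child(node, "entry")
        res <- xml2::xml_add_child(entry, "resource")
        child <- xml2::xml_add_child(res, e$resource$resourceType)
        xml_write_fields(child, e$resource)
        search <- xml2::xml_add_child(entry, "search")
        xml2::xml_add_child(search, "mode", value = e$search$mode)
      }
    } else {
      xml_write_element(node, name, value)
    }
  }
}

xml_write_element <- function(node, name, value) {
  if (is.list(value)) {
    if (is.null(names(value))) {
      # array: repeated elements of the same name (e.g. coding)
      for (item in value) xml_write_element(node, name, item)
    } else {
      child <- xml2::xml_add_child(node, name)
      for (sub in names(value)) xml_write_element(child, sub, value[[sub]])
    }
  } else {
    xml2::xml_add_child(node, name, value = as.character(value))
  }
}

#' Parse a wire document back into a resource or Bundle
#'
#' Inverse of [to_wire()] up to structural equality: the parsed object is
#' rebuilt through the same constructors, so
#' `identical(from_wire(to_wire(r, f)), r)` holds for any valid resource and
#' either format.
#'
#' @param doc A `fhir_wire` object, or a single string (the format is then
#'   sniffed from the leading character).
#' @return The reconstructed resource or Bundle.
#' @export
from_wire <- function(doc) {
  if (inherits(doc, "fhir_wire")) {
    body <- doc$body
    format <- if (grepl("xml", doc$media_type, fixed = TRUE)) "xml" else "json"
  } else if (is.character(doc) && length(doc) == 1L) {
    body <- doc
    format <- if (grepl("^\\s*<", doc)) "xml" else "json"
  } else {
    fhir_parse_error("from_wire expects a fhir_wire object or a single string")
  }
  if (format == "json") {
    x <- tryCatch(jsonlite::fromJSON(body, simplifyVector = FALSE),
                  error = function(e) fhir_parse_error(
                    paste0("malformed JSON: ", conditionMessage(e))))
    resource_from_plain(x)
  } else {
    x <- tryCatch(xml2::read_xml(body),
                  error = function(e) fhir_parse_error(
                    paste0("malformed XML: ", conditionMessage(e))))
    resource_from_xml(x)
  }
}

# ---- JSON reconstruction --------------------------------------------------

coding_from_plain <- function(x) {
  fhir_coding(x$system, x$code, x$display)
}

concept_from_plain <- function(x) {
  fhir_codeable_concept(lapply(x$coding, coding_from_plain), x$text)
}

ref_from_plain <- function(x) fhir_reference(x$reference, x$display)

resource_from_plain <- function(x) {
  type <- x$resourceType
  if (is.null(type)) fhir_parse_error("document lacks a resourceType discriminator")
  contained <- lapply(x$contained %||% list(), resource_from_plain)
  switch(type,
    Patient = fhir_patient(x$id, coding_from_plain(x$identifier),
                           x$birthDate, x$gender),
    Encounter = fhir_encounter(x$id, coding_from_plain(x$identifier),
                               ref_from_plain(x$patient),
                               x$period$start, x$period$end),
    Medication = fhir_medication(x$id, concept_from_plain(x$code)),
    MedicationOrder = fhir_medication_order(
      x$id, x$dateWritten, ref_from_plain(x$patient),
      ref_from_plain(x$encounter), ref_from_plain(x$medicationReference),
      contained),
    DiagnosticReport = fhir_diagnostic_report(
      x$id, concept_from_plain(x$code), ref_from_plain(x$subject),
      ref_from_plain(x$encounter), x$effectiveDateTime, contained),
    Bundle = {
      entries <- x$entry %||% list()
      modes <- vapply(entries, function(e) e$search$mode, character(1))
      resources <- lapply(entries, function(e) resource_from_plain(e$resource))
      b <- fhir_bundle(matches = resources[modes == "match"],
                       includes = resources[modes == "include"])
      if (!identical(b$total, as.integer(x$total))) {
        fhir_parse_error(sprintf(
          "Bundle total %s disagrees with its %d match entries", x$total, b$total))
      }
      b
    },
    fhir_parse_error(sprintf("unsupported resource type '%s'", type))
  )
}

# ---- XML reconstruction ---------------------------------------------------

xml_value1 <- function(node, name) {
  child <- xml2::xml_find_first(node, paste0("./f:", name), c(f = FHIR_XMLNS))
  if (inherits(child, "xml_missing")) return(NULL)
  xml2::xml_attr(child, "value")
}

xml_children_named <- function(node, name) {
  xml2::xml_find_all(node, paste0("./f:", name), c(f = FHIR_XMLNS))
}

coding_from_xml <- function(node) {
  fhir_coding(xml_value1(node, "system"), xml_value1(node, "code"),
              xml_value1(node, "display"))
}

concept_from_xml <- function(node) {
  fhir_codeable_concept(lapply(xml_children_named(node, "coding"),
                               coding_from_xml),
                        xml_value1(node, "text"))
}

ref_from_xml <- function(node) {
  if (is.null(node) || inherits(node, "xml_missing")) return(NULL)
  fhir_reference(xml_value1(node, "reference"), xml_value1(node, "display"))
}

child1 <- function(node, name) {
  out <- xml_children_named(node, name)
  if (length(out) == 0L) NULL else out[[1]]
}

resource_from_xml <- function(node) {
  type <- xml2::xml_name(node)
  contained <- lapply(xml_children_named(node, "contained"),
                      function(wrap) resource_from_xml(xml2::xml_child(wrap)))
  id <- xml_value1(node, "id")
  switch(type,
    Patient = fhir_patient(id, coding_from_xml(child1(node, "identifier")),
                           xml_value1(node, "birthDate"),
                           xml_value1(node, "gender")),
    Encounter = {
      period <- child1(node, "period")
      fhir_encounter(id, coding_from_xml(child1(node, "identifier")),
                     ref_from_xml(child1(node, "patient")),
                     xml_value1(period, "start"), xml_value1(period, "end"))
    },
    Medication = fhir_medication(id, concept_from_xml(child1(node, "code"))),
    MedicationOrder = fhir_medication_order(
      id, xml_value1(node, "dateWritten"),
      ref_from_xml(child1(node, "patient")),
      ref_from_xml(child1(node, "encounter")),
      ref_from_xml(child1(node, "medicationReference")), contained),
    DiagnosticReport = fhir_diagnostic_report(
      id, concept_from_xml(child1(node, "code")),
      ref_from_xml(child1(node, "subject")),
      ref_from_xml(child1(node, "encounter")),
      xml_value1(node, "effectiveDateTime"), contained),
    Bundle = {
      entries <- xml_children_named(node, "entry")
      modes <- vapply(entries, function(e)
        xml_value1(child1(e, "search"), "mode"), character(1))
      resources <- lapply(entries, function(e)
        resource_from_xml(xml2::xml_child(child1(e, "resource"))))
      b <- fhir_bundle(matches = resources[modes == "match"],
                       includes = resources[modes == "include"])
      total <- as.integer(xml_value1(node, "total"))
      if (!identical(b$total, total)) {
        fhir_parse_error(sprintf(
          "Bundle total %d disagrees with its %d match entries", total, b$total))
      }
      b
    },
    fhir_parse_error(sprintf("unsupported resource type '%s'", type))
  )
}

#' @export
print.fhir_wire <- function(x, ...) {
  cat(sprintf("<fhir_wire %s, %d bytes>\n", x$media_type, nchar(x$body)))
  invisible(x)
}
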