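# The REST search facade: parse FHIR search URLs, run them against the
# warehouse through the mapping layer, and package the requested _include
# resources as contained ("#id") or external (Bundle include entry)
# references, following the served presentation: Patient and Encounter are
# contained in each match, Medication is emitted once per distinct drug as an
# include entry referenced literally.

SEARCH_PARAMS <- list(
  DiagnosticReport = list(filters = "code", includes = c("subject", "encounter")),
  MedicationOrder = list(filters = "medication.code",
                         includes = c("patient", "encounter", "medication"))
)

#' Server configuration
#'
#' @param packaging `"figures"` (default) keeps the asymmetric presentation —
#'   requested Patient/Encounter contained inside each match, requested
#'   Medication external as a deduplicated include entry; `"external"` puts
#'   every requested related resource in deduplicated include entries with
#'   literal references.
#' @param strict Reject unknown search parameters with a 400-class error
#'   (default) instead of ignoring them.
#' @param count_cap Upper bound applied to `_count`; `Inf` disables paging
#'   entirely (result sets are returned whole).
#' @param system_uris Terminology system URIs, see [terminology_context()].
#' @return An object of class `fhir_config`.
#' @export
fhir_config <- function(packaging = c("figures", "external"), strict = TRUE,
                        count_cap = Inf, system_uris = DEFAULT_SYSTEM_URIS) {
  structure(list(packaging = match.arg(packaging), strict = strict,
                 count_cap = count_cap, system_uris = system_uris),
            class = "fhir_config")
}

url_decode <- function(x) {
  vapply(x, function(s) utils::URLdecode(chartr("+", " ", s)), character(1),
         USE.NAMES = FALSE)
}

#' Parse a FHIR search request
#'
#' Decomposes the path and query string of a FHIR search URL into a
#' structured query: resource type, filter parameters (simple like `code`, or
#' chained with one hop like `medication.code`), accumulated `_include`
#' directives, response format and `_count`. Parsing is strict: an unknown
#' resource type raises a 404-class `fhir_error`, an unknown or malformed
#' parameter a 400-class one naming the parameter.
#'
#' @param path URL path whose last segment names the resource type, e.g.
#'   `"/DiagnosticReport"` (a server prefix before it is ignored).
#' @param query_string Raw query string, without the leading `?`. May be
#'   omitted if `path` contains `?`.
#' @return An object of class `fhir_search_query` with elements
#'   `resource_type`, `filters` (named character vector), `includes`
#'   (character vector of include search-parameter names), `format`
#'   (`"json"` or `"xml"`) and `count`.
#' @examples
#' parse_search_request(
#'   "/DiagnosticReport",
#'   "code=M321&_include=DiagnosticReport:subject&_include=DiagnosticReport:encounter")
#' @export
parse_search_request <- function(path, query_string = NULL) {
  if (is.null(query_string) && grepl("?", path, fixed = TRUE)) {
    parts <- strsplit(path, "?", fixed = TRUE)[[1]]
    path <- parts[1]
    query_string <- paste(parts[-1], collapse = "?")
  }
  segments <- strsplit(path, "/", fixed = TRUE)[[1]]
  segments <- segments[nzchar(segments)]
  if (length(segments) == 0L) fhir_error(404L, "no resource type in request path")
  rtype <- segments[length(segments)]
  if (!(rtype %in% names(SEARCH_PARAMS))) {
    fhir_error(404L, sprintf("unknown resource type '%s'", rtype))
  }
  spec <- SEARCH_PARAMS[[rtype]]

  filters <- character()
  includes <- character()
  format <- "json"
  count <- Inf
  if (!is.null(query_string) && nzchar(query_string)) {
    pairs <- strsplit(query_string, "&", fixed = TRUE)[[1]]
    for (pair in pairs[nzchar(pairs)]) {
      eq <- regexpr("=", pair, fixed = TRUE)
      if (eq < 0L) fhir_error(400L, sprintf("malformed parameter '%s'", pair))
      name <- url_decode(substring(pair, 1L, eq - 1L))
      value <- url_decode(substring(pair, eq + 1L))
      if (name == "_include") {
        inc <- strsplit(value, ":", fixed = TRUE)[[1]]
        if (length(inc) != 2L || inc[1] != rtype || !(inc[2] %in% spec$includes)) {
          fhir_error(400L, sprintf(
            "_include '%s' is not supported for %s", value, rtype))
        }
        includes <- union(includes, inc[2])
      } else if (name == "_format") {
        format <- switch(value,
          json = , `application/json` = , `application/json+fhir` = "json",
          xml = , `application/xml` = , `application/xml+fhir` = "xml",
          fhir_error(400L, sprintf("_format '%s' is not supported", value)))
      } else if (name == "_count") {
        if (!grepl("^\\d+$", value)) {
          fhir_error(400L, sprintf("_count '%s' is not a non-negative integer", value))
        }
        count <- as.numeric(value)
      } else if (name %in% spec$filters) {
        if (!nzchar(value)) {
          fhir_error(400L, sprintf("search parameter '%s' has an empty value", name))
        }
        if (name %in% names(filters)) {
          fhir_error(400L, sprintf("search parameter '%s' given more than once", name))
        }
        filters[name] <- value
      } else {
        fhir_error(400L, sprintf(
          "unknown search parameter '%s' for %s", name, rtype))
      }
    }
  }
  structure(list(resource_type = rtype, filters = filters,
                 includes = includes, format = format, count = count),
            class = "fhir_search_query")
}

# Chained medication.code values dispatch on shape: 13 digits = CIP
# presentation code, letter-digit ATC class pattern = ATC; an explicit
# "system|code" prefix overrides the shape rule.
dispatch_medication_code <- function(value, config) {
  if (grepl("|", value, fixed = TRUE)) {
    parts <- strsplit(value, "|", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !nzchar(parts[2])) {
      fhir_error(400L, sprintf("malformed system|code value '%s'", value))
    }
    system <- parts[1]
    code <- parts[2]
    if (system == config$system_uris[["CIP"]]) return(list(ns = "CIP", code = code))
    if (system == config$system_uris[["ATC"]]) return(list(ns = "ATC", code = code))
    fhir_error(400L, sprintf("unknown medication code system '%s'", system))
  }
  if (grepl("^[0-9]{13}$", value)) return(list(ns = "CIP", code = value))
  if (grepl("^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$", value)) {
    return(list(ns = "ATC", code = value))
  }
  # neither shape: a valid search that can match nothing
  list(ns = "CIP", code = value)
}

#' Execute a parsed search against the warehouse
#'
#' Runs the query's filter through the warehouse find operations (simple
#' `code` filter via the ICD-10 lookup; chained `medication.code` via the CIP
#' lookup, or the ATC crosswalk expansion when the value has ATC shape), maps
#' every matching fact row to its resource, and packages the requested
#' includes with [package_references()]. An empty result is a valid Bundle
#' with total 0. Without a filter, every fact of the resource's terminology
#' namespace matches.
#'
#' @param q A [parse_search_request()] result.
#' @param h A `cdw` handle.
#' @param ctx A [terminology_context()]; defaults to the handle's.
#' @param config A [fhir_config()].
#' @return A searchset [fhir_bundle()].
#' @export
execute_search <- function(q, h, ctx = NULL, config = fhir_config()) {
  stopifnot(inherits(q, "fhir_search_query"), inherits(h, "cdw"))
  if (is.null(ctx)) ctx <- terminology_context_from(h, config$system_uris)

  rows <- if (q$resource_type == "DiagnosticReport") {
    if ("code" %in% names(q$filters)) {
      find_observations_by_icd10(h, q$filters[["code"]])
    } else {
      find_by_namespace(h, "ICD10")
    }
  } else {
    if ("medication.code" %in% names(q$filters)) {
      d <- dispatch_medication_code(q$filters[["medication.code"]], config)
      if (d$ns == "CIP") find_observations_by_cip(h, d$code)
      else find_observations_by_atc(h, d$code)
    } else {
      find_by_namespace(h, "CIP")
    }
  }
  cap <- min(q$count, config$count_cap)
  if (is.finite(cap) && nrow(rows) > cap) {
    rows <- rows[seq_len(cap), , drop = FALSE]
  }

  n <- nrow(rows)
  if (q$resource_type == "DiagnosticReport") {
    matches <- lapply(seq_len(n), function(i)
      to_diagnostic_report(joined_row(rows, i), ctx))
    related <- lapply(seq_len(n), function(i) {
      j <- joined_row(rows, i)
      list(patient = to_patient(j, ctx), encounter = to_encounter(j, ctx),
           medication = NULL)
    })
  } else {
    mapped <- lapply(seq_len(n), function(i)
      to_medication_order(joined_row(rows, i), ctx))
    matches <- lapply(mapped, `[[`, "order")
    related <- lapply(seq_len(n), function(i) {
      j <- joined_row(rows, i)
      list(patient = to_patient(j, ctx), encounter = to_encounter(j, ctx),
           medication = mapped[[i]]$medication)
    })
  }
  package_references(matches, q, related, config)
}

#' Package related resources into a searchset Bundle
#'
#' Applies the reference-packaging rules to the matched resources. In the
#' default `"figures"` packaging, a requested Patient or Encounter is placed
#' in each match's `contained` list and referenced as `"#<id>"` (the
#' contained Encounter's own patient reference is rewritten to `"#<id>"` too
#' when the Patient sits beside it); a requested Medication is emitted once
#' per distinct drug as an include entry at the end of the Bundle, referenced
#' literally as `"Medication/<id>"`. Related resources that were not
#' requested stay as literal references and are not included. `"external"`
#' packaging instead emits every requested related resource as a deduplicated
#' include entry.
#'
#' @param matches List of matched resources (DiagnosticReport or
#'   MedicationOrder), in result order.
#' @param q The [parse_search_request()] query (its `includes` drive the
#'   packaging).
#' @param related List parallel to `matches`; each element a list with the
#'   match's resolved `patient`, `encounter` and (for orders) `medication`.
#' @param config A [fhir_config()].
#' @return A searchset [fhir_bundle()].
#' @export
package_references <- function(matches, q, related, config = fhir_config()) {
  stopifnot(length(matches) == length(related))
  patient_param <- if (q$resource_type == "DiagnosticReport") "subject" else "patient"
  want_patient <- patient_param %in% q$includes
  want_encounter <- "encounter" %in% q$includes
  want_medication <- "medication" %in% q$includes
  contain <- config$packaging == "figures"

  includes <- list()
  include_keys <- character()
  add_include <- function(r) {
    key <- paste0(r$resourceType, "/", r$id)
    if (!(key %in% include_keys)) {
      includes[[length(includes) + 1L]] <<- r
      include_keys <<- c(include_keys, key)
    }
  }

  out <- vector("list", length(matches))
  for (i in seq_along(matches)) {
    m <- matches[[i]]
    rel <- related[[i]]
    contained <- list()
    if (want_patient && !is.null(rel$patient)) {
      if (contain) {
        contained <- c(contained, list(rel$patient))
        m[[patient_param]] <- fhir_reference(paste0("#", rel$patient$id))
      } else {
        add_include(rel$patient)
      }
    }
    if (want_encounter && !is.null(rel$encounter)) {
      enc <- rel$encounter
      if (contain) {
        if (want_patient && !is.null(rel$patient)) {
          # sibling contained resources may reference each other locally
          enc$patient <- fhir_reference(paste0("#", rel$patient$id))
        }
        contained <- c(contained, list(enc))
        m$encounter <- fhir_reference(paste0("#", enc$id))
      } else {
        add_include(enc)
      }
    }
    if (want_medication && !is.null(rel$medication)) {
      add_include(rel$medication)
    }
    if (length(contained) > 0L) {
      # rebuild so 'contained' sits in its canonical position after id
      m <- if (m$resourceType == "DiagnosticReport") {
        fhir_diagnostic_report(m$id, m$code, m$subject, m$encounter,
                               m$effectiveDateTime, contained)
      } else {
        fhir_medication_order(m$id, m$dateWritten, m$patient, m$encounter,
                              m$medicationReference, contained)
      }
    }
    out[[i]] <- m
  }
  fhir_bundle(matches = out, includes = includes)
}

#' Run a FHIR search URL against a warehouse
#'
#' Convenience wrapper: [parse_search_request()] then [execute_search()].
#'
#' @param h A `cdw` handle.
#' @param url Relative FHIR search URL, e.g.
#'   `"DiagnosticReport?code=M321&_include=DiagnosticReport:subject"`.
#' @inheritParams execute_search
#' @return A searchset [fhir_bundle()].
#' @export
fhir_search <- function(h, url, ctx = NULL, config = fhir_config()) {
  execute_search(parse_search_request(url), h, ctx, config)
}
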