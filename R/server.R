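# HTTP facade. The whole surface is a pure request -> response function
# (Rook application), so the status codes, media types and bodies can be
# exercised directly; serve() runs the same application on a real socket via
# httpuv when that package is installed.

operation_outcome_json <- function(severity, msg) {
  as.character(jsonlite::toJSON(list(
    resourceType = "OperationOutcome",
    issue = list(list(severity = severity, diagnostics = msg))),
    auto_unbox = TRUE))
}

negotiate_format <- function(q_format, query_has_format, accept) {
  if (query_has_format) return(q_format)
  if (!is.null(accept) && grepl("xml", accept, fixed = TRUE)) return("xml")
  "json"
}

#' Handle one FHIR HTTP request
#'
#' The server's request dispatcher: a search interaction
#' (`GET <base>/<ResourceType>?...`) returns a serialized searchset Bundle; a
#' read interaction (`GET <base>/<ResourceType>/<id>`) returns the single
#' resource. Parse and lookup failures map to HTTP 400/404 with an
#' OperationOutcome body; unexpected failures map to a generic 500 that never
#' leaks internal error details. The response format follows `_format` when
#' given, else an XML `Accept` header, else JSON.
#'
#' @param h A `cdw` handle.
#' @param path Request path, e.g. `"/DiagnosticReport"`.
#' @param query_string Raw query string without the leading `?`.
#' @param ctx A [terminology_context()]; defaults to the handle's.
#' @param config A [fhir_config()].
#' @param method HTTP method; only GET is served.
#' @param accept Value of the Accept header, if any.
#' @return List with elements `status`, `content_type` and `body`.
#' @export
handle_request <- function(h, path, query_string = "", ctx = NULL,
                           config = fhir_config(), method = "GET",
                           accept = NULL) {
  if (is.null(ctx)) ctx <- terminology_context_from(h, config$system_uris)
  response <- function(status, content_type, body) {
    list(status = status, content_type = content_type, body = body)
  }
  tryCatch({
    if (!identical(method, "GET")) {
      return(response(405L, "application/json+fhir",
                      operation_outcome_json("error", "only GET is supported")))
    }
    segments <- strsplit(path, "/", fixed = TRUE)[[1]]
    segments <- segments[nzchar(segments)]
    is_read <- length(segments) >= 2L &&
      segments[length(segments) - 1L] %in% FHIR_SERVED_TYPES
    if (is_read) {
      rtype <- segments[length(segments) - 1L]
      id <- segments[length(segments)]
      fq <- parse_read_format(query_string)
      format <- negotiate_format(fq$format, fq$has_format, accept)
      r <- resource_read(h, rtype, id, ctx)
      wire <- to_wire(r, format)
      response(200L, wire$media_type, wire$body)
    } else {
      q <- parse_search_request(path, query_string)
      format <- negotiate_format(q$format,
                                 grepl("(^|&)_format=", query_string),
                                 accept)
      bundle <- execute_search(q, h, ctx, config)
      wire <- to_wire(bundle, format)
      response(200L, wire$media_type, wire$body)
    }
  },
  fhir_error = function(e) {
    status <- attr(e, "status") %||% e$status %||% 400L
    response(as.integer(status), "application/json+fhir",
             operation_outcome_json("error", conditionMessage(e)))
  },
  cdw_argument_error = function(e) {
    response(400L, "application/json+fhir",
             operation_outcome_json("error", conditionMessage(e)))
  },
  error = function(e) {
    response(500L, "application/json+fhir",
             operation_outcome_json("fatal", "internal server error"))
  })
}

parse_read_format <- function(query_string) {
  has <- FALSE
  format <- "json"
  if (!is.null(query_string) && nzchar(query_string)) {
    for (pair in strsplit(query_string, "&", fixed = TRUE)[[1]]) {
      eq <- regexpr("=", pair, fixed = TRUE)
      if (eq < 0L) next
      if (substring(pair, 1L, eq - 1L) == "_format") {
        has <- TRUE
        value <- url_decode(substring(pair, eq + 1L))
        format <- if (grepl("xml", value, fixed = TRUE)) "xml" else "json"
      }
    }
  }
  list(format = format, has_format = has)
}

# Read interaction: resource ids are deterministic functions of the source
# keys, so a read is answered by parsing the id and looking the keys up.
resource_read <- function(h, rtype, id, ctx) {
  not_found <- function() fhir_error(404L, sprintf("%s/%s not found", rtype, id))
  switch(rtype,
    Patient = {
      n <- suppressWarnings(as.integer(sub("^pat-", "", id)))
      i <- match(n, h$patients$patient_num)
      if (!startsWith(id, "pat-") || is.na(i)) not_found()
      to_patient(as.list(h$patients[i, ]), ctx)
    },
    Encounter = {
      n <- suppressWarnings(as.integer(sub("^enc-", "", id)))
      i <- match(n, h$visits$encounter_num)
      if (!startsWith(id, "enc-") || is.na(i)) not_found()
      to_encounter(as.list(h$visits[i, ]), ctx)
    },
    Medication = {
      code <- sub("^med-", "", id)
      i <- match(paste0("CIP:", code), h$concepts$concept_cd)
      if (!startsWith(id, "med-") || is.na(i)) not_found()
      to_medication(as.list(h$concepts[i, ]), ctx)
    },
    DiagnosticReport = read_fact_resource(h, id, "dr", "ICD10", ctx, not_found),
    MedicationOrder = read_fact_resource(h, id, "mo", "CIP", ctx, not_found),
    not_found()
  )
}

read_fact_resource <- function(h, id, prefix, namespace, ctx, not_found) {
  parts <- strsplit(id, "-", fixed = TRUE)[[1]]
  if (length(parts) != 6L || parts[1] != prefix) not_found()
  pn <- suppressWarnings(as.integer(parts[2]))
  en <- suppressWarnings(as.integer(parts[3]))
  code <- parts[4]
  date <- paste0(substring(parts[5], 1, 4), "-", substring(parts[5], 5, 6),
                 "-", substring(parts[5], 7, 8))
  inst <- suppressWarnings(as.integer(parts[6]))
  idx <- which(h$facts$patient_num == pn & h$facts$encounter_num == en &
                 h$facts$concept_cd == paste0(namespace, ":", code) &
                 h$facts$start_date == date & h$facts$instance_num == inst)
  if (length(idx) != 1L) not_found()
  j <- joined_row(join_facts(h, idx), 1L)
  if (prefix == "dr") to_diagnostic_report(j, ctx)
  else to_medication_order(j, ctx)$order
}

#' Rook application wrapping the FHIR request handler
#'
#' Returns a function of a Rook request environment suitable for
#' `httpuv::startServer()`; [serve()] is the ready-made runner.
#'
#' @inheritParams handle_request
#' @return `function(req)` returning a Rook response list.
#' @export
fhir_app <- function(h, ctx = NULL, config = fhir_config()) {
  if (is.null(ctx)) ctx <- terminology_context_from(h, config$system_uris)
  force(h); force(config)
  function(req) {
    qs <- req$QUERY_STRING %||% ""
    qs <- sub("^\\?", "", qs)
    res <- handle_request(h, req$PATH_INFO %||% "/", qs, ctx, config,
                          method = req$REQUEST_METHOD %||% "GET",
                          accept = req$HTTP_ACCEPT)
    list(status = res$status,
         headers = list("Content-Type" = paste0(res$content_type,
                                                ";charset=utf-8")),
         body = res$body)
  }
}

#' Serve a warehouse over HTTP
#'
#' Blocks and serves GET search and read interactions on
#' `http://<host>:<port>/...` until interrupted. Requires the `httpuv`
#' package.
#'
#' @inheritParams handle_request
#' @param host,port Listen address.
#' @export
serve <- function(h, ctx = NULL, config = fhir_config(),
                  host = "127.0.0.1", port = 8080L) {
  if (!requireNamespace("httpuv", quietly = TRUE)) {
    stop("serve() needs the 'httpuv' package; use fhir_app()/handle_request() otherwise")
  }
  message(sprintf("FHIR layer listening on http://%s:%d/", host, port))
  httpuv::runServer(host, port, list(call = fhir_app(h, ctx, config)))
}
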