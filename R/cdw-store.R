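# In-memory representation of the targeted i2b2 star-schema subset:
# observation_fact joined to the patient, visit, concept and provider
# dimensions, queried by terminology code.

CDW_TABLES <- c("observation_fact", "patient_dimension", "visit_dimension",
                "concept_dimension", "provider_dimension")

CDW_COLUMNS <- list(
  observation_fact  = c("patient_num", "encounter_num", "concept_cd",
                        "provider_id", "start_date", "end_date",
                        "instance_num"),
  patient_dimension = c("patient_num", "birth_date", "sex_cd"),
  visit_dimension   = c("encounter_num", "patient_num", "start_date",
                        "end_date"),
  concept_dimension = c("concept_cd", "concept_path", "name_char"),
  provider_dimension = c("provider_id", "name_char")
)

cdw_load_error <- function(msg) {
  stop(errorCondition(msg, class = c("cdw_load_error", "error")))
}

cdw_argument_error <- function(msg) {
  stop(errorCondition(msg, class = c("cdw_argument_error", "error")))
}

is_iso_date <- function(x) {
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  ok[ok] <- !is.na(as.Date(x[ok], format = "%Y-%m-%d"))
  ok
}

# Empty string and NA both mean "absent" for nullable date columns.
normalize_date_col <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & !nzchar(x)] <- NA_character_
  x
}

check_date_col <- function(x, table, column, nullable = FALSE) {
  x <- normalize_date_col(x)
  bad <- if (nullable) which(!is.na(x) & !is_iso_date(x)) else
    which(is.na(x) | !is_iso_date(x))
  if (length(bad) > 0L) {
    cdw_load_error(sprintf(
      "%s: malformed date in column '%s' at row %d (got '%s'); dates must be ISO-8601 (YYYY-MM-DD)",
      table, column, bad[1L], x[bad[1L]]))
  }
  x
}

check_fk <- function(child, keys, parent_keys, table, column, parent) {
  bad <- which(!(keys %in% parent_keys))
  if (length(bad) > 0L) {
    cdw_load_error(sprintf(
      "%s: foreign key violation at row %d: %s '%s' not present in %s",
      table, bad[1L], column, keys[bad[1L]], parent))
  }
  invisible(NULL)
}

#' Load an i2b2 star-schema subset into a queryable warehouse handle
#'
#' Builds an in-memory clinical data warehouse (CDW) handle from the five
#' targeted i2b2 tables. All referential-integrity invariants are checked at
#' load time: every `observation_fact` row must resolve to a patient, visit,
#' concept and provider; every visit must belong to a patient; dates must be
#' ISO-8601; a patient's birth date may not postdate any of their facts.
#'
#' @param tables Named list of data frames with elements `observation_fact`,
#'   `patient_dimension`, `visit_dimension`, `concept_dimension` and
#'   `provider_dimension`, each carrying the standard i2b2 columns for the
#'   targeted subset (see [cdw_generate()] for the exact layout).
#' @param crosswalk Optional data frame with columns `cip_code` and
#'   `atc_code`, the many-to-one CIP-to-ATC mapping used by
#'   [find_observations_by_atc()] and for Medication coding enrichment.
#' @return An object of class `cdw`: a queryable handle with per-table row
#'   counts available through [cdw_counts()].
#' @seealso [cdw_load_dir()] to read the CSV layout from disk,
#'   [find_observations_by_icd10()] and friends for querying.
#' @export
cdw_load <- function(tables, crosswalk = NULL) {
  if (!is.list(tables)) cdw_argument_error("'tables' must be a named list of data frames")
  missing_tabs <- setdiff(CDW_TABLES, names(tables))
  if (length(missing_tabs) > 0L) {
    cdw_load_error(paste0("missing table(s): ", paste(missing_tabs, collapse = ", ")))
  }
  for (tab in CDW_TABLES) {
    df <- tables[[tab]]
    if (!is.data.frame(df)) cdw_load_error(paste0(tab, ": not a data frame"))
    missing_cols <- setdiff(CDW_COLUMNS[[tab]], names(df))
    if (length(missing_cols) > 0L) {
      cdw_load_error(sprintf("%s: missing column(s): %s", tab,
                             paste(missing_cols, collapse = ", ")))
    }
  }

  pat <- tables$patient_dimension
  vis <- tables$visit_dimension
  con <- tables$concept_dimension
  pro <- tables$provider_dimension
  fct <- tables$observation_fact

  pat$patient_num <- as.integer(pat$patient_num)
  pat$birth_date <- check_date_col(pat$birth_date, "patient_dimension", "birth_date")
  pat$sex_cd <- as.character(pat$sex_cd)
  if (anyNA(pat$patient_num) || any(pat$patient_num <= 0L)) {
    cdw_load_error("patient_dimension: patient_num must be a positive integer")
  }
  if (anyDuplicated(pat$patient_num)) {
    cdw_load_error(sprintf("patient_dimension: duplicate patient_num '%s'",
                           pat$patient_num[duplicated(pat$patient_num)][1L]))
  }

  vis$encounter_num <- as.integer(vis$encounter_num)
  vis$patient_num <- as.integer(vis$patient_num)
  vis$start_date <- check_date_col(vis$start_date, "visit_dimension", "start_date")
  vis$end_date <- check_date_col(vis$end_date, "visit_dimension", "end_date",
                                 nullable = TRUE)
  if (anyDuplicated(vis$encounter_num)) {
    cdw_load_error(sprintf("visit_dimension: duplicate encounter_num '%s'",
                           vis$encounter_num[duplicated(vis$encounter_num)][1L]))
  }
  check_fk(vis, vis$patient_num, pat$patient_num,
           "visit_dimension", "patient_num", "patient_dimension")
  # ISO-8601 strings compare correctly as strings
  bad <- which(!is.na(vis$end_date) & vis$end_date < vis$start_date)
  if (length(bad) > 0L) {
    cdw_load_error(sprintf("visit_dimension: end_date before start_date at row %d", bad[1L]))
  }

  con$concept_cd <- as.character(con$concept_cd)
  con$concept_path <- as.character(con$concept_path)
  con$name_char <- as.character(con$name_char)
  if (anyDuplicated(con$concept_cd)) {
    cdw_load_error(sprintf("concept_dimension: duplicate concept_cd '%s'",
                           con$concept_cd[duplicated(con$concept_cd)][1L]))
  }

  pro$provider_id <- as.character(pro$provider_id)
  pro$name_char <- as.character(pro$name_char)
  if (anyDuplicated(pro$provider_id)) {
    cdw_load_error(sprintf("provider_dimension: duplicate provider_id '%s'",
                           pro$provider_id[duplicated(pro$provider_id)][1L]))
  }

  fct$patient_num <- as.integer(fct$patient_num)
  fct$encounter_num <- as.integer(fct$encounter_num)
  fct$concept_cd <- as.character(fct$concept_cd)
  fct$provider_id <- as.character(fct$provider_id)
  fct$instance_num <- as.integer(fct$instance_num)
  fct$start_date <- check_date_col(fct$start_date, "observation_fact", "start_date")
  fct$end_date <- check_date_col(fct$end_date, "observation_fact", "end_date",
                                 nullable = TRUE)
  check_fk(fct, fct$patient_num, pat$patient_num,
           "observation_fact", "patient_num", "patient_dimension")
  check_fk(fct, fct$encounter_num, vis$encounter_num,
           "observation_fact", "encounter_num", "visit_dimension")
  check_fk(fct, fct$concept_cd, con$concept_cd,
           "observation_fact", "concept_cd", "concept_dimension")
  check_fk(fct, fct$provider_id, pro$provider_id,
           "observation_fact", "provider_id", "provider_dimension")
  key <- paste(fct$patient_num, fct$encounter_num, fct$concept_cd,
               fct$start_date, fct$instance_num, sep = "\r")
  if (anyDuplicated(key)) {
    cdw_load_error(sprintf(
      "observation_fact: duplicate (patient_num, encounter_num, concept_cd, start_date, instance_num) at row %d",
      which(duplicated(key))[1L]))
  }
  if (nrow(fct) > 0L) {
    birth <- pat$birth_date[match(fct$patient_num, pat$patient_num)]
    bad <- which(birth > fct$start_date)
    if (length(bad) > 0L) {
      cdw_load_error(sprintf(
        "observation_fact: row %d starts before patient %d's birth date",
        bad[1L], fct$patient_num[bad[1L]]))
    }
  }

  if (!is.null(crosswalk)) {
    if (!all(c("cip_code", "atc_code") %in% names(crosswalk))) {
      cdw_load_error("crosswalk: must have columns cip_code and atc_code")
    }
    crosswalk <- data.frame(cip_code = as.character(crosswalk$cip_code),
                            atc_code = as.character(crosswalk$atc_code),
                            stringsAsFactors = FALSE)
    if (anyDuplicated(crosswalk$cip_code)) {
      cdw_load_error("crosswalk: cip_code must map to at most one atc_code")
    }
  } else {
    crosswalk <- data.frame(cip_code = character(), atc_code = character(),
                            stringsAsFactors = FALSE)
  }

  structure(list(
    patients = pat[, CDW_COLUMNS$patient_dimension],
    visits = vis[, CDW_COLUMNS$visit_dimension],
    concepts = con[, CDW_COLUMNS$concept_dimension],
    providers = pro[, CDW_COLUMNS$provider_dimension],
    facts = fct[, CDW_COLUMNS$observation_fact],
    crosswalk = crosswalk
  ), class = "cdw")
}

#' Load a warehouse from a directory of CSV files
#'
#' Reads the CSV layout written by [cdw_write_fixture()]: one UTF-8 file per
#' i2b2 table (`observation_fact.csv`, `patient_dimension.csv`,
#' `visit_dimension.csv`, `concept_dimension.csv`, `provider_dimension.csv`),
#' plus, when present, the two-column `cip_atc.csv` crosswalk.
#'
#' @param dir Directory containing the CSV files.
#' @return A `cdw` handle, as from [cdw_load()].
#' @export
cdw_load_dir <- function(dir) {
  if (!dir.exists(dir)) cdw_load_error(paste0("directory not found: ", dir))
  tables <- list()
  for (tab in CDW_TABLES) {
    path <- file.path(dir, paste0(tab, ".csv"))
    if (!file.exists(path)) cdw_load_error(paste0("missing table file: ", path))
    tables[[tab]] <- utils::read.csv(path, colClasses = "character",
                                     stringsAsFactors = FALSE)
  }
  cw_path <- file.path(dir, "cip_atc.csv")
  crosswalk <- if (file.exists(cw_path)) {
    utils::read.csv(cw_path, colClasses = "character", stringsAsFactors = FALSE)
  } else NULL
  cdw_load(tables, crosswalk)
}

#' Per-table row counts of a warehouse handle
#'
#' @param h A `cdw` handle.
#' @return Named integer vector over the five i2b2 tables.
#' @export
cdw_counts <- function(h) {
  stopifnot(inherits(h, "cdw"))
  c(observation_fact = nrow(h$facts),
    patient_dimension = nrow(h$patients),
    visit_dimension = nrow(h$visits),
    concept_dimension = nrow(h$concepts),
    provider_dimension = nrow(h$providers))
}

#' @export
print.cdw <- function(x, ...) {
  cat("<cdw> i2b2 star-schema warehouse\n")
  n <- cdw_counts(x)
  for (i in seq_along(n)) cat(sprintf("  %-20s %d rows\n", names(n)[i], n[i]))
  cat(sprintf("  %-20s %d rows\n", "cip_atc crosswalk", nrow(x$crosswalk)))
  invisible(x)
}

# Star join of a subset of fact rows to their patient, visit and concept
# dimension rows, in the deterministic result order.
join_facts <- function(h, idx) {
  f <- h$facts[idx, , drop = FALSE]
  pi <- match(f$patient_num, h$patients$patient_num)
  vi <- match(f$encounter_num, h$visits$encounter_num)
  ci <- match(f$concept_cd, h$concepts$concept_cd)
  out <- data.frame(
    patient_num = f$patient_num,
    encounter_num = f$encounter_num,
    concept_cd = f$concept_cd,
    provider_id = f$provider_id,
    start_date = f$start_date,
    end_date = f$end_date,
    instance_num = f$instance_num,
    birth_date = h$patients$birth_date[pi],
    sex_cd = h$patients$sex_cd[pi],
    visit_start_date = h$visits$start_date[vi],
    visit_end_date = h$visits$end_date[vi],
    concept_path = h$concepts$concept_path[ci],
    name_char = h$concepts$name_char[ci],
    stringsAsFactors = FALSE
  )
  ord <- order(out$patient_num, out$encounter_num, out$start_date,
               out$instance_num, out$concept_cd)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

find_by_concept_cds <- function(h, concept_cds) {
  join_facts(h, which(h$facts$concept_cd %in% concept_cds))
}

# All facts whose concept lives in the given terminology namespace.
find_by_namespace <- function(h, namespace) {
  join_facts(h, which(startsWith(h$facts$concept_cd, paste0(namespace, ":"))))
}

#' Find observations by diagnosis, medication or drug-class code
#'
#' The three query operations of the warehouse service layer. Each returns the
#' fact rows whose concept matches the requested code, star-joined to the
#' patient, visit and concept dimensions, in a stable order
#' (`patient_num`, `encounter_num`, `start_date`, `instance_num`).
#'
#' Concept codes are namespaced in `concept_cd`: diagnosis facts use
#' `ICD10:<code>`, medication-order facts `CIP:<code>`. An ATC query is
#' answered by expanding the ATC class to its CIP presentation codes through
#' the loaded crosswalk, so it matches every presentation of every drug in the
#' class; no facts are stored at ATC granularity.
#'
#' @param h A `cdw` handle from [cdw_load()].
#' @param code Non-empty code string: an ICD-10 diagnosis code (e.g. `"M321"`),
#'   a 13-digit CIP presentation code, or an ATC class code (e.g. `"C07AB07"`).
#' @return Data frame of joined observations, zero rows when the code matches
#'   no fact.
#' @export
find_observations_by_icd10 <- function(h, code) {
  stopifnot(inherits(h, "cdw"))
  if (!is.character(code) || length(code) != 1L || is.na(code) || !nzchar(code)) {
    cdw_argument_error("'code' must be a non-empty ICD-10 code string")
  }
  find_by_concept_cds(h, paste0("ICD10:", code))
}

#' @rdname find_observations_by_icd10
#' @export
find_observations_by_cip <- function(h, code) {
  stopifnot(inherits(h, "cdw"))
  if (!is.character(code) || length(code) != 1L || is.na(code) || !nzchar(code)) {
    cdw_argument_error("'code' must be a non-empty CIP code string")
  }
  find_by_concept_cds(h, paste0("CIP:", code))
}

#' @rdname find_observations_by_icd10
#' @export
find_observations_by_atc <- function(h, code) {
  stopifnot(inherits(h, "cdw"))
  if (!is.character(code) || length(code) != 1L || is.na(code) || !nzchar(code)) {
    cdw_argument_error("'code' must be a non-empty ATC code string")
  }
  cips <- h$crosswalk$cip_code[h$crosswalk$atc_code == code]
  if (length(cips) == 0L) return(join_facts(h, integer()))
  find_by_concept_cds(h, paste0("CIP:", cips))
}
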