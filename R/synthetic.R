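# Seeded generator of a synthetic i2b2 warehouse: patients with birth dates
# and sex codes, encounters with periods, ICD-10-coded diagnosis facts and
# CIP-coded medication-order facts (each CIP carrying an ATC parent in the
# crosswalk), plus a ground-truth manifest of per-code tallies so every query
# has an independent expected answer. The default configuration emulates the
# served slice of a hospital warehouse at desk scale, skewed towards elderly
# patients (the drug-surveillance population the layer was built to serve);
# the two worked query codes, ICD-10 M321 and CIP 3400893219874, are in the
# default pools so the canonical search URLs run verbatim against fixtures.

DEFAULT_ICD10_POOL <- data.frame(
  code = c("M321", "I10", "E119", "J189", "N390"),
  display = c("Systemic lupus erythematosus with organ involvement",
              "Essential hypertension",
              "Type 2 diabetes mellitus without complications",
              "Pneumonia, unspecified organism",
              "Urinary tract infection, site not specified"),
  weight = c(0.10, 0.30, 0.25, 0.20, 0.15),
  stringsAsFactors = FALSE)

DEFAULT_CIP_POOL <- data.frame(
  code = c("3400893219874", "3400891942341", "3400935955838",
           "3400930011201", "3400932796557"),
  atc = c("C07AB07", "C07AB07", "N02BE01", "B01AC06", "A10BA02"),
  display = c("BISOPROLOL BGR 1.25MG CPR", "BISOPROLOL BGR 2.50MG CPR",
              "PARACETAMOL BGR 500MG CPR", "ASPIRINE PROTECT 100MG CPR",
              "METFORMINE BGR 850MG CPR"),
  weight = c(0.20, 0.15, 0.30, 0.20, 0.15),
  stringsAsFactors = FALSE)

cdw_config_error <- function(msg) {
  stop(errorCondition(msg, class = c("cdw_config_error", "error")))
}

#' Configuration of the synthetic-warehouse generator
#'
#' All scale and content knobs of [cdw_generate()], validated. Defaults
#' describe a small warehouse with the content profile the layer serves:
#' diagnosis and drug-order facts only, an elderly-skewed population, and
#' code pools containing the two canonical query codes.
#'
#' @param n_patients Number of patients.
#' @param encounters_per_patient Inclusive integer range `c(min, max)`;
#'   sampled uniformly per patient.
#' @param facts_per_encounter Inclusive integer range; sampled uniformly per
#'   encounter.
#' @param icd10_codes Data frame `code`, `display`, `weight` (weights sum to
#'   1 within the pool).
#' @param cip_codes Data frame `code`, `atc`, `display`, `weight`; `atc` is
#'   the crosswalk parent of each presentation code.
#' @param diagnosis_fraction Probability that a fact is a diagnosis (the rest
#'   are medication orders).
#' @param date_window `c(start, end)` ISO dates bounding encounter starts.
#' @param elderly_fraction Proportion of patients aged 75 or more at the
#'   window start.
#' @param open_encounter_prob Probability an encounter has no end date.
#' @param n_providers Size of the provider dimension.
#' @param fixed_counts Optional scenario pinning: data frame with columns
#'   `namespace` (`"ICD10"`/`"CIP"`), `code`, `display`, `atc` (NA for
#'   diagnoses), `n_facts`, `n_patients`. Each pinned code receives exactly
#'   `n_facts` facts spread over exactly `n_patients` distinct patients, and
#'   is removed from the random pools.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return An object of class `cdw_config`.
#' @export
cdw_config <- function(n_patients = 200L,
                       encounters_per_patient = c(1L, 4L),
                       facts_per_encounter = c(1L, 5L),
                       icd10_codes = DEFAULT_ICD10_POOL,
                       cip_codes = DEFAULT_CIP_POOL,
                       diagnosis_fraction = 0.5,
                       date_window = c("2014-01-01", "2016-06-30"),
                       elderly_fraction = 0.7,
                       open_encounter_prob = 0.05,
                       n_providers = 8L,
                       fixed_counts = NULL,
                       seed = 42L) {
  cfg <- list(n_patients = as.integer(n_patients),
              encounters_per_patient = as.integer(encounters_per_patient),
              facts_per_encounter = as.integer(facts_per_encounter),
              icd10_codes = icd10_codes, cip_codes = cip_codes,
              diagnosis_fraction = diagnosis_fraction,
              date_window = as.character(date_window),
              elderly_fraction = elderly_fraction,
              open_encounter_prob = open_encounter_prob,
              n_providers = as.integer(n_providers),
              fixed_counts = fixed_counts, seed = as.integer(seed))
  if (cfg$n_patients <= 0L) cdw_config_error("n_patients must be positive")
  if (length(cfg$encounters_per_patient) != 2L ||
      cfg$encounters_per_patient[1] < 1L ||
      diff(cfg$encounters_per_patient) < 0L) {
    cdw_config_error("encounters_per_patient must be an increasing range with min >= 1")
  }
  if (length(cfg$facts_per_encounter) != 2L ||
      cfg$facts_per_encounter[1] < 0L || diff(cfg$facts_per_encounter) < 0L) {
    cdw_config_error("facts_per_encounter must be a non-decreasing range")
  }
  for (pool in list(cfg$icd10_codes, cfg$cip_codes)) {
    if (nrow(pool) > 0 && abs(sum(pool$weight) - 1) > 1e-8) {
      cdw_config_error("code pool weights must sum to 1")
    }
  }
  if (!all(is_iso_date(cfg$date_window)) ||
      cfg$date_window[1] >= cfg$date_window[2]) {
    cdw_config_error("date_window must be two ISO dates with start < end")
  }
  if (cfg$elderly_fraction < 0 || cfg$elderly_fraction > 1) {
    cdw_config_error("elderly_fraction must be in [0, 1]")
  }
  may_emit_facts <- cfg$facts_per_encounter[2] > 0L
  if (may_emit_facts && cfg$diagnosis_fraction > 0 && nrow(cfg$icd10_codes) == 0L) {
    cdw_config_error("diagnosis facts requested but the ICD-10 pool is empty")
  }
  if (may_emit_facts && cfg$diagnosis_fraction < 1 && nrow(cfg$cip_codes) == 0L) {
    cdw_config_error("medication facts requested but the CIP pool is empty")
  }
  if (!is.null(fixed_counts)) {
    needed <- c("namespace", "code", "display", "atc", "n_facts", "n_patients")
    if (!all(needed %in% names(fixed_counts))) {
      cdw_config_error(paste0("fixed_counts needs columns: ",
                              paste(needed, collapse = ", ")))
    }
    if (any(fixed_counts$n_patients > cfg$n_patients)) {
      cdw_config_error("fixed_counts n_patients exceeds the patient population")
    }
    if (any(fixed_counts$n_facts < fixed_counts$n_patients)) {
      cdw_config_error("fixed_counts n_facts must be >= n_patients")
    }
  }
  structure(cfg, class = "cdw_config")
}

sample_range <- function(n, range) {
  if (range[1] == range[2]) rep.int(range[1], n)
  else sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

sample_pool <- function(n, pool) {
  if (n == 0L) return(integer())
  sample.int(nrow(pool), n, replace = TRUE, prob = pool$weight)
}

#' Generate a synthetic i2b2 warehouse with its ground truth
#'
#' Emits the five i2b2 tables, the CIP-to-ATC crosswalk, and a ground-truth
#' manifest recording per-table row counts and, for every generated code, its
#' fact count and distinct-patient count (plus the same tallies per ATC
#' class). Fact dates always fall within their encounter's period; open
#' encounters receive facts within 14 days of admission. The output is fully
#' deterministic given the configuration, including its seed.
#'
#' @param cfg A [cdw_config()].
#' @return An object of class `cdw_fixture`: list with `tables` (named list
#'   of the five data frames), `crosswalk`, `ground_truth` and `config`.
#' @seealso [cdw_write_fixture()] to put the fixture on disk, [cdw_load()] to
#'   query it.
#' @export
cdw_generate <- function(cfg = cdw_config()) {
  stopifnot(inherits(cfg, "cdw_config"))
  set.seed(cfg$seed)
  win_start <- as.Date(cfg$date_window[1])
  win_end <- as.Date(cfg$date_window[2])
  win_days <- as.integer(win_end - win_start)

  # patients: elderly are >= 75 years old at the window start
  n <- cfg$n_patients
  elderly <- stats::runif(n) < cfg$elderly_fraction
  age_days <- integer(n)
  age_days[elderly] <- as.integer(stats::runif(sum(elderly), 75 * 365.25, 95 * 365.25))
  age_days[!elderly] <- as.integer(stats::runif(sum(!elderly), 18 * 365.25, 75 * 365.25))
  patients <- data.frame(
    patient_num = seq_len(n),
    birth_date = format(win_start - age_days, "%Y-%m-%d"),
    sex_cd = sample(c("M", "F", "U"), n, replace = TRUE,
                    prob = c(0.48, 0.48, 0.04)),
    stringsAsFactors = FALSE)

  # encounters: uniform start in the window, stay lengths 1-30 days with a
  # geometric tail, a few left open
  n_enc_per <- sample_range(n, cfg$encounters_per_patient)
  enc_patient <- rep.int(patients$patient_num, n_enc_per)
  n_enc <- length(enc_patient)
  enc_start <- win_start + as.integer(stats::runif(n_enc, 0, max(win_days - 30L, 1L)))
  enc_len <- pmin(1L + stats::rgeom(n_enc, 0.25), 30L)
  enc_open <- stats::runif(n_enc) < cfg$open_encounter_prob
  visits <- data.frame(
    encounter_num = seq_len(n_enc),
    patient_num = enc_patient,
    start_date = format(enc_start, "%Y-%m-%d"),
    end_date = ifelse(enc_open, NA_character_,
                      format(enc_start + enc_len, "%Y-%m-%d")),
    stringsAsFactors = FALSE)

  providers <- data.frame(
    provider_id = paste0("prov-", seq_len(cfg$n_providers)),
    name_char = paste("Provider", seq_len(cfg$n_providers)),
    stringsAsFactors = FALSE)

  # pinned scenario codes never appear in the random pools
  icd_pool <- cfg$icd10_codes
  cip_pool <- cfg$cip_codes
  fixed <- cfg$fixed_counts
  if (!is.null(fixed)) {
    icd_pool <- icd_pool[!(icd_pool$code %in% fixed$code[fixed$namespace == "ICD10"]), ]
    cip_pool <- cip_pool[!(cip_pool$code %in% fixed$code[fixed$namespace == "CIP"]), ]
    if (nrow(icd_pool) > 0) icd_pool$weight <- icd_pool$weight / sum(icd_pool$weight)
    if (nrow(cip_pool) > 0) cip_pool$weight <- cip_pool$weight / sum(cip_pool$weight)
  }

  # random facts: a diagnosis or a drug order per row, dated inside the
  # encounter period (open encounters: within 14 days of admission)
  n_facts_per <- sample_range(n_enc, cfg$facts_per_encounter)
  fact_enc <- rep.int(visits$encounter_num, n_facts_per)
  nf <- length(fact_enc)
  is_diag <- stats::runif(nf) < cfg$diagnosis_fraction
  if (nrow(icd_pool) == 0L) is_diag[] <- FALSE
  if (nrow(cip_pool) == 0L) is_diag[] <- TRUE
  concept_cd <- character(nf)
  concept_cd[is_diag] <- paste0("ICD10:",
                                icd_pool$code[sample_pool(sum(is_diag), icd_pool)])
  concept_cd[!is_diag] <- paste0("CIP:",
                                 cip_pool$code[sample_pool(sum(!is_diag), cip_pool)])
  span <- ifelse(enc_open, 14L, enc_len)[fact_enc]
  offset <- as.integer(floor(stats::runif(nf) * (span + 1L)))
  facts <- data.frame(
    patient_num = visits$patient_num[fact_enc],
    encounter_num = fact_enc,
    concept_cd = concept_cd,
    provider_id = providers$provider_id[sample.int(cfg$n_providers, nf, replace = TRUE)],
    start_date = format(enc_start[fact_enc] + offset, "%Y-%m-%d"),
    end_date = NA_character_,
    stringsAsFactors = FALSE)

  # pinned codes: exactly n_facts facts over exactly n_patients patients,
  # one anchor fact per selected patient, the remainder spread inside the
  # selection; facts attach to a random existing encounter of the patient
  if (!is.null(fixed)) {
    enc_by_patient <- split(visits$encounter_num, visits$patient_num)
    for (k in seq_len(nrow(fixed))) {
      sel <- sample(patients$patient_num, fixed$n_patients[k])
      extra <- fixed$n_facts[k] - fixed$n_patients[k]
      fact_pats <- c(sel, if (extra > 0L) sample(sel, extra, replace = TRUE))
      encs <- vapply(fact_pats, function(p) {
        e <- enc_by_patient[[as.character(p)]]
        if (length(e) == 1L) e else sample(e, 1L)
      }, integer(1))
      ei <- match(encs, visits$encounter_num)
      span <- ifelse(enc_open[ei], 14L, enc_len[ei])
      offset <- as.integer(floor(stats::runif(length(encs)) * (span + 1L)))
      facts <- rbind(facts, data.frame(
        patient_num = fact_pats,
        encounter_num = encs,
        concept_cd = paste0(fixed$namespace[k], ":", fixed$code[k]),
        provider_id = providers$provider_id[
          sample.int(cfg$n_providers, length(encs), replace = TRUE)],
        start_date = format(enc_start[ei] + offset, "%Y-%m-%d"),
        end_date = NA_character_,
        stringsAsFactors = FALSE))
    }
  }

  # repeated same-day orders of one concept are disambiguated by instance_num
  key <- paste(facts$patient_num, facts$encounter_num, facts$concept_cd,
               facts$start_date, sep = "\r")
  facts$instance_num <- stats::ave(integer(nrow(facts)), key,
                                   FUN = seq_along)

  used_icd <- icd_pool
  used_cip <- cip_pool
  if (!is.null(fixed)) {
    fi <- fixed[fixed$namespace == "ICD10", ]
    if (nrow(fi) > 0) used_icd <- rbind(used_icd[, c("code", "display")],
                                        data.frame(code = fi$code, display = fi$display))
    else used_icd <- used_icd[, c("code", "display")]
    fc <- fixed[fixed$namespace == "CIP", ]
    if (nrow(fc) > 0) used_cip <- rbind(used_cip[, c("code", "atc", "display")],
                                        data.frame(code = fc$code, atc = fc$atc,
                                                   display = fc$display))
    else used_cip <- used_cip[, c("code", "atc", "display")]
  } else {
    used_icd <- used_icd[, c("code", "display")]
    used_cip <- used_cip[, c("code", "atc", "display")]
  }

  concepts <- rbind(
    if (nrow(used_icd) > 0) data.frame(
      concept_cd = paste0("ICD10:", used_icd$code),
      concept_path = paste0("\\Diagnoses\\ICD10\\", used_icd$code, "\\"),
      name_char = used_icd$display, stringsAsFactors = FALSE),
    if (nrow(used_cip) > 0) data.frame(
      concept_cd = paste0("CIP:", used_cip$code),
      concept_path = paste0("\\Medications\\CIP\\", used_cip$code, "\\"),
      name_char = used_cip$display, stringsAsFactors = FALSE))
  if (is.null(concepts)) {
    concepts <- data.frame(concept_cd = character(), concept_path = character(),
                           name_char = character(), stringsAsFactors = FALSE)
  }

  crosswalk <- data.frame(cip_code = used_cip$code, atc_code = used_cip$atc,
                          stringsAsFactors = FALSE)
  crosswalk <- crosswalk[!is.na(crosswalk$atc_code), , drop = FALSE]
  rownames(crosswalk) <- NULL

  tables <- list(observation_fact = facts,
                 patient_dimension = patients,
                 visit_dimension = visits,
                 concept_dimension = concepts,
                 provider_dimension = providers)

  structure(list(tables = tables, crosswalk = crosswalk,
                 ground_truth = tally_ground_truth(tables, crosswalk),
                 config = cfg),
            class = "cdw_fixture")
}

# Full-scan tallies of the emitted tables; this is the manifest every query
# result can be checked against.
tally_ground_truth <- function(tables, crosswalk) {
  facts <- tables$observation_fact
  per_code <- function(cds) {
    do.call(rbind, lapply(cds, function(cd) {
      idx <- facts$concept_cd == cd
      data.frame(concept_cd = cd, n_facts = sum(idx),
                 n_patients = length(unique(facts$patient_num[idx])),
                 stringsAsFactors = FALSE)
    }))
  }
  codes <- per_code(sort(unique(tables$concept_dimension$concept_cd)))
  if (is.null(codes)) {
    codes <- data.frame(concept_cd = character(), n_facts = integer(),
                        n_patients = integer(), stringsAsFactors = FALSE)
  }
  atc <- do.call(rbind, lapply(sort(unique(crosswalk$atc_code)), function(a) {
    cds <- paste0("CIP:", crosswalk$cip_code[crosswalk$atc_code == a])
    idx <- facts$concept_cd %in% cds
    data.frame(atc_code = a, n_facts = sum(idx),
               n_patients = length(unique(facts$patient_num[idx])),
               stringsAsFactors = FALSE)
  }))
  if (is.null(atc)) {
    atc <- data.frame(atc_code = character(), n_facts = integer(),
                      n_patients = integer(), stringsAsFactors = FALSE)
  }
  list(table_counts = vapply(tables, nrow, integer(1)),
       codes = codes, atc = atc)
}

#' Write a generated fixture to a directory of CSV files
#'
#' Emits the five i2b2 table CSVs, `cip_atc.csv` and a `ground_truth.json`
#' manifest. Refuses to overwrite existing fixture files unless
#' `force = TRUE`.
#'
#' @param fixture A [cdw_generate()] result.
#' @param dir Output directory (created if needed).
#' @param force Overwrite existing files.
#' @return `dir`, invisibly.
#' @export
cdw_write_fixture <- function(fixture, dir, force = FALSE) {
  stopifnot(inherits(fixture, "cdw_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(paste0(CDW_TABLES, ".csv"), "cip_atc.csv", "ground_truth.json")
  existing <- files[file.exists(file.path(dir, files))]
  if (length(existing) > 0L && !force) {
    stop("refusing to overwrite ", paste(existing, collapse = ", "),
         " in ", dir, " (use force = TRUE)")
  }
  for (tab in CDW_TABLES) {
    utils::write.csv(fixture$tables[[tab]], file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE, na = "")
  }
  utils::write.csv(fixture$crosswalk, file.path(dir, "cip_atc.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(fixture$ground_truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(dir)
}

#' @export
print.cdw_fixture <- function(x, ...) {
  cat("<cdw_fixture> synthetic i2b2 warehouse (seed ", x$config$seed, ")\n",
      sep = "")
  n <- x$ground_truth$table_counts
  for (i in seq_along(n)) cat(sprintf("  %-20s %d rows\n", names(n)[i], n[i]))
  invisible(x)
}
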