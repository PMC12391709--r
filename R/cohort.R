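#' @rdname ade_cohort
#' @export
ANALYTES <- c(
  eosinophils_abs = "10^9/L", platelets = "10^9/L", leukocytes = "10^9/L",
  alt = "U/L", ast = "U/L", total_bilirubin = "umol/L", alp = "U/L",
  bun = "mmol/L", creatinine = "umol/L", hemoglobin = "g/L", sodium = "mmol/L"
)

empty_labs <- function() {
  tibble::tibble(patient_id = character(), analyte = character(),
                 value = double(), timestamp = as.POSIXct(character(), tz = "UTC"))
}
empty_medications <- function() {
  tibble::tibble(patient_id = character(), drug_name = character(),
                 start = as.POSIXct(character(), tz = "UTC"),
                 stop = as.POSIXct(character(), tz = "UTC"),
                 is_target_pah_drug = logical(), stopped_abruptly = logical())
}
empty_events <- function() {
  tibble::tibble(patient_id = character(), term = character(),
                 timestamp = as.POSIXct(character(), tz = "UTC"))
}
empty_interventions <- function() {
  tibble::tibble(patient_id = character(), kind = character(),
                 timestamp = as.POSIXct(character(), tz = "UTC"))
}
empty_patients <- function() {
  tibble::tibble(patient_id = character(), age_at_admission = double(),
                 sex = character(), admission_date = as.Date(character()),
                 discharge_date = as.Date(character()),
                 n_comorbidities = integer(), n_prior_hospitalizations = integer(),
                 target_drug_classes = character())
}

#' Assemble and validate a hospitalization cohort
#'
#' A cohort is a small relational model of one hospital admission per row of
#' `patients`, with four child streams keyed by `patient_id`: laboratory
#' observations, medication exposures, coded clinical events and
#' interventions. All inclusion-criterion invariants are enforced here:
#' discharge on or after admission, age above 28 days, at least one targeted
#' drug class, at least one (the current) hospitalization on record,
#' non-negative laboratory values timestamped within the stay, and medication
#' intervals with `start <= stop`. Event terms are resolved against the
#' controlled symptom vocabulary and medication names against the drug
#' dictionary (unknown drugs resolve to class `"other"`).
#'
#' @param patients Tibble with columns `patient_id`, `age_at_admission`
#'   (fractional years), `sex` (`"male"`/`"female"`), `admission_date`,
#'   `discharge_date` (Date), `n_comorbidities`, `n_prior_hospitalizations`,
#'   `target_drug_classes` (`;`-separated identifiers of the targeted drugs).
#' @param labs,medications,events,interventions Child stream tibbles; see the
#'   `empty_*()` templates for the expected columns. Defaults are empty.
#' @param dictionary,vocabulary Controlled vocabularies; defaults are the
#'   shipped ones.
#' @return An object of class `ade_cohort`: a named list of validated tibbles
#'   (`patients`, `labs`, `medications`, `events`, `interventions`) with
#'   stable per-stream row identifiers (`lab_id`, `med_id`, `event_id`,
#'   `intervention_id`), resolved `drug_class` on medications and canonical
#'   `code` on events.
#' @examples
#' pts <- tibble::tibble(
#'   patient_id = "p1", age_at_admission = 42, sex = "female",
#'   admission_date = as.Date("2022-03-01"), discharge_date = as.Date("2022-03-09"),
#'   n_comorbidities = 3L, n_prior_hospitalizations = 1L,
#'   target_drug_classes = "sildenafil"
#' )
#' coh <- ade_cohort(pts)
#' length_of_stay(coh)
#' @export
ade_cohort <- function(patients,
                       labs = empty_labs(),
                       medications = empty_medications(),
                       events = empty_events(),
                       interventions = empty_interventions(),
                       dictionary = load_drug_dictionary(),
                       vocabulary = load_symptom_vocabulary()) {
  patients <- tibble::as_tibble(patients)
  labs <- tibble::as_tibble(labs)
  medications <- tibble::as_tibble(medications)
  events <- tibble::as_tibble(events)
  interventions <- tibble::as_tibble(interventions)

  req <- names(empty_patients())
  missing_cols <- setdiff(req, names(patients))
  assert_that(length(missing_cols) == 0,
              paste0("patients: missing column(s) ",
                     paste(missing_cols, collapse = ", ")))
  assert_that(!anyDuplicated(patients$patient_id),
              "patients: duplicated patient_id")
  assert_that(all(patients$sex %in% c("male", "female")),
              "patients: sex must be 'male' or 'female'")
  bad <- patients$patient_id[patients$discharge_date < patients$admission_date]
  assert_that(length(bad) == 0,
              paste0("patients: discharge before admission for ",
                     paste(bad, collapse = ", ")))
  bad <- patients$patient_id[patients$age_at_admission <= 28 / 365]
  assert_that(length(bad) == 0,
              paste0("patients: age at admission must exceed 28 days for ",
                     paste(bad, collapse = ", ")))
  assert_that(all(patients$n_comorbidities >= 0),
              "patients: n_comorbidities must be non-negative")
  assert_that(all(patients$n_prior_hospitalizations >= 1),
              "patients: n_prior_hospitalizations counts the current admission (>= 1)")
  n_target <- lengths(strsplit(patients$target_drug_classes, ";", fixed = TRUE))
  assert_that(all(n_target >= 1),
              "patients: at least one target drug class is required")
  patients <- patients[c(req, setdiff(names(patients), req))]

  check_ref <- function(stream, name) {
    orphan <- setdiff(unique(stream$patient_id), patients$patient_id)
    assert_that(length(orphan) == 0,
                paste0(name, ": rows for unknown patient_id ",
                       paste(orphan, collapse = ", ")))
  }
  check_ref(labs, "labs"); check_ref(medications, "medications")
  check_ref(events, "events"); check_ref(interventions, "interventions")

  if (nrow(labs)) {
    bad <- setdiff(unique(labs$analyte), names(ANALYTES))
    assert_that(length(bad) == 0,
                paste0("labs: unknown analyte(s) ", paste(bad, collapse = ", ")))
    assert_that(all(labs$value >= 0), "labs: values must be non-negative")
    if ("unit" %in% names(labs)) {
      exp_unit <- unname(ANALYTES[labs$analyte])
      bad <- which(!is.na(labs$unit) & labs$unit != exp_unit)
      assert_that(length(bad) == 0,
                  paste0("labs: unit disagrees with the fixed analyte unit at row(s) ",
                         paste(head(bad, 5), collapse = ", "),
                         " (units are fixed per analyte; convert upstream)"))
      labs$unit <- NULL
    }
    win <- dplyr::left_join(
      labs, dplyr::select(patients, "patient_id", "admission_date", "discharge_date"),
      by = "patient_id")
    inside <- as.Date(win$timestamp, tz = "UTC") >= win$admission_date &
      as.Date(win$timestamp, tz = "UTC") <= win$discharge_date
    assert_that(all(inside),
                "labs: timestamps must fall within the admission-discharge window")
  }
  labs$lab_id <- seq_len(nrow(labs))

  if (nrow(medications)) {
    assert_that(all(medications$start <= medications$stop),
                "medications: start must not exceed stop")
    medications$drug_class <- resolve_drug_class(medications$drug_name, dictionary)
  } else {
    medications$drug_class <- character()
  }
  medications$med_id <- seq_len(nrow(medications))

  if (nrow(events)) {
    code <- normalize_symptom(events$term, vocabulary)
    bad <- unique(events$term[is.na(code)])
    assert_that(length(bad) == 0,
                paste0("events: term(s) not in the symptom vocabulary: ",
                       paste(bad, collapse = ", ")))
    events$code <- code
  } else {
    events$code <- character()
  }
  events$event_id <- seq_len(nrow(events))

  if (nrow(interventions)) {
    assert_that(all(interventions$kind %in% c("icu_transfer", "salvage")),
                "interventions: kind must be 'icu_transfer' or 'salvage'")
  }
  interventions$intervention_id <- seq_len(nrow(interventions))

  structure(
    list(patients = patients, labs = labs, medications = medications,
         events = events, interventions = interventions),
    class = "ade_cohort")
}

#' @export
print.ade_cohort <- function(x, ...) {
  cat("<ade_cohort> ", nrow(x$patients), " admissions | ",
      nrow(x$labs), " labs, ", nrow(x$medications), " medications, ",
      nrow(x$events), " events, ", nrow(x$interventions), " interventions\n",
      sep = "")
  invisible(x)
}

#' Length of stay per admission
#'
#' Calendar days between admission and discharge with a floor of one day:
#' stays of at least 24 h recorded on a single calendar date count as one
#' patient-day.
#'
#' @param cohort An [ade_cohort()].
#' @return Tibble with `patient_id` and integer `los_days`.
#' @export
length_of_stay <- function(cohort) {
  stopifnot(inherits(cohort, "ade_cohort"))
  dplyr::transmute(
    cohort$patients,
    patient_id = .data$patient_id,
    los_days = pmax(1L, as.integer(.data$discharge_date - .data$admission_date)))
}

cohort_files <- c(patients = "patients.csv", labs = "labs.csv",
                  medications = "medications.csv", events = "events.csv",
                  interventions = "interventions.csv")

#' Read a cohort from CSV files
#'
#' Expects the five-file layout written by [write_cohort()]: `patients.csv`
#' plus optional `labs.csv`, `medications.csv`, `events.csv`,
#' `interventions.csv` in one directory. Missing stream files are treated as
#' empty streams. All validation of [ade_cohort()] applies; schema violations
#' name the offending file and field.
#'
#' @param dir Directory containing the cohort files.
#' @inheritParams ade_cohort
#' @return A validated [ade_cohort()].
#' @export
read_cohort <- function(dir, dictionary = load_drug_dictionary(),
                        vocabulary = load_symptom_vocabulary()) {
  assert_that(dir.exists(dir), paste0("cohort directory not found: ", dir))
  p <- file.path(dir, cohort_files["patients"])
  assert_that(file.exists(p), paste0("missing required file: ", p))
  patients <- readr::read_csv(
    p,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      age_at_admission = readr::col_double(),
      sex = readr::col_character(),
      admission_date = readr::col_date(),
      discharge_date = readr::col_date(),
      n_comorbidities = readr::col_integer(),
      n_prior_hospitalizations = readr::col_integer(),
      target_drug_classes = readr::col_character()))

  read_stream <- function(key, empty, types) {
    f <- file.path(dir, cohort_files[key])
    if (!file.exists(f)) return(empty)
    readr::read_csv(f, col_types = types)
  }
  dt <- function() readr::col_datetime(format = "")
  labs <- read_stream("labs", empty_labs(), readr::cols(
    patient_id = readr::col_character(), analyte = readr::col_character(),
    value = readr::col_double(), timestamp = dt(),
    .default = readr::col_character()))
  labs$lab_id <- NULL
  medications <- read_stream("medications", empty_medications(), readr::cols(
    patient_id = readr::col_character(), drug_name = readr::col_character(),
    start = dt(), stop = dt(),
    is_target_pah_drug = readr::col_logical(),
    stopped_abruptly = readr::col_logical(),
    .default = readr::col_character()))
  medications$med_id <- NULL; medications$drug_class <- NULL
  events <- read_stream("events", empty_events(), readr::cols(
    patient_id = readr::col_character(), term = readr::col_character(),
    timestamp = dt(), .default = readr::col_character()))
  events$event_id <- NULL; events$code <- NULL
  interventions <- read_stream("interventions", empty_interventions(), readr::cols(
    patient_id = readr::col_character(), kind = readr::col_character(),
    timestamp = dt()))
  interventions$intervention_id <- NULL

  ade_cohort(patients, labs, medications, events, interventions,
             dictionary = dictionary, vocabulary = vocabulary)
}

#' Write a cohort to CSV files
#'
#' Lossless inverse of [read_cohort()]: writes the five stream files with a
#' stable column order. Derived columns (row ids, resolved drug class, event
#' codes) are recomputed on read and not written.
#'
#' @param cohort An [ade_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ade_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$patients[names(empty_patients())],
                   file.path(dir, cohort_files["patients"]))
  readr::write_csv(cohort$labs[names(empty_labs())],
                   file.path(dir, cohort_files["labs"]))
  readr::write_csv(cohort$medications[names(empty_medications())],
                   file.path(dir, cohort_files["medications"]))
  readr::write_csv(cohort$events[names(empty_events())],
                   file.path(dir, cohort_files["events"]))
  readr::write_csv(cohort$interventions[names(empty_interventions())],
                   file.path(dir, cohort_files["interventions"]))
  invisible(dir)
}
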