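#' Published validation counts for the default trigger set
#'
#' The count tables from the published single-center validation of the
#' 24-trigger PAH surveillance set (626 admissions, January 2022 - June
#' 2023), packaged for exact-arithmetic reporting and as a reference fixture:
#' per-trigger positive instances and adjudicated ADEs, the patient-level
#' confusion matrix, cohort denominators (patient-days, admissions, total
#' medication types), severity / causality / organ-system tallies, the
#' univariate risk-factor contingency rows, and the paired trigger-versus-
#' spontaneous-reporting detection table.
#'
#' @return An object of class `ade_counts` (a named list of tibbles and
#'   scalars) accepted by [build_report()].
#' @examples
#' rep <- build_report(counts = published_counts())
#' rep$summary
#' @export
published_counts <- function() {
  per_trigger <- tibble::tribble(
    ~trigger_id, ~positives, ~true_ades, ~printed_utility,
    "L1",  6L,  4L, "high",
    "L2",  7L,  3L, "moderate",
    "L3",  5L,  3L, "high",
    "L4", 18L,  7L, "moderate",
    "L5", 21L,  8L, "moderate",
    "L6", 88L, 35L, "moderate",
    "L7",  5L,  3L, "high",
    "A1", 27L,  5L, "low",
    "A2", 28L, 12L, "moderate",
    "A3", 40L, 14L, "moderate",
    "A4", 22L,  6L, "moderate",
    "A5", 21L,  7L, "moderate",
    "A6", 42L, 10L, "moderate",
    "S1", 14L,  1L, "low",
    "S2", 13L,  5L, "moderate",
    "S3",  6L,  2L, NA,
    "S4",  6L,  4L, "high",
    "S5", 51L,  5L, "low",
    "S6",  9L,  5L, NA,
    "S7",  1L,  1L, "high",
    "S8",  2L,  0L, "low",
    "T1",  3L,  0L, "low",
    "T2",  6L,  1L, "low",
    "T3", 31L,  2L, "low")

  severity <- tibble::tibble(severity = c("D", "E", "F", "H"),
                             n = c(24L, 102L, 15L, 2L))
  causality <- tibble::tibble(
    causality = c("probably_related", "very_probably_related",
                  "definitely_related"),
    n = c(119L, 19L, 5L))
  organ_systems <- tibble::tibble(
    organ_system = c("blood_bleeding_clotting", "gastrointestinal",
                     "liver_kidney", "systemic", "metabolic_nutritional",
                     "other", "central_peripheral_nervous", "skin_adnexal",
                     "musculoskeletal"),
    n = c(46L, 38L, 21L, 10L, 8L, 8L, 6L, 4L, 2L))

  # Univariate risk-factor contingency rows: admissions without / with an ADE.
  univariate <- tibble::tribble(
    ~covariate, ~level, ~without_ade, ~with_ade,
    "age", "0-17", 19L, 7L,
    "age", "18-40", 153L, 33L,
    "age", "41-60", 172L, 39L,
    "age", ">60", 170L, 33L,
    "sex", "male", 201L, 44L,
    "sex", "female", 313L, 68L,
    "los_days", "1-10", 431L, 60L,
    "los_days", "11-20", 61L, 32L,
    "los_days", "21-30", 12L, 11L,
    "los_days", ">30", 10L, 9L,
    "prior_hospitalizations", "1-3", 328L, 75L,
    "prior_hospitalizations", "4-6", 114L, 23L,
    "prior_hospitalizations", ">6", 72L, 14L,
    "target_drug_classes", "1", 208L, 34L,
    "target_drug_classes", "2", 189L, 49L,
    "target_drug_classes", "3", 85L, 19L,
    "target_drug_classes", ">3", 32L, 10L,
    "comorbidities", "1-3", 175L, 23L,
    "comorbidities", "4-6", 181L, 38L,
    "comorbidities", "7-9", 104L, 24L,
    "comorbidities", ">9", 54L, 27L,
    "positive_triggers", "0-1", 455L, 39L,
    "positive_triggers", "2-4", 52L, 58L,
    "positive_triggers", ">=5", 7L, 15L)

  # Paired per-patient detection flags: trigger screen vs spontaneous
  # reporting over the same admissions.
  paired_detection <- matrix(
    c(2L, 108L, 0L, 516L), nrow = 2, byrow = TRUE,
    dimnames = list(trigger = c("ade", "no_ade"),
                    spontaneous = c("ade", "no_ade")))

  structure(
    list(per_trigger = per_trigger,
         confusion = confusion_matrix(tp = 110, fp = 141, fn = 2, tn = 373),
         n_ades = 143L, n_ade_patients = 110L, n_patients = 626L,
         patient_days = 5554L, n_medication_types = 1208L,
         severity = severity, causality = causality,
         organ_systems = organ_systems,
         univariate = univariate,
         paired_detection = paired_detection),
    class = "ade_counts")
}
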