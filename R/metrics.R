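#' Positive predictive value of a trigger
#'
#' PPV = number of true positives / number of positives x 100%. A trigger
#' with zero positives has an undefined PPV, reported as `NA` (never silently
#' zero).
#'
#' @param positives Count of positive trigger instances.
#' @param true_ades Count of instances adjudicated as true ADEs.
#' @return PPV in percent, rounded half-up to 2 dp; `NA` when undefined.
#' @examples
#' ppv(472, 143)  # 30.30
#' ppv(6, 4)      # 66.67
#' @export
ppv <- function(positives, true_ades) {
  assert_that(all(true_ades >= 0) && all(positives >= 0),
              "counts must be non-negative")
  assert_that(all(true_ades <= positives),
              "true_ades cannot exceed positives")
  out <- ifelse(positives == 0, NA_real_,
                round_half_up(100 * true_ades / positives))
  unname(out)
}

#' Patient-level confusion matrix
#'
#' Cross-classification of trigger-positive status against adjudicated ADE
#' status at the patient level.
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts (trigger-positive with
#'   ADE, trigger-positive without ADE, trigger-negative with ADE,
#'   trigger-negative without ADE).
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  assert_that(all(counts >= 0) && all(counts == round(counts)),
              "confusion matrix cells must be non-negative integers")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, byrow = TRUE,
              dimnames = list(trigger = c("positive", "negative"),
                              ade = c("ade", "no_ade")))
  print(m)
  invisible(x)
}

#' Detection metrics from a confusion matrix
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP) (both in percent),
#' Youden index J = sensitivity + specificity - 1 (fractional, rounded to
#' 2 dp), and the false-negative rate FN/(FN+TN) — the share of
#' trigger-negative patients who nonetheless had an ADE. Margins of zero
#' yield `NA` markers.
#'
#' @param cm A [confusion_matrix()].
#' @return Tibble with `sensitivity`, `specificity`, `youden`,
#'   `false_negative_rate`.
#' @examples
#' confusion_metrics(confusion_matrix(110, 141, 2, 373))
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  sens <- if (cm$tp + cm$fn == 0) NA_real_ else
    round_half_up(100 * cm$tp / (cm$tp + cm$fn))
  spec <- if (cm$tn + cm$fp == 0) NA_real_ else
    round_half_up(100 * cm$tn / (cm$tn + cm$fp))
  fnr <- if (cm$fn + cm$tn == 0) NA_real_ else
    round_half_up(100 * cm$fn / (cm$fn + cm$tn))
  youden <- if (is.na(sens) || is.na(spec)) NA_real_ else
    round_half_up(sens / 100 + spec / 100 - 1)
  tibble::tibble(sensitivity = sens, specificity = spec,
                 youden = youden, false_negative_rate = fnr)
}

#' ADE occurrence rates and detection prevalence
#'
#' The four incidence formulas: ADEs per 1,000 patient-days
#' (`n_ades / patient_days x 1000`), ADEs per 100 patients
#' (`n_ades / n_patients x 100`), the "per 1,000 drugs" rate, and detection
#' prevalence (`n_ade_patients / n_patients x 100%`). Note the per-1,000-drug
#' rate is defined with a x100 multiplier over the total count of medication
#' types across cases — the formula as conventionally printed, kept verbatim;
#' see the methods vignette for the naming inconsistency.
#'
#' @param n_ades Total number of ADE occurrences.
#' @param patient_days Sum of lengths of stay over the cohort.
#' @param n_patients Number of admissions.
#' @param n_medication_types Total number of (target) medication types across
#'   cases.
#' @param n_ade_patients Number of patients with at least one ADE.
#' @return Tibble with `rate_per_1000_patient_days`, `rate_per_100_patients`,
#'   `rate_per_1000_drugs`, `prevalence` (percent).
#' @examples
#' ade_rates(143, 5554, 626, 1208, 110)
#' @export
ade_rates <- function(n_ades, patient_days, n_patients, n_medication_types,
                      n_ade_patients) {
  assert_that(patient_days > 0 && n_patients > 0 && n_medication_types > 0,
              "rate denominators must be positive")
  tibble::tibble(
    rate_per_1000_patient_days = round_half_up(n_ades / patient_days * 1000),
    rate_per_100_patients = round_half_up(n_ades / n_patients * 100),
    rate_per_1000_drugs = round_half_up(n_ades / n_medication_types * 100),
    prevalence = round_half_up(100 * n_ade_patients / n_patients))
}

#' Classify trigger utility from its PPV
#'
#' Cut points are configurable; the defaults label a trigger high utility at
#' PPV >= 50%, moderate in [20, 50) and low below 20%.
#'
#' @param ppv PPV in percent (may be `NA`).
#' @param high,moderate Lower cut points in percent.
#' @return Character vector in `{"high", "moderate", "low"}` (`NA` for
#'   undefined PPV).
#' @export
classify_utility <- function(ppv, high = 50, moderate = 20) {
  dplyr::case_when(
    is.na(ppv) ~ NA_character_,
    ppv >= high ~ "high",
    ppv >= moderate ~ "moderate",
    TRUE ~ "low")
}

#' Assemble the full detection-performance report
#'
#' Combines a trigger screening, the adjudicated ADEs and the cohort into a
#' single report: per-trigger positives, true ADEs, PPV and utility class;
#' the overall PPV (total ADEs over total positive instances — the weighted
#' ratio, not a mean of per-trigger PPVs); the patient-level confusion matrix
#' with sensitivity, specificity, Youden index and false-negative rate; and
#' the ADE rates and detection prevalence.
#'
#' Alternatively pass a pre-tabulated counts bundle (see [published_counts()])
#' via `counts` for exact-arithmetic reporting from published count tables.
#'
#' @param screening An `ade_screening` from [screen_cohort()].
#' @param ades An [ade_records()] tibble; `supporting_trigger_id` links each
#'   ADE to the trigger that found it (`NA` = found outside the screen).
#' @param cohort The [ade_cohort()] that was screened.
#' @param counts Optional counts bundle of class `ade_counts`; when supplied
#'   the other arguments are ignored.
#' @return An object of class `ade_metrics`: list with `per_trigger` (tibble),
#'   `overall_ppv`, `confusion` ([confusion_matrix()]), `summary` (one-row
#'   tibble of the headline metrics), `severity`, `causality`,
#'   `organ_systems` summaries (when ADE detail is available).
#' @export
build_report <- function(screening = NULL, ades = NULL, cohort = NULL,
                         counts = NULL) {
  if (!is.null(counts)) {
    stopifnot(inherits(counts, "ade_counts"))
    return(report_from_counts(counts))
  }
  stopifnot(inherits(screening, "ade_screening"),
            inherits(cohort, "ade_cohort"))
  ades <- ades %||% ade_records(character(), character(), character(), character())
  bad <- setdiff(ades$patient_id, cohort$patients$patient_id)
  assert_that(length(bad) == 0,
              paste0("ADE records reference unknown patient(s): ",
                     paste(bad, collapse = ", ")))

  ades$supporting_trigger_id <- as.character(ades$supporting_trigger_id)
  per_trigger <- screening$hits |>
    dplyr::count(.data$trigger_id, name = "positives") |>
    dplyr::left_join(
      ades |>
        dplyr::filter(!is.na(.data$supporting_trigger_id)) |>
        dplyr::count(trigger_id = .data$supporting_trigger_id, name = "true_ades"),
      by = "trigger_id") |>
    dplyr::mutate(true_ades = dplyr::coalesce(.data$true_ades, 0L),
                  ppv = ppv(.data$positives, .data$true_ades),
                  utility = classify_utility(.data$ppv))

  ade_patients <- unique(ades$patient_id)
  flagged <- screening$patients$flagged
  has_ade <- screening$patients$patient_id %in% ade_patients
  cm <- confusion_matrix(tp = sum(flagged & has_ade), fp = sum(flagged & !has_ade),
                         fn = sum(!flagged & has_ade), tn = sum(!flagged & !has_ade))

  n_med_types <- sum(lengths(strsplit(cohort$patients$target_drug_classes,
                                      ";", fixed = TRUE)))
  rates <- ade_rates(n_ades = nrow(ades),
                     patient_days = sum(length_of_stay(cohort)$los_days),
                     n_patients = nrow(cohort$patients),
                     n_medication_types = n_med_types,
                     n_ade_patients = length(ade_patients))
  overall <- ppv(sum(per_trigger$positives), sum(per_trigger$true_ades))

  structure(
    list(per_trigger = per_trigger,
         overall_ppv = overall,
         confusion = cm,
         summary = dplyr::bind_cols(
           tibble::tibble(overall_ppv = overall), confusion_metrics(cm), rates),
         severity = summarize_severity(ades),
         causality = summarize_causality(ades),
         organ_systems = summarize_organ_systems(ades)),
    class = "ade_metrics")
}

report_from_counts <- function(counts) {
  per_trigger <- counts$per_trigger |>
    dplyr::mutate(ppv = ppv(.data$positives, .data$true_ades),
                  utility = classify_utility(.data$ppv))
  cm <- counts$confusion
  rates <- ade_rates(counts$n_ades, counts$patient_days, counts$n_patients,
                     counts$n_medication_types, counts$n_ade_patients)
  overall <- ppv(sum(per_trigger$positives), sum(per_trigger$true_ades))
  mk_summary <- function(df) {
    if (is.null(df)) return(NULL)
    df |> dplyr::mutate(pct = as_pct(.data$n, sum(.data$n)))
  }
  structure(
    list(per_trigger = per_trigger,
         overall_ppv = overall,
         confusion = cm,
         summary = dplyr::bind_cols(
           tibble::tibble(overall_ppv = overall), confusion_metrics(cm), rates),
         severity = mk_summary(counts$severity),
         causality = mk_summary(counts$causality),
         organ_systems = {
           os <- mk_summary(counts$organ_systems)
           if (!is.null(os)) dplyr::arrange(os, dplyr::desc(.data$n)) else NULL
         }),
    class = "ade_metrics")
}

#' @export
print.ade_metrics <- function(x, ...) {
  cat("<ade_metrics>\n")
  print(x$summary)
  invisible(x)
}

#' @rdname build_report
#' @param x An `ade_metrics` report.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ade_metrics <- function(x, ...) x$per_trigger

#' @rdname build_report
#' @exportS3Method generics::glance
glance.ade_metrics <- function(x, ...) x$summary
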