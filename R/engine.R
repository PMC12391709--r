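no_hits <- function() {
  tibble::tibble(patient_id = character(),
                 first_satisfied_at = as.POSIXct(character(), tz = "UTC"),
                 evidence = character())
}

# Evaluate one condition node against the whole cohort.
# Returns at most one row per patient: the earliest time the condition was
# satisfied plus references to the satisfying rows.
eval_condition <- function(cond, cohort) {
  switch(
    cond$type,
    threshold = eval_threshold(cond, cohort),
    any = {
      kids <- dplyr::bind_rows(purrr::map(cond$of, eval_condition,
                                          cohort = cohort))
      if (nrow(kids) == 0) return(no_hits())
      kids |>
        dplyr::group_by(.data$patient_id) |>
        dplyr::summarise(
          first_satisfied_at = min(.data$first_satisfied_at),
          evidence = paste(unique(.data$evidence), collapse = ";"),
          .groups = "drop")
    },
    all = {
      kids <- purrr::map(cond$of, eval_condition, cohort = cohort)
      common <- Reduce(intersect, purrr::map(kids, "patient_id"))
      if (length(common) == 0) return(no_hits())
      dplyr::bind_rows(kids) |>
        dplyr::filter(.data$patient_id %in% common) |>
        dplyr::group_by(.data$patient_id) |>
        dplyr::summarise(
          # a conjunction is satisfied once its last component appears
          first_satisfied_at = max(.data$first_satisfied_at),
          evidence = paste(unique(.data$evidence), collapse = ";"),
          .groups = "drop")
    },
    baseline_ratio = eval_baseline_ratio(cond, cohort),
    drug_class = {
      hit <- dplyr::filter(cohort$medications,
                           !.data$is_target_pah_drug,
                           .data$drug_class == cond$class)
      summarise_hits(hit, time_col = "start", id_col = "med_id", prefix = "medications")
    },
    symptom_set = {
      hit <- dplyr::filter(cohort$events, .data$code %in% cond$terms)
      summarise_hits(hit, time_col = "timestamp", id_col = "event_id", prefix = "events")
    },
    intervention = {
      hit <- dplyr::filter(cohort$interventions, .data$kind == cond$kind)
      summarise_hits(hit, time_col = "timestamp", id_col = "intervention_id",
                     prefix = "interventions")
    },
    abrupt_cessation = {
      hit <- dplyr::filter(cohort$medications,
                           .data$is_target_pah_drug, .data$stopped_abruptly)
      summarise_hits(hit, time_col = "stop", id_col = "med_id", prefix = "medications")
    },
    abort(paste0("unknown condition type: ", cond$type)))
}

summarise_hits <- function(rows, time_col, id_col, prefix) {
  if (nrow(rows) == 0) return(no_hits())
  rows |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      first_satisfied_at = min(.data[[time_col]]),
      evidence = paste0(prefix, ":",
                        paste(sort(.data[[id_col]]), collapse = ",")),
      .groups = "drop")
}

eval_threshold <- function(cond, cohort) {
  obs <- dplyr::filter(cohort$labs, .data$analyte == cond$analyte)
  if (nrow(obs) == 0) return(no_hits())
  if (is.null(cond$strata)) {
    obs$bound_ <- cond$bound
  } else {
    strata <- purrr::map_dfr(cond$strata, ~ tibble::tibble(
      age_min = .x$age_min, age_max = .x$age_max,
      sex_ = .x$sex, bound_ = .x$bound))
    obs <- obs |>
      dplyr::left_join(dplyr::select(cohort$patients, "patient_id",
                                     "age_at_admission", "sex"),
                       by = "patient_id") |>
      dplyr::cross_join(strata) |>
      dplyr::filter(.data$age_at_admission >= .data$age_min,
                    .data$age_at_admission < .data$age_max,
                    is.na(.data$sex_) | .data$sex_ == .data$sex)
    if (nrow(obs) == 0) return(no_hits())
  }
  sat <- if (cond$comparator == ">") obs$value > obs$bound_ else obs$value < obs$bound_
  summarise_hits(obs[sat, , drop = FALSE], "timestamp", "lab_id", "labs")
}

eval_baseline_ratio <- function(cond, cohort) {
  obs <- cohort$labs |>
    dplyr::filter(.data$analyte %in% cond$analytes) |>
    dplyr::arrange(.data$timestamp, .data$lab_id) |>
    dplyr::group_by(.data$patient_id, .data$analyte) |>
    dplyr::mutate(baseline_ = dplyr::first(.data$value),
                  is_baseline_ = dplyr::row_number() == 1) |>
    dplyr::ungroup() |>
    dplyr::filter(!.data$is_baseline_, .data$baseline_ > 0,
                  .data$value > cond$ratio * .data$baseline_)
  summarise_hits(obs, "timestamp", "lab_id", "labs")
}

#' Evaluate a single trigger rule against a cohort
#'
#' `evaluate_trigger()` runs one rule of any shape; `evaluate_lab_trigger()`,
#' `evaluate_exposure_trigger()` and `evaluate_event_trigger()` are
#' category-checked aliases for laboratory, antidote-exposure and
#' symptom/treatment rules respectively. Missing analytes or empty streams
#' simply produce no hit.
#'
#' @param rule A `trigger_rule` from [load_ruleset()].
#' @param cohort An [ade_cohort()].
#' @return A tibble of trigger hits with at most one row per patient:
#'   `patient_id`, `trigger_id`, `first_satisfied_at`, `evidence` (references
#'   to the satisfying stream rows, e.g. `"labs:3,7"`).
#' @export
evaluate_trigger <- function(rule, cohort) {
  stopifnot(inherits(rule, "trigger_rule"), inherits(cohort, "ade_cohort"))
  hits <- eval_condition(rule$condition, cohort)
  if (nrow(hits) == 0) {
    return(tibble::tibble(patient_id = character(), trigger_id = character(),
                          first_satisfied_at = as.POSIXct(character(), tz = "UTC"),
                          evidence = character()))
  }
  hits |>
    dplyr::mutate(trigger_id = rule$id, .after = "patient_id") |>
    dplyr::arrange(.data$patient_id)
}

#' @rdname evaluate_trigger
#' @export
evaluate_lab_trigger <- function(rule, cohort) {
  assert_that(rule$category == "laboratory", "rule is not a laboratory trigger")
  evaluate_trigger(rule, cohort)
}

#' @rdname evaluate_trigger
#' @export
evaluate_exposure_trigger <- function(rule, cohort) {
  assert_that(rule$category == "antidote", "rule is not an antidote-exposure trigger")
  evaluate_trigger(rule, cohort)
}

#' @rdname evaluate_trigger
#' @export
evaluate_event_trigger <- function(rule, cohort) {
  assert_that(rule$category %in% c("symptom", "treatment"),
              "rule is not a symptom/treatment trigger")
  evaluate_trigger(rule, cohort)
}

#' Screen a cohort against a trigger rule set
#'
#' Evaluates every rule against every admission. Hits are deduplicated to one
#' per (patient, trigger) pair per admission — the counting unit under which
#' per-trigger positive counts and positive predictive values are defined —
#' and the result is independent of input row order.
#'
#' @param cohort An [ade_cohort()].
#' @param ruleset A [load_ruleset()] rule set.
#' @return An object of class `ade_screening`: list with `hits` (tibble
#'   `patient_id`, `trigger_id`, `first_satisfied_at`, `evidence`) and
#'   `patients` (tibble `patient_id`, `n_triggers`, `flagged`), where
#'   `flagged` is true iff the admission has at least one hit.
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 50), seed = 1)
#' scr <- screen_cohort(sim$cohort, load_ruleset())
#' head(scr$hits)
#' @export
screen_cohort <- function(cohort, ruleset = load_ruleset()) {
  stopifnot(inherits(cohort, "ade_cohort"), inherits(ruleset, "trigger_ruleset"))
  hits <- purrr::map_dfr(ruleset, evaluate_trigger, cohort = cohort) |>
    dplyr::arrange(.data$patient_id, .data$trigger_id)
  patients <- cohort$patients |>
    dplyr::select("patient_id") |>
    dplyr::left_join(dplyr::count(hits, .data$patient_id, name = "n_triggers"),
                     by = "patient_id") |>
    dplyr::mutate(n_triggers = dplyr::coalesce(.data$n_triggers, 0L),
                  flagged = .data$n_triggers > 0)
  structure(list(hits = hits, patients = patients), class = "ade_screening")
}

#' @export
print.ade_screening <- function(x, ...) {
  cat("<ade_screening> ", nrow(x$hits), " hits across ",
      sum(x$patients$flagged), "/", nrow(x$patients),
      " flagged admissions\n", sep = "")
  invisible(x)
}
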