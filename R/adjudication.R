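#' Controlled vocabularies for adjudication
#'
#' `CAUSALITY_LEVELS` are the six WHO-UMC drug-event causality levels,
#' `SEVERITY_GRADES` the NCC MERP A-I harm ladder, and `ORGAN_SYSTEMS` the
#' nine-group organ/system taxonomy used to classify adjudicated ADEs.
#' Grades E-I constitute the "harm" subset; grade D events (monitoring
#' required, no harm) are recorded and reported but excluded from
#' harm-restricted analyses.
#'
#' @name adjudication-vocab
#' @export
CAUSALITY_LEVELS <- c("definitely_related", "very_probably_related",
                      "probably_related", "probably_not_related",
                      "to_be_evaluated", "not_evaluable")

#' @rdname adjudication-vocab
#' @export
SEVERITY_GRADES <- LETTERS[1:9]

#' @rdname adjudication-vocab
#' @export
HARM_GRADES <- LETTERS[5:9]

#' @rdname adjudication-vocab
#' @export
ORGAN_SYSTEMS <- c(
  "blood_bleeding_clotting", "gastrointestinal", "liver_kidney",
  "systemic", "metabolic_nutritional", "other",
  "central_peripheral_nervous", "skin_adnexal", "musculoskeletal")

#' Construct a table of adjudicated adverse drug events
#'
#' One row per adjudicated ADE. `supporting_trigger_id` is the trigger whose
#' firing led reviewers to the event, or `NA` for ADEs discovered outside the
#' trigger screen (the false-negative route).
#'
#' @param patient_id,description,implicated_drug Character vectors.
#' @param organ_system One of [ORGAN_SYSTEMS].
#' @param causality One of [CAUSALITY_LEVELS].
#' @param severity One of [SEVERITY_GRADES].
#' @param supporting_trigger_id Trigger id or `NA`.
#' @return A tibble of class `ade_records`.
#' @export
ade_records <- function(patient_id, organ_system, causality, severity,
                        supporting_trigger_id = NA_character_,
                        implicated_drug = NA_character_,
                        description = NA_character_) {
  assert_that(all(organ_system %in% ORGAN_SYSTEMS),
              "organ_system must be one of the nine-group taxonomy")
  assert_that(all(causality %in% CAUSALITY_LEVELS),
              "causality must be a WHO-UMC level")
  assert_that(all(severity %in% SEVERITY_GRADES),
              "severity must be an NCC MERP grade A-I")
  out <- tibble::tibble(patient_id = as.character(patient_id),
                        organ_system = organ_system, causality = causality,
                        severity = severity,
                        supporting_trigger_id = supporting_trigger_id,
                        implicated_drug = implicated_drug,
                        description = description)
  class(out) <- c("ade_records", class(out))
  out
}

#' Reconcile dual-reviewer verdicts
#'
#' Two junior reviewers independently judge whether a flagged case is a true
#' ADE. Agreement stands as the final verdict; disagreement must be settled
#' by the senior panel, whose verdict becomes final. Calling with discordant
#' junior verdicts and no senior verdict is an error (escalation required).
#'
#' @param junior_1,junior_2 Logical verdicts of the two junior reviewers.
#' @param senior_panel Optional logical verdict of the senior panel.
#' @return Logical final verdict (vectorized).
#' @examples
#' reconcile(TRUE, TRUE)            # agreement
#' reconcile(TRUE, FALSE, FALSE)    # escalated to the senior panel
#' @export
reconcile <- function(junior_1, junior_2, senior_panel = NA) {
  n <- max(length(junior_1), length(junior_2))
  junior_1 <- rep_len(as.logical(junior_1), n)
  junior_2 <- rep_len(as.logical(junior_2), n)
  senior_panel <- rep_len(as.logical(senior_panel), n)
  disagree <- junior_1 != junior_2
  if (any(disagree & is.na(senior_panel))) {
    abort("junior reviewers disagree: a senior panel verdict is required")
  }
  ifelse(disagree, senior_panel, junior_1)
}

summarize_by <- function(ades, col, levels = NULL) {
  stopifnot(inherits(ades, "ade_records") || is.data.frame(ades))
  if (nrow(ades) == 0) {
    return(tibble::tibble(!!col := character(), n = integer(), pct = double()))
  }
  out <- ades |>
    dplyr::count(.data[[col]]) |>
    dplyr::mutate(pct = as_pct(.data$n, sum(.data$n)))
  if (!is.null(levels)) {
    out <- out[order(match(out[[col]], levels)), ]
  }
  tibble::as_tibble(out)
}

#' Summarize adjudicated ADEs
#'
#' Counts and percentages (rounded half-up to 2 dp) of adjudicated ADEs by
#' NCC MERP severity grade, WHO-UMC causality level, or organ-system group.
#' Counts always sum to the number of ADEs; the organ-system summary is
#' ordered by descending count.
#'
#' @param ades An [ade_records()] tibble.
#' @return A tibble of `n` and `pct` per level present in the data.
#' @export
summarize_severity <- function(ades) summarize_by(ades, "severity", SEVERITY_GRADES)

#' @rdname summarize_severity
#' @export
summarize_causality <- function(ades) summarize_by(ades, "causality", CAUSALITY_LEVELS)

#' @rdname summarize_severity
#' @export
summarize_organ_systems <- function(ades) {
  out <- summarize_by(ades, "organ_system")
  dplyr::arrange(out, dplyr::desc(.data$n))
}
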