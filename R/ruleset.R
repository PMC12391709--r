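CONDITION_TYPES <- c("threshold", "any", "all", "baseline_ratio", "drug_class",
                     "symptom_set", "intervention", "abrupt_cessation")
RULE_CATEGORIES <- c("laboratory", "antidote", "symptom", "treatment")

# Recursively validate one condition node and resolve uln_multiple bounds.
prepare_condition <- function(cond, uln, id) {
  assert_that(is.list(cond) && !is.null(cond$type),
              paste0(id, ": condition must have a 'type'"))
  assert_that(cond$type %in% CONDITION_TYPES,
              paste0(id, ": unknown condition shape '", cond$type, "'"))
  switch(
    cond$type,
    threshold = {
      assert_that(cond$analyte %in% names(ANALYTES),
                  paste0(id, ": unknown analyte '", cond$analyte, "'"))
      assert_that(cond$comparator %in% c("<", ">"),
                  paste0(id, ": comparator must be '<' or '>'"))
      if (!is.null(cond$uln_multiple)) {
        assert_that(!is.null(uln[[cond$analyte]]),
                    paste0(id, ": uln_multiple used but no ULN configured for '",
                           cond$analyte, "'"))
        cond$bound <- cond$uln_multiple * uln[[cond$analyte]]
      }
      if (!is.null(cond$strata)) {
        cond$strata <- purrr::map(cond$strata, function(s) {
          s$age_max <- s$age_max %||% Inf
          s$sex <- s$sex %||% NA_character_
          s
        })
        validate_strata(cond$strata, id)
      } else {
        assert_that(is.numeric(cond$bound),
                    paste0(id, ": threshold needs a numeric bound"))
      }
      cond
    },
    any = ,
    all = {
      assert_that(is.list(cond$of) && length(cond$of) >= 2,
                  paste0(id, ": composite condition needs >= 2 children"))
      cond$of <- purrr::map(cond$of, prepare_condition, uln = uln, id = id)
      cond
    },
    baseline_ratio = {
      assert_that(length(cond$analytes) >= 1 &&
                    all(unlist(cond$analytes) %in% names(ANALYTES)),
                  paste0(id, ": baseline_ratio needs known analytes"))
      assert_that(is.numeric(cond$ratio) && cond$ratio > 0,
                  paste0(id, ": baseline_ratio needs a positive ratio"))
      cond$analytes <- unlist(cond$analytes)
      cond
    },
    drug_class = {
      assert_that(is.character(cond$class) && nzchar(cond$class),
                  paste0(id, ": drug_class condition needs a class"))
      cond
    },
    symptom_set = {
      assert_that(length(cond$terms) >= 1,
                  paste0(id, ": symptom_set needs at least one term"))
      cond$terms <- unlist(cond$terms)
      cond
    },
    intervention = {
      assert_that(cond$kind %in% c("icu_transfer", "salvage"),
                  paste0(id, ": intervention kind must be icu_transfer or salvage"))
      cond
    },
    abrupt_cessation = cond)
}

# Age/sex strata must be non-overlapping and, within each sex, contiguous
# from the youngest stated age upward.
validate_strata <- function(strata, id) {
  df <- purrr::map_dfr(strata, ~ tibble::tibble(
    age_min = .x$age_min, age_max = .x$age_max, sex = .x$sex))
  for (s in c("male", "female")) {
    sub <- df[is.na(df$sex) | df$sex == s, ]
    sub <- sub[order(sub$age_min), ]
    assert_that(nrow(sub) > 0, paste0(id, ": no strata applicable to sex ", s))
    if (nrow(sub) > 1) {
      gaps <- sub$age_min[-1] != sub$age_max[-nrow(sub)]
      overl <- sub$age_min[-1] < sub$age_max[-nrow(sub)]
      assert_that(!any(overl), paste0(id, ": overlapping age strata"))
      assert_that(!any(gaps), paste0(id, ": age strata leave a gap"))
    }
    assert_that(is.infinite(sub$age_max[nrow(sub)]),
                paste0(id, ": strata must cover the open upper age range"))
  }
  invisible(TRUE)
}

#' Load a trigger rule set
#'
#' Reads a YAML rule configuration into a validated rule set. The shipped
#' default encodes the 24 triggers used for PAH inpatient ADE surveillance:
#' seven laboratory indicators (L1-L7), six antidote exposures (A1-A6), eight
#' clinical symptom groups (S1-S8) and three treatment interventions (T1-T3).
#' Users may add rules of any supported condition shape; the engine treats
#' user rules and shipped rules identically.
#'
#' Condition shapes: `threshold` (analyte vs strict bound, optionally
#' stratified by age band and sex, optionally expressed as `uln_multiple` of a
#' configured upper limit of normal), `any`/`all` boolean composites,
#' `baseline_ratio` (value exceeding a multiple of the first in-stay value),
#' `drug_class` (exposure to a non-target drug of a dictionary class),
#' `symptom_set` (coded clinical event in a term set), `intervention`
#' (ICU transfer / salvage) and `abrupt_cessation` (target drug stopped
#' abruptly).
#'
#' @param path YAML rule file; defaults to the shipped 24-trigger set.
#' @return An object of class `trigger_ruleset`: a named list of rules, each
#'   with `id`, `category`, `description` and a prepared `condition`.
#' @examples
#' rules <- load_ruleset()
#' length(rules)
#' table(purrr::map_chr(rules, "category"))
#' @export
load_ruleset <- function(path = NULL) {
  path <- path %||% system.file("extdata", "triggers.yaml",
                                package = "adetrigger", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  assert_that(is.list(cfg$triggers) && length(cfg$triggers) > 0,
              "rule config must contain a non-empty 'triggers' list")
  uln <- cfg$uln %||% list()
  ids <- purrr::map_chr(cfg$triggers, ~ .x$id %||% NA_character_)
  assert_that(!anyNA(ids), "every trigger needs an id")
  dup <- unique(ids[duplicated(ids)])
  assert_that(length(dup) == 0,
              paste0("duplicate trigger id(s): ", paste(dup, collapse = ", ")))
  rules <- purrr::map(cfg$triggers, function(tr) {
    assert_that(tr$category %in% RULE_CATEGORIES,
                paste0(tr$id, ": unknown category '", tr$category, "'"))
    structure(
      list(id = tr$id, category = tr$category,
           description = tr$description %||% tr$id,
           condition = prepare_condition(tr$condition, uln, tr$id)),
      class = "trigger_rule")
  })
  structure(setNames(rules, ids), class = "trigger_ruleset", uln = uln)
}

#' @export
print.trigger_ruleset <- function(x, ...) {
  cat("<trigger_ruleset> ", length(x), " rules: ",
      paste(names(x), collapse = " "), "\n", sep = "")
  invisible(x)
}
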