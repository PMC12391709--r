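#' Load a drug dictionary
#'
#' A drug dictionary maps normalized generic drug names to drug-class
#' identifiers (e.g. `vasopressor`, `antiemetic`, `pah_target`). The shipped
#' default covers the antidote classes used by the default trigger set and the
#' eight targeted pulmonary arterial hypertension (PAH) drugs. Lookup is case-
#' and whitespace-insensitive; names not present in any class resolve to
#' `"other"`.
#'
#' @param path Path to a YAML file with a top-level `classes:` map from class
#'   identifier to a list of drug names. Defaults to the shipped dictionary.
#' @return An object of class `drug_dictionary`: a named character vector
#'   mapping normalized drug name to class.
#' @examples
#' dict <- load_drug_dictionary()
#' resolve_drug_class(c("Ondansetron", "loperamide", "unobtainium"), dict)
#' @export
load_drug_dictionary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "drug_dictionary.yaml",
                                package = "adetrigger", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  assert_that(is.list(cfg$classes) && length(cfg$classes) > 0,
              "drug dictionary must contain a non-empty 'classes' map")
  entries <- purrr::imap(cfg$classes, function(names, cls) {
    setNames(rep(cls, length(names)), normalize_term(unlist(names)))
  })
  map <- unlist(unname(entries))
  dup <- duplicated(names(map))
  if (any(dup)) {
    abort(paste0("drug name(s) mapped to more than one class: ",
                 paste(unique(names(map)[dup]), collapse = ", ")))
  }
  structure(map, class = "drug_dictionary")
}

#' Resolve drug names to drug classes
#'
#' @param drug_name Character vector of drug names (any case/spacing).
#' @param dictionary A [load_drug_dictionary()] object.
#' @return Character vector of class identifiers; unknown names map to
#'   `"other"`, never to an antidote class.
#' @export
resolve_drug_class <- function(drug_name, dictionary) {
  stopifnot(inherits(dictionary, "drug_dictionary"))
  cls <- unname(dictionary[normalize_term(drug_name)])
  cls[is.na(cls)] <- "other"
  cls
}

#' Load a controlled symptom vocabulary
#'
#' Clinical event terms are recorded against a flat controlled vocabulary of
#' canonical codes, each with free-text aliases (e.g. "joint pain" maps to
#' `arthralgia`). The cohort reader rejects events whose term cannot be
#' resolved.
#'
#' @param path YAML file with a `terms:` list of `{code, aliases}` entries;
#'   defaults to the shipped vocabulary.
#' @return An object of class `symptom_vocabulary`: a named character vector
#'   from normalized alias (codes included) to canonical code.
#' @export
load_symptom_vocabulary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "symptom_vocabulary.yaml",
                                package = "adetrigger", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  assert_that(is.list(cfg$terms) && length(cfg$terms) > 0,
              "symptom vocabulary must contain a non-empty 'terms' list")
  entries <- purrr::map(cfg$terms, function(t) {
    aliases <- unique(normalize_term(c(t$code, gsub("_", " ", t$code),
                                       unlist(t$aliases))))
    setNames(rep(t$code, length(aliases)), aliases)
  })
  map <- unlist(unname(entries))
  map <- map[!duplicated(names(map))]
  structure(map, class = "symptom_vocabulary")
}

#' Normalize symptom terms to canonical codes
#'
#' @param term Character vector of raw terms or codes.
#' @param vocabulary A [load_symptom_vocabulary()] object.
#' @return Canonical codes; unresolvable terms return `NA`.
#' @export
normalize_symptom <- function(term, vocabulary) {
  stopifnot(inherits(vocabulary, "symptom_vocabulary"))
  unname(vocabulary[normalize_term(term)])
}
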