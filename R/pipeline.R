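write_manifest <- function(out_dir, step, inputs, seed = NULL) {
  manifest <- list(
    step = step,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    package = "adetrigger",
    version = as.character(utils::packageVersion("adetrigger")),
    seed = seed,
    inputs = inputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

#' Read / write adjudication label files
#'
#' Adjudication labels are stored as one CSV row per ADE with columns
#' `patient_id`, `organ_system`, `causality`, `severity`,
#' `supporting_trigger_id` (empty for ADEs found outside the trigger screen),
#' `implicated_drug`, `description`.
#'
#' @param path CSV file path.
#' @return [read_ade_labels()] returns an [ade_records()] tibble.
#' @export
read_ade_labels <- function(path) {
  assert_that(file.exists(path), paste0("label file not found: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()))
  ade_records(patient_id = df$patient_id, organ_system = df$organ_system,
              causality = df$causality, severity = df$severity,
              supporting_trigger_id = df$supporting_trigger_id %na% NA_character_,
              implicated_drug = df$implicated_drug %na% NA_character_,
              description = df$description %na% NA_character_)
}

#' @rdname read_ade_labels
#' @param ades An [ade_records()] tibble.
#' @export
write_ade_labels <- function(ades, path) {
  readr::write_csv(ades, path)
  invisible(path)
}

#' Pipeline steps
#'
#' Thin orchestration wrappers that run one stage of the surveillance
#' pipeline against files on disk and write that stage's artifacts plus a
#' JSON run manifest (inputs, seed, package version) into `out_dir`. They
#' exist for scripted use; interactive analyses should call the underlying
#' functions ([simulate_cohort()], [screen_cohort()], [build_report()],
#' [univariate_chisq()], [fit_logistic()], [item_stats()]) directly.
#'
#' @param out_dir Output directory, created if needed.
#' @param n_patients,seed,config Simulation inputs ([sim_config()]).
#' @param cohort_dir Directory of cohort CSVs ([write_cohort()] layout).
#' @param ruleset_path Optional rule YAML; default the shipped 24 triggers.
#' @param hits_path CSV of screening hits written by [run_screen()].
#' @param labels_path Adjudication CSV ([read_ade_labels()]).
#' @param scores_path Experts x items score matrix CSV (first column
#'   `expert`).
#' @name pipeline
#' @return Each step invisibly returns its main result object.
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(out_dir, n_patients = 626, seed = 1,
                         config = sim_config(n_patients = n_patients)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(config, seed = seed)
  write_cohort(sim$cohort, file.path(out_dir, "cohort"))
  write_ade_labels(sim$ades, file.path(out_dir, "labels.csv"))
  jsonlite::write_json(sim$ledger, file.path(out_dir, "ledger.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  write_manifest(out_dir, "simulate",
                 list(n_patients = config$n_patients), seed = seed)
  invisible(sim)
}

#' @rdname pipeline
#' @export
run_screen <- function(cohort_dir, out_dir, ruleset_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- read_cohort(cohort_dir)
  ruleset <- load_ruleset(ruleset_path)
  scr <- screen_cohort(cohort, ruleset)
  readr::write_csv(scr$hits, file.path(out_dir, "hits.csv"))
  readr::write_csv(scr$patients, file.path(out_dir, "flags.csv"))
  write_manifest(out_dir, "screen",
                 list(cohort_dir = cohort_dir,
                      ruleset = ruleset_path %||% "default"))
  invisible(scr)
}

read_screening <- function(hits_path, cohort) {
  hits <- readr::read_csv(hits_path, col_types = readr::cols(
    patient_id = readr::col_character(),
    trigger_id = readr::col_character(),
    first_satisfied_at = readr::col_datetime(format = ""),
    evidence = readr::col_character()))
  patients <- cohort$patients |>
    dplyr::select("patient_id") |>
    dplyr::left_join(dplyr::count(hits, .data$patient_id, name = "n_triggers"),
                     by = "patient_id") |>
    dplyr::mutate(n_triggers = dplyr::coalesce(.data$n_triggers, 0L),
                  flagged = .data$n_triggers > 0)
  structure(list(hits = hits, patients = patients), class = "ade_screening")
}

#' @rdname pipeline
#' @param fixture `"published"` to report from the packaged published count
#'   tables instead of cohort files.
#' @export
run_metrics <- function(out_dir, cohort_dir = NULL, hits_path = NULL,
                        labels_path = NULL, fixture = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (identical(fixture, "published")) {
    report <- build_report(counts = published_counts())
    inputs <- list(fixture = "published")
  } else {
    cohort <- read_cohort(cohort_dir)
    scr <- read_screening(hits_path, cohort)
    ades <- read_ade_labels(labels_path)
    report <- build_report(scr, ades, cohort)
    inputs <- list(cohort_dir = cohort_dir, hits = hits_path,
                   labels = labels_path)
  }
  readr::write_csv(report$per_trigger, file.path(out_dir, "per_trigger.csv"))
  jsonlite::write_json(
    list(summary = report$summary,
         confusion = unclass(report$confusion),
         severity = report$severity, causality = report$causality,
         organ_systems = report$organ_systems),
    file.path(out_dir, "metrics.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA)
  write_manifest(out_dir, "metrics", inputs)
  invisible(report)
}

#' @rdname pipeline
#' @export
run_riskfactors <- function(out_dir, cohort_dir, hits_path, labels_path) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- read_cohort(cohort_dir)
  scr <- read_screening(hits_path, cohort)
  ades <- read_ade_labels(labels_path)
  flag <- cohort$patients$patient_id %in% ades$patient_id
  binned_u <- bin_cohort(cohort, scr, "positive_triggers")
  chisq <- univariate_chisq(binned_u, flag)
  binned_r <- bin_cohort(cohort, scr, "positive_triggers_regression")
  fit <- fit_logistic(binned_r, flag)
  readr::write_csv(chisq, file.path(out_dir, "univariate.csv"))
  readr::write_csv(tidy(fit), file.path(out_dir, "logistic.csv"))
  jsonlite::write_json(list(univariate = chisq, logistic = tidy(fit),
                            fit = glance(fit)),
                       file.path(out_dir, "risk_factors.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, "riskfactors",
                 list(cohort_dir = cohort_dir, hits = hits_path,
                      labels = labels_path))
  invisible(list(univariate = chisq, logistic = fit))
}

#' @rdname pipeline
#' @export
run_delphi <- function(out_dir, scores_path) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  df <- readr::read_csv(scores_path, col_types = readr::cols(
    expert = readr::col_character(), .default = readr::col_double()))
  m <- as.matrix(df[setdiff(names(df), "expert")])
  rownames(m) <- df$expert
  stats <- item_stats(m)
  cuts <- delphi_cutoffs(stats)
  decisions <- select_items(stats, cuts)
  w <- kendall_w(m)
  readr::write_csv(decisions, file.path(out_dir, "decisions.csv"))
  jsonlite::write_json(list(cutoffs = cuts, kendall_w = w,
                            n_experts = nrow(m), n_items = ncol(m)),
                       file.path(out_dir, "delphi.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, "delphi", list(scores = scores_path))
  invisible(list(stats = stats, cutoffs = cuts, decisions = decisions,
                 kendall_w = w))
}
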