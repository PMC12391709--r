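RULES <- load_ruleset()

one_patient_cohort <- function(patient = make_patient(), labs = NULL,
                               medications = NULL, events = NULL,
                               interventions = NULL) {
  ade_cohort(patient,
             labs = labs %||% empty_streams$labs,
             medications = medications %||% empty_streams$medications,
             events = events %||% empty_streams$events,
             interventions = interventions %||% empty_streams$interventions)
}
empty_streams <- list(
  labs = tibble::tibble(patient_id = character(), analyte = character(),
                        value = double(),
                        timestamp = as.POSIXct(character(), tz = "UTC")),
  medications = tibble::tibble(patient_id = character(), drug_name = character(),
                               start = as.POSIXct(character(), tz = "UTC"),
                               stop = as.POSIXct(character(), tz = "UTC"),
                               is_target_pah_drug = logical(),
                               stopped_abruptly = logical()),
  events = tibble::tibble(patient_id = character(), term = character(),
                          timestamp = as.POSIXct(character(), tz = "UTC")),
  interventions = tibble::tibble(patient_id = character(), kind = character(),
                                 timestamp = as.POSIXct(character(), tz = "UTC")))
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("each trigger has a minimal firing record and a boundary non-firing record", {
  lab2 <- function(a1, v1, a2, v2) {
    dplyr::bind_rows(make_lab("p1", a1, v1, date = "2022-03-02"),
                     make_lab("p1", a2, v2, date = "2022-03-04"))
  }
  cases <- list(
    list("L1", labs = make_lab("p1", "eosinophils_abs", 0.31),
         miss_labs = make_lab("p1", "eosinophils_abs", 0.3)),
    list("L2", labs = make_lab("p1", "platelets", 49.9),
         miss_labs = make_lab("p1", "platelets", 50)),
    list("L3", labs = make_lab("p1", "leukocytes", 2.9),
         miss_labs = make_lab("p1", "leukocytes", 3)),
    list("L4", labs = make_lab("p1", "alt", 121),
         miss_labs = lab2("total_bilirubin", 60, "alp", 200)),
    list("L5", labs = lab2("creatinine", 60, "creatinine", 130),
         miss_labs = lab2("creatinine", 60, "creatinine", 120)),
    list("L6", labs = make_lab("p1", "hemoglobin", 109.9),
         miss_labs = make_lab("p1", "hemoglobin", 110)),
    list("L7", labs = make_lab("p1", "sodium", 145.1),
         miss_labs = make_lab("p1", "sodium", 145)),
    list("A1", meds = make_med("p1", "Norepinephrine"),
         miss_meds = make_med("p1", "an unlisted compound")),
    list("A2", meds = make_med("p1", "ondansetron"),
         miss_meds = make_med("p1", "sildenafil", target = TRUE)),
    list("A3", meds = make_med("p1", "loperamide"),
         miss_meds = make_med("p1", "loratadine")),
    list("A4", meds = make_med("p1", "glutathione"),
         miss_meds = make_med("p1", "lactulose")),
    list("A5", meds = make_med("p1", "senna"),
         miss_meds = make_med("p1", "glutathione")),
    list("A6", meds = make_med("p1", "cetirizine"),
         miss_meds = make_med("p1", "ondansetron")),
    list("S1", events = make_event("p1", "nosebleeds"),
         miss_events = make_event("p1", "nausea")),
    list("S2", events = make_event("p1", "vomiting"),
         miss_events = make_event("p1", "rash")),
    list("S3", events = make_event("p1", "jaw pain"),
         miss_events = make_event("p1", "headache")),
    list("S4", events = make_event("p1", "rash"),
         miss_events = make_event("p1", "edema")),
    list("S5", events = make_event("p1", "puffiness"),
         miss_events = make_event("p1", "rash")),
    list("S6", events = make_event("p1", "dizziness"),
         miss_events = make_event("p1", "vertigo")),
    list("S7", events = make_event("p1", "vertigo"),
         miss_events = make_event("p1", "dizziness")),
    list("S8", events = make_event("p1", "proteinuria"),
         miss_events = make_event("p1", "vomiting blood")),
    list("T1", ints = make_intervention("p1", "icu_transfer"),
         miss_ints = make_intervention("p1", "salvage")),
    list("T2", ints = make_intervention("p1", "salvage"),
         miss_ints = make_intervention("p1", "icu_transfer")),
    list("T3", meds = make_med("p1", "sildenafil", target = TRUE, abrupt = TRUE),
         miss_meds = make_med("p1", "cetirizine", abrupt = TRUE)))
  for (cs in cases) {
    id <- cs[[1]]
    fire <- one_patient_cohort(labs = cs$labs, medications = cs$meds,
                               events = cs$events, interventions = cs$ints)
    miss <- one_patient_cohort(labs = cs$miss_labs, medications = cs$miss_meds,
                               events = cs$miss_events,
                               interventions = cs$miss_ints)
    expect_true(id %in% screen_cohort(fire, RULES)$hits$trigger_id,
                label = paste(id, "fires on its minimal record"))
    expect_false(id %in% screen_cohort(miss, RULES)$hits$trigger_id,
                 label = paste(id, "stays silent on its boundary record"))
  }
})

test_that("liver trigger requires the bilirubin/ALP conjunction but either transaminase", {
  both <- one_patient_cohort(labs = dplyr::bind_rows(
    make_lab("p1", "total_bilirubin", 43), make_lab("p1", "alp", 251)))
  expect_true("L4" %in% screen_cohort(both, RULES)$hits$trigger_id)
  ast_only <- one_patient_cohort(labs = make_lab("p1", "ast", 140))
  expect_true("L4" %in% screen_cohort(ast_only, RULES)$hits$trigger_id)
  at_limit <- one_patient_cohort(labs = make_lab("p1", "alt", 120))
  expect_false("L4" %in% screen_cohort(at_limit, RULES)$hits$trigger_id)
})

test_that("baseline-ratio rule uses the first in-stay value and a strict ratio", {
  # ratio exactly 2 does not fire; the first observation is the baseline
  # even when a later value would give a larger ratio
  labs <- dplyr::bind_rows(
    make_lab("p1", "bun", 4, date = "2022-03-01", hour = 8),
    make_lab("p1", "bun", 3, date = "2022-03-02"),
    make_lab("p1", "bun", 8, date = "2022-03-05"))
  coh <- one_patient_cohort(labs = labs)
  expect_false("L5" %in% screen_cohort(coh, RULES)$hits$trigger_id)
  labs$value[3] <- 8.1
  coh <- one_patient_cohort(labs = labs)
  expect_true("L5" %in% screen_cohort(coh, RULES)$hits$trigger_id)
})

test_that("hemoglobin strata follow age bands and sex above 15 years", {
  hb_case <- function(age, sex, value) {
    coh <- one_patient_cohort(make_patient(age = age, sex = sex),
                              labs = make_lab("p1", "hemoglobin", value))
    "L6" %in% screen_cohort(coh, RULES)$hits$trigger_id
  }
  expect_true(hb_case(2, "male", 109))     # 6 mo - 5 y band: < 110
  expect_false(hb_case(2, "male", 112))
  expect_true(hb_case(8, "female", 114))   # 5 - 12 y band: < 115
  expect_true(hb_case(13, "male", 119))    # 12 - 15 y band: < 120
  expect_true(hb_case(30, "male", 115))    # adult male: < 120
  expect_false(hb_case(30, "female", 115)) # adult female: < 110
  expect_false(hb_case(0.33, "male", 80))  # below the youngest stratum
})

test_that("hits are deduplicated to one per patient and trigger with pooled evidence", {
  labs <- dplyr::bind_rows(make_lab("p1", "sodium", 150, date = "2022-03-04"),
                           make_lab("p1", "sodium", 152, date = "2022-03-02"))
  scr <- screen_cohort(one_patient_cohort(labs = labs), RULES)
  hit <- scr$hits[scr$hits$trigger_id == "L7", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$first_satisfied_at, ts_day("2022-03-02"))
  expect_equal(hit$evidence, "labs:1,2")
})

test_that("screening is invariant to input row order and monotone in added rows", {
  sim <- simulate_cohort(sim_config(n_patients = 30), seed = 3)
  coh <- sim$cohort
  base <- hit_pairs(screen_cohort(coh, RULES))
  set.seed(99)
  shuf <- ade_cohort(coh$patients[sample(nrow(coh$patients)), ],
                     coh$labs[sample(nrow(coh$labs)), names(empty_streams$labs)],
                     coh$medications[sample(nrow(coh$medications)),
                                     names(empty_streams$medications)],
                     coh$events[sample(nrow(coh$events)), names(empty_streams$events)],
                     coh$interventions[sample(nrow(coh$interventions)),
                                       names(empty_streams$interventions)])
  expect_equal(hit_pairs(screen_cohort(shuf, RULES)), base)

  more <- ade_cohort(coh$patients,
                     dplyr::bind_rows(coh$labs[names(empty_streams$labs)],
                                      make_lab(coh$patients$patient_id[1],
                                               "sodium", 155,
                                               date = coh$patients$admission_date[1])),
                     coh$medications[names(empty_streams$medications)],
                     coh$events[names(empty_streams$events)],
                     coh$interventions[names(empty_streams$interventions)])
  grown <- hit_pairs(screen_cohort(more, RULES))
  expect_true(nrow(dplyr::anti_join(base, grown,
                                    by = c("patient_id", "trigger_id"))) == 0)
})

test_that("the engine matches a brute-force scan on small random cohorts", {
  for (seed in c(5, 17, 29)) {
    sim <- simulate_cohort(sim_config(n_patients = 50, noise_rate = 0.03),
                           seed = seed)
    engine <- hit_pairs(screen_cohort(sim$cohort, RULES))
    brute <- oracle_screen(sim$cohort)
    expect_equal(as.data.frame(engine), as.data.frame(brute),
                 label = paste("seed", seed))
  }
})

test_that("an empty cohort screens to an empty result", {
  coh <- ade_cohort(make_patient()[0, ])
  scr <- screen_cohort(coh, RULES)
  expect_equal(nrow(scr$hits), 0)
  expect_equal(nrow(scr$patients), 0)
})

test_that("category-checked evaluation wrappers enforce their category", {
  coh <- one_patient_cohort(labs = make_lab("p1", "sodium", 150))
  expect_equal(nrow(evaluate_lab_trigger(RULES$L7, coh)), 1)
  expect_error(evaluate_lab_trigger(RULES$A1, coh), "not a laboratory")
  expect_error(evaluate_exposure_trigger(RULES$S1, coh), "not an antidote")
  expect_equal(nrow(evaluate_event_trigger(RULES$S1, coh)), 0)
})
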