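test_that("simulation is deterministic given the seed", {
  a <- simulate_cohort(sim_config(n_patients = 60), seed = 9)
  b <- simulate_cohort(sim_config(n_patients = 60), seed = 9)
  for (stream in c("patients", "labs", "medications", "events",
                   "interventions")) {
    expect_identical(a$cohort[[stream]], b$cohort[[stream]])
  }
  expect_identical(a$ledger, b$ledger)
  c <- simulate_cohort(sim_config(n_patients = 60), seed = 10)
  expect_false(identical(a$cohort$labs, c$cohort$labs))
})

test_that("generated marginals match the configured cohort description", {
  sim <- simulate_cohort(sim_config(n_patients = 5000, emission_prob = 0,
                                    noise_rate = 0), seed = 101)
  pts <- sim$cohort$patients
  los <- length_of_stay(sim$cohort)$los_days
  expect_equal(mean(los), 8.87, tolerance = 0.35 / 8.87)
  expect_equal(sd(los), 8.08, tolerance = 0.05)
  expect_equal(mean(pts$sex == "male"), 0.3914, tolerance = 0.02 / 0.3914)
  expect_equal(mean(pts$n_comorbidities), 5.74, tolerance = 0.2 / 5.74)
  expect_equal(mean(pts$n_prior_hospitalizations), 3.65, tolerance = 0.2 / 3.65)
  expect_equal(mean(lengths(strsplit(pts$target_drug_classes, ";"))),
               1.93, tolerance = 0.05 / 1.93)
  expect_true(all(los >= 1 & los <= 68))
  expect_true(all(pts$age_at_admission > 28 / 365 & pts$age_at_admission <= 93))
  # ADE prevalence is calibrated to its target within Monte-Carlo error
  prev <- mean(pts$patient_id %in% sim$ades$patient_id)
  expect_equal(prev, 0.1757, tolerance = 3 * sqrt(0.1757 * 0.8243 / 5000) / 0.1757)
})

test_that("raising a risk coefficient raises incidence in that stratum", {
  base_cfg <- sim_config(n_patients = 3000, emission_prob = 0, noise_rate = 0)
  hi_betas <- base_cfg$risk_betas
  hi_betas$comorbidities[">9"] <- 3
  hi_cfg <- sim_config(n_patients = 3000, emission_prob = 0, noise_rate = 0,
                       risk_betas = hi_betas)
  rate_in_stratum <- function(sim) {
    pts <- sim$cohort$patients
    sel <- pts$n_comorbidities > 9
    mean(pts$patient_id[sel] %in% sim$ades$patient_id)
  }
  expect_gt(rate_in_stratum(simulate_cohort(hi_cfg, seed = 41)),
            rate_in_stratum(simulate_cohort(base_cfg, seed = 41)))
})

test_that("with no ADEs and no noise the screen is silent", {
  sim <- simulate_cohort(sim_config(n_patients = 80, prevalence = 0,
                                    noise_rate = 0), seed = 15)
  expect_equal(nrow(sim$ledger$ades), 0)
  expect_equal(nrow(screen_cohort(sim$cohort)$hits), 0)
})

test_that("ledger closure: full emission and zero noise make the screen exact", {
  sim <- simulate_cohort(sim_config(n_patients = 300, emission_prob = 1,
                                    noise_rate = 0), seed = 23)
  scr <- screen_cohort(sim$cohort)
  expect_equal(as.data.frame(hit_pairs(scr)),
               as.data.frame(sim$ledger$expected_hits))
  # every ADE patient is flagged: patient-level sensitivity is 100%
  ade_patients <- unique(sim$ledger$ades$patient_id)
  flagged <- scr$patients$patient_id[scr$patients$flagged]
  expect_true(all(ade_patients %in% flagged))
})

test_that("silent ADEs appear in the ledger but not in the screen", {
  sim <- simulate_cohort(sim_config(n_patients = 400, emission_prob = 0.5,
                                    noise_rate = 0), seed = 37)
  silent <- sim$ledger$ades[!sim$ledger$ades$emitted, ]
  expect_gt(nrow(silent), 0)
  scr <- screen_cohort(sim$cohort)
  hits <- hit_pairs(scr)
  missed <- dplyr::anti_join(
    silent[, c("patient_id", "trigger_id")], hits,
    by = c("patient_id", "trigger_id"))
  # a silent ADE only surfaces if another ADE of the same patient emitted
  # the same trigger
  emitted_pairs <- unique(sim$ledger$ades[sim$ledger$ades$emitted,
                                          c("patient_id", "trigger_id")])
  surfaced <- dplyr::anti_join(silent[, c("patient_id", "trigger_id")],
                               missed, by = c("patient_id", "trigger_id"))
  expect_true(all(
    paste(surfaced$patient_id, surfaced$trigger_id) %in%
      paste(emitted_pairs$patient_id, emitted_pairs$trigger_id)))
})

test_that("injected ADE signatures fire their mapped triggers", {
  coh <- ade_cohort(make_patient("p1", age = 30, sex = "female"))
  set.seed(2)
  inj <- inject_ade(coh, "p1", "anemia")
  expect_true("L6" %in% screen_cohort(inj$cohort)$hits$trigger_id)
  hb <- inj$cohort$labs$value[inj$cohort$labs$analyte == "hemoglobin"]
  expect_lt(hb, 110)

  inj <- inject_ade(coh, "p1", "liver_injury")
  expect_true("L4" %in% screen_cohort(inj$cohort)$hits$trigger_id)
  expect_gt(inj$cohort$labs$value[inj$cohort$labs$analyte == "alt"], 120)

  inj <- inject_ade(coh, "p1", "kidney_damage")
  expect_true("L5" %in% screen_cohort(inj$cohort)$hits$trigger_id)

  # silent injection leaves the record untouched and marks the ledger
  silent <- inject_ade(coh, "p1", "anemia", emit = FALSE)
  expect_equal(nrow(silent$cohort$labs), 0)
  expect_false(silent$ledger_entry$emitted)
  expect_error(inject_ade(coh, "p1", "spontaneous combustion"), "unknown ade_type")
})
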