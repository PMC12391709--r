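#' Configuration for the synthetic cohort generator
#'
#' The defaults emulate the published validation cohort: 626 admissions,
#' 39.14% male, age 50.04 +/- 18.18 years (range 4 months to 93 years),
#' length of stay with mean 8.87 and SD 8.08 days on [1, 68] (modelled
#' lognormal, truncated), comorbidity count 5.74 +/- 3.63 and previous
#' hospitalizations 3.65 +/- 3.55 (shifted negative binomial), and 1.93 +/-
#' 0.95 targeted drug classes on 1-6 (shifted Poisson). ADE status follows a
#' logistic model over the standard covariate binning whose default
#' coefficients are the published regression coefficients; the intercept is
#' calibrated at run time so that the marginal ADE-patient fraction matches
#' `prevalence`. Each ADE is assigned a type from the nine-group organ-system
#' taxonomy (empirical type frequencies), a severity and a causality from the
#' published empirical distributions, and — with probability `emission_prob`
#' — a detectable trigger signature injected into the record streams.
#' ADEs whose signature is not emitted are the false-negative mechanism.
#' Independently, each (patient, trigger) pair receives a false-positive
#' noise signature with probability `noise_rate`.
#'
#' @param n_patients Number of admissions.
#' @param p_male Probability of male sex.
#' @param age,los,comorbidities,prior_hospitalizations,target_drugs Lists of
#'   distribution parameters (see defaults).
#' @param prevalence Target marginal fraction of patients with >= 1 ADE.
#' @param risk_betas Named list of per-covariate coefficient vectors on the
#'   non-reference bins of [covariate_binnings()].
#' @param extra_ades_mean Mean of the Poisson count of ADEs beyond the first
#'   for each ADE patient.
#' @param emission_prob Probability that an ADE emits its trigger signature.
#' @param noise_rate Per-(patient, trigger) false-positive signature
#'   probability.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 626,
                       p_male = 0.3914,
                       age = list(mean = 50.04, sd = 18.18, min = 0.33, max = 93),
                       los = list(mean = 8.87, sd = 8.08, min = 1, max = 68),
                       comorbidities = list(mean = 5.74, sd = 3.63, min = 1, max = 25),
                       prior_hospitalizations = list(mean = 3.65, sd = 3.55,
                                                     min = 1, max = 24),
                       target_drugs = list(mean = 1.93, min = 1, max = 6),
                       prevalence = 0.1757,
                       risk_betas = list(
                         sex = c("female" = 0.333),
                         age = c("18-40" = -0.291, "41-60" = -0.612,
                                 ">60" = -1.080),
                         los_days = c("11-20" = 0.782, "21-30" = 0.811,
                                      ">30" = 0.580),
                         comorbidities = c("4-6" = 0.523, "7-9" = 0.430,
                                           ">9" = 0.922),
                         target_drug_classes = c("2" = 0.400, "3" = 0.163,
                                                 ">3" = 0.403),
                         prior_hospitalizations = c("4-6" = 0.090,
                                                    ">6" = 0.085)),
                       extra_ades_mean = 0.3,
                       emission_prob = 1 - 2 / 143,
                       noise_rate = 0.0133) {
  assert_that(n_patients >= 1, "n_patients must be positive")
  assert_that(p_male >= 0 && p_male <= 1, "p_male must be a probability")
  assert_that(prevalence >= 0 && prevalence < 1,
              "prevalence must be in [0, 1)")
  assert_that(emission_prob >= 0 && emission_prob <= 1,
              "emission_prob must be a probability")
  assert_that(noise_rate >= 0 && noise_rate <= 1,
              "noise_rate must be a probability")
  structure(
    list(n_patients = as.integer(n_patients), p_male = p_male, age = age,
         los = los, comorbidities = comorbidities,
         prior_hospitalizations = prior_hospitalizations,
         target_drugs = target_drugs, prevalence = prevalence,
         risk_betas = risk_betas, extra_ades_mean = extra_ades_mean,
         emission_prob = emission_prob, noise_rate = noise_rate),
    class = "sim_config")
}

TARGET_DRUGS <- c("sildenafil", "tadalafil", "ambrisentan", "macitentan",
                  "riociguat", "selexipag", "beraprost", "treprostinil")

# ADE taxonomy: type, empirical frequency weight, organ-system group and the
# trigger whose signature the type emits.
ADE_TAXONOMY <- tibble::tribble(
  ~ade_type, ~weight, ~organ_system, ~trigger_id,
  "anemia", 35, "blood_bleeding_clotting", "L6",
  "eosinophilia", 4, "blood_bleeding_clotting", "L1",
  "thrombocytopenia", 3, "blood_bleeding_clotting", "L2",
  "leukopenia", 3, "blood_bleeding_clotting", "L3",
  "hemorrhage", 1, "blood_bleeding_clotting", "S1",
  "gi_symptoms", 31, "gastrointestinal", "S2",
  "constipation", 7, "gastrointestinal", "A5",
  "liver_injury", 13, "liver_kidney", "L4",
  "kidney_damage", 8, "liver_kidney", "L5",
  "allergic_reaction", 10, "systemic", "S4",
  "hypotension", 5, "metabolic_nutritional", "A1",
  "hypernatremia", 3, "metabolic_nutritional", "L7",
  "edema", 5, "other", "S5",
  "abrupt_stop", 2, "other", "T3",
  "rescue", 1, "other", "T2",
  "dizziness_headache", 5, "central_peripheral_nervous", "S6",
  "neuro", 1, "central_peripheral_nervous", "S7",
  "skin_reaction", 4, "skin_adnexal", "S4",
  "musculoskeletal", 2, "musculoskeletal", "S3")

SEVERITY_PROBS <- c(D = 24, E = 102, F = 15, H = 2) / 143
CAUSALITY_PROBS <- c(probably_related = 119, very_probably_related = 19,
                     definitely_related = 5) / 143

# Age/sex-specific hemoglobin lower bound of the default L6 rule.
hb_bound <- function(age, sex) {
  dplyr::case_when(age >= 0.5 & age < 5 ~ 110,
                   age >= 5 & age < 12 ~ 115,
                   age >= 12 & age < 15 ~ 120,
                   age >= 15 & sex == "male" ~ 120,
                   age >= 15 & sex == "female" ~ 110,
                   TRUE ~ NA_real_)
}

rnorm_trunc <- function(n, mean, sd, min, max) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < min | out > max)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < min | out > max)
  }
  out
}

# Moments of a lognormal truncated to [a, b].
trunc_lnorm_moments <- function(mu, s, a, b) {
  za <- (log(a) - mu) / s
  zb <- (log(b) - mu) / s
  d <- pnorm(zb) - pnorm(za)
  m1 <- exp(mu + s^2 / 2) * (pnorm(zb - s) - pnorm(za - s)) / d
  m2 <- exp(2 * mu + 2 * s^2) * (pnorm(zb - 2 * s) - pnorm(za - 2 * s)) / d
  c(mean = m1, sd = sqrt(pmax(m2 - m1^2, 0)))
}

# Lognormal, truncated to [min, max] and rounded to integer days, with the
# pre-truncation parameters adjusted so the TRUNCATED distribution matches
# the stated mean/SD.
rlnorm_trunc_int <- function(n, mean, sd, min, max) {
  sigma2 <- log(1 + (sd / mean)^2)
  start <- c(log(mean) - sigma2 / 2, sqrt(sigma2))
  fit <- stats::optim(start, function(p) {
    m <- trunc_lnorm_moments(p[1], abs(p[2]), min - 0.5 + 1e-9, max + 0.5)
    (m["mean"] - mean)^2 + (m["sd"] - sd)^2
  })
  mu <- fit$par[1]; sig <- abs(fit$par[2])
  out <- round(rlnorm(n, mu, sig))
  bad <- which(out < min | out > max)
  while (length(bad) > 0) {
    out[bad] <- round(rlnorm(length(bad), mu, sig))
    bad <- which(out < min | out > max)
  }
  as.integer(out)
}

# Shifted negative binomial matched to the stated mean/SD, support [min, max].
rnbinom_shift <- function(n, mean, sd, min, max) {
  m <- mean - min
  v <- sd^2
  size <- if (v > m) m^2 / (v - m) else Inf
  out <- if (is.finite(size)) rnbinom(n, size = size, mu = m) else rpois(n, m)
  as.integer(pmin(out + min, max))
}

day_ts <- function(date, hour) as.POSIXct(paste0(date, " ", hour, ":00:00"),
                                          tz = "UTC")

# Generate the record-stream rows that make `trigger_id` fire for `p`
# (one patient row joined with los_days). Returns a list of stream tibbles.
signature_rows <- function(trigger_id, p, baseline_creatinine) {
  day <- p$admission_date + sample.int(p$los_days, 1) - 1L
  ts <- day_ts(day, 12)
  lab <- function(analyte, value, t = ts) {
    list(labs = tibble::tibble(patient_id = p$patient_id, analyte = analyte,
                               value = round(value, 2), timestamp = t))
  }
  med <- function(drug, target = FALSE, abrupt = FALSE) {
    list(medications = tibble::tibble(
      patient_id = p$patient_id, drug_name = drug,
      start = day_ts(p$admission_date, 9), stop = ts,
      is_target_pah_drug = target, stopped_abruptly = abrupt))
  }
  evt <- function(code) {
    list(events = tibble::tibble(patient_id = p$patient_id, term = code,
                                 timestamp = ts))
  }
  intv <- function(kind) {
    list(interventions = tibble::tibble(patient_id = p$patient_id,
                                        kind = kind, timestamp = ts))
  }
  switch(
    trigger_id,
    L1 = lab("eosinophils_abs", 0.3 + runif(1, 0.05, 1.2)),
    L2 = lab("platelets", runif(1, 5, 49.5)),
    L3 = lab("leukocytes", runif(1, 0.5, 2.9)),
    L4 = lab("alt", 120 * runif(1, 1.1, 3)),
    L5 = lab("creatinine", baseline_creatinine * runif(1, 2.2, 4),
             t = day_ts(day, 18)),
    L6 = lab("hemoglobin",
             max(40, hb_bound(p$age_at_admission, p$sex) - runif(1, 5, 30))),
    L7 = lab("sodium", runif(1, 146, 160)),
    A1 = med("norepinephrine"),
    A2 = med("ondansetron"),
    A3 = med("loperamide"),
    A4 = med("glutathione"),
    A5 = med("lactulose"),
    A6 = med("loratadine"),
    S1 = evt("hemorrhage"),
    S2 = evt(sample(c("nausea", "vomiting", "diarrhea"), 1)),
    S3 = evt(sample(c("arthralgia", "jaw_pain", "back_pain"), 1)),
    S4 = evt(sample(c("rash", "itching", "flushing"), 1)),
    S5 = evt(sample(c("peripheral_edema", "edema"), 1)),
    S6 = evt(sample(c("dizziness", "headache"), 1)),
    S7 = evt(sample(c("insomnia", "vertigo", "fainting"), 1)),
    S8 = evt(sample(c("kidney_injury", "proteinuria"), 1)),
    T1 = intv("icu_transfer"),
    T2 = intv("salvage"),
    T3 = med(strsplit(p$target_drug_classes, ";", fixed = TRUE)[[1]][1],
             target = TRUE, abrupt = TRUE),
    abort(paste0("no signature defined for trigger ", trigger_id)))
}

# The trigger a given ADE type emits for a given patient. Infants below the
# youngest hemoglobin stratum emit a bleeding event instead of a low
# hemoglobin, so every emitted signature is detectable.
type_trigger <- function(ade_type, age) {
  tr <- ADE_TAXONOMY$trigger_id[match(ade_type, ADE_TAXONOMY$ade_type)]
  ifelse(ade_type == "anemia" & age < 0.5, "S1", tr)
}

#' Simulate a synthetic PAH surveillance cohort with ground truth
#'
#' Draws a cohort under [sim_config()], injects ADE trigger signatures and
#' false-positive noise into the record streams, and returns both the
#' validated [ade_cohort()] and a complete ground-truth ledger. The ledger
#' makes the generator a testing oracle: every emitted ADE signature and
#' every noise signature corresponds to a record feature the trigger engine
#' fires on, so with `noise_rate = 0` and `emission_prob = 1` the engine's
#' hit set equals the ledger exactly.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the run is fully deterministic given the seed.
#' @return List with `cohort` ([ade_cohort()]), `ledger` (list of `ades`,
#'   `noise`, `expected_hits` tibbles), `ades` (an [ade_records()] table of
#'   the adjudicated truth, with `supporting_trigger_id` present only for
#'   emitted signatures), and `intercept` (the calibrated logistic
#'   intercept).
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 100), seed = 42)
#' sim$cohort
#' nrow(sim$ledger$ades)
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_patients

  patients <- tibble::tibble(
    patient_id = sprintf("p%05d", seq_len(n)),
    age_at_admission = round(rnorm_trunc(n, config$age$mean, config$age$sd,
                                         config$age$min, config$age$max), 2),
    sex = ifelse(runif(n) < config$p_male, "male", "female"),
    admission_date = as.Date("2022-01-01") + sample.int(440, n, replace = TRUE) - 1L,
    n_comorbidities = rnbinom_shift(n, config$comorbidities$mean,
                                    config$comorbidities$sd,
                                    config$comorbidities$min,
                                    config$comorbidities$max),
    n_prior_hospitalizations = rnbinom_shift(
      n, config$prior_hospitalizations$mean, config$prior_hospitalizations$sd,
      config$prior_hospitalizations$min, config$prior_hospitalizations$max),
    los_days = rlnorm_trunc_int(n, config$los$mean, config$los$sd,
                                config$los$min, config$los$max))
  n_drugs <- pmin(1L + rpois(n, config$target_drugs$mean - 1),
                  config$target_drugs$max)
  patients$target_drug_classes <- vapply(
    n_drugs, function(k) paste(sample(TARGET_DRUGS, k), collapse = ";"),
    character(1))
  patients$discharge_date <- patients$admission_date + patients$los_days

  # Logistic ADE risk over the standard binning; intercept calibrated so the
  # marginal prevalence matches the configured target.
  b <- covariate_binnings()
  beta_of <- function(betas, lev) {
    out <- betas[as.character(lev)]
    out[is.na(out)] <- 0
    unname(out)
  }
  lp <- beta_of(config$risk_betas$sex, patients$sex) +
    beta_of(config$risk_betas$age,
            bin_one(floor(patients$age_at_admission), b$age)) +
    beta_of(config$risk_betas$los_days,
            bin_one(patients$los_days, b$los_days)) +
    beta_of(config$risk_betas$comorbidities,
            bin_one(patients$n_comorbidities, b$comorbidities)) +
    beta_of(config$risk_betas$target_drug_classes,
            bin_one(n_drugs, b$target_drug_classes)) +
    beta_of(config$risk_betas$prior_hospitalizations,
            bin_one(patients$n_prior_hospitalizations,
                    b$prior_hospitalizations))
  intercept <- if (config$prevalence == 0) -Inf else
    uniroot(function(a) mean(plogis(a + lp)) - config$prevalence,
            c(-20, 10))$root
  has_ade <- runif(n) < plogis(intercept + lp)

  # Baseline labs for every admission (renal baseline feeds the
  # baseline-ratio rule).
  baseline_creatinine <- runif(n, 50, 90)
  labs <- tibble::tibble(
    patient_id = rep(patients$patient_id, 2),
    analyte = rep(c("creatinine", "bun"), each = n),
    value = round(c(baseline_creatinine, runif(n, 3, 7)), 2),
    timestamp = rep(day_ts(patients$admission_date, 8), 2))

  medications <- tibble::tibble(
    patient_id = rep(patients$patient_id, n_drugs),
    drug_name = unlist(strsplit(patients$target_drug_classes, ";", fixed = TRUE)),
    start = rep(day_ts(patients$admission_date, 9), n_drugs),
    stop = rep(day_ts(patients$discharge_date, 18), n_drugs),
    is_target_pah_drug = TRUE, stopped_abruptly = FALSE)
  events <- empty_events()
  interventions <- empty_interventions()

  extra <- list(labs = list(labs), medications = list(medications),
                events = list(events), interventions = list(interventions))
  add_rows <- function(extra, rows) {
    for (nm in names(rows)) extra[[nm]] <- c(extra[[nm]], list(rows[[nm]]))
    extra
  }

  # ADE truth; signatures are injected per emitted ADE below. A patient's
  # ADE types are drawn so their mapped triggers are distinct: one positive
  # trigger instance corresponds to at most one adjudicated ADE, keeping
  # per-trigger true-positive counts within per-trigger positives.
  idx_ade <- which(has_ade)
  k <- pmin(1L + rpois(length(idx_ade), config$extra_ades_mean), 10L)
  owner <- rep(idx_ade, k)
  n_ades <- length(owner)
  if (n_ades > 0) {
    types <- character(n_ades)
    pos <- 1L
    for (j in seq_along(idx_ade)) {
      age_j <- patients$age_at_admission[idx_ade[j]]
      repeat {
        draw <- sample(ADE_TAXONOMY$ade_type, k[j], replace = FALSE,
                       prob = ADE_TAXONOMY$weight)
        if (!anyDuplicated(type_trigger(draw, age_j))) break
      }
      types[pos:(pos + k[j] - 1L)] <- draw
      pos <- pos + k[j]
    }
    ades <- tibble::tibble(
      patient_id = patients$patient_id[owner],
      ade_type = types,
      organ_system = ADE_TAXONOMY$organ_system[
        match(types, ADE_TAXONOMY$ade_type)],
      severity = sample(names(SEVERITY_PROBS), n_ades, replace = TRUE,
                        prob = SEVERITY_PROBS),
      causality = sample(names(CAUSALITY_PROBS), n_ades, replace = TRUE,
                         prob = CAUSALITY_PROBS),
      trigger_id = type_trigger(types, patients$age_at_admission[owner]),
      emitted = runif(n_ades) < config$emission_prob,
      ade_id = seq_len(n_ades))
    for (j in which(ades$emitted)) {
      extra <- add_rows(extra, signature_rows(ades$trigger_id[j],
                                              patients[owner[j], ],
                                              baseline_creatinine[owner[j]]))
    }
  } else {
    ades <- tibble::tibble(patient_id = character(), ade_type = character(),
                           organ_system = character(), severity = character(),
                           causality = character(), trigger_id = character(),
                           emitted = logical(), ade_id = integer())
  }

  # False-positive noise signatures
  noise <- tibble::tibble(patient_id = character(), trigger_id = character())
  if (config$noise_rate > 0) {
    trigger_ids <- sort(c(paste0("L", 1:7), paste0("A", 1:6),
                          paste0("S", 1:8), paste0("T", 1:3)))
    fire <- which(matrix(runif(n * length(trigger_ids)) < config$noise_rate,
                         nrow = n), arr.ind = TRUE)
    keep <- !(trigger_ids[fire[, "col"]] == "L6" &
                patients$age_at_admission[fire[, "row"]] < 0.5)
    fire <- fire[keep, , drop = FALSE]
    if (nrow(fire) > 0) {
      for (r in seq_len(nrow(fire))) {
        i <- fire[r, "row"]
        extra <- add_rows(extra, signature_rows(trigger_ids[fire[r, "col"]],
                                                patients[i, ],
                                                baseline_creatinine[i]))
      }
      noise <- tibble::tibble(patient_id = patients$patient_id[fire[, "row"]],
                              trigger_id = trigger_ids[fire[, "col"]]) |>
        dplyr::arrange(.data$patient_id, .data$trigger_id)
    }
  }

  expected_hits <- dplyr::bind_rows(
    dplyr::select(dplyr::filter(ades, .data$emitted), "patient_id", "trigger_id"),
    noise) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$patient_id, .data$trigger_id)

  cohort <- ade_cohort(
    patients = dplyr::select(patients, -"los_days"),
    labs = dplyr::bind_rows(extra$labs),
    medications = dplyr::bind_rows(extra$medications),
    events = dplyr::bind_rows(extra$events),
    interventions = dplyr::bind_rows(extra$interventions))

  truth <- ade_records(
    patient_id = ades$patient_id, organ_system = ades$organ_system,
    causality = ades$causality, severity = ades$severity,
    supporting_trigger_id = dplyr::if_else(ades$emitted, ades$trigger_id,
                                           NA_character_),
    description = ades$ade_type)

  list(cohort = cohort,
       ledger = list(ades = ades, noise = noise, expected_hits = expected_hits),
       ades = truth,
       intercept = intercept,
       config = config, seed = seed)
}

#' Inject one ADE signature into an existing cohort
#'
#' Appends the record-stream feature that makes the trigger mapped to
#' `ade_type` fire for `patient_id` (e.g. anemia appends a hemoglobin value
#' below the admission's age/sex band so the hemoglobin trigger fires;
#' liver injury appends an ALT observation above three times the upper limit
#' of normal). With `emit = FALSE` the record is left unchanged and the
#' returned ledger entry marks a silent ADE — the false-negative mechanism.
#'
#' @param cohort An [ade_cohort()].
#' @param patient_id Admission to modify.
#' @param ade_type One of the types in `ADE_TAXONOMY`.
#' @param severity,causality Optional fixed grades; sampled from the
#'   empirical distributions when `NULL`.
#' @param emit Emit the detectable signature?
#' @return List with the modified `cohort` and a one-row `ledger_entry`.
#' @export
inject_ade <- function(cohort, patient_id, ade_type, severity = NULL,
                       causality = NULL, emit = TRUE) {
  stopifnot(inherits(cohort, "ade_cohort"))
  assert_that(ade_type %in% ADE_TAXONOMY$ade_type,
              paste0("unknown ade_type: ", ade_type))
  i <- match(patient_id, cohort$patients$patient_id)
  assert_that(!is.na(i), paste0("unknown patient_id: ", patient_id))
  p <- dplyr::left_join(cohort$patients[i, ], length_of_stay(cohort),
                        by = "patient_id")
  trig <- type_trigger(ade_type, p$age_at_admission)
  entry <- tibble::tibble(
    patient_id = patient_id, ade_type = ade_type,
    organ_system = ADE_TAXONOMY$organ_system[
      match(ade_type, ADE_TAXONOMY$ade_type)],
    severity = severity %||% sample(names(SEVERITY_PROBS), 1,
                                    prob = SEVERITY_PROBS),
    causality = causality %||% sample(names(CAUSALITY_PROBS), 1,
                                      prob = CAUSALITY_PROBS),
    trigger_id = trig, emitted = emit)
  if (emit) {
    base_cr <- cohort$labs |>
      dplyr::filter(.data$patient_id == !!patient_id,
                    .data$analyte == "creatinine") |>
      dplyr::arrange(.data$timestamp) |>
      dplyr::pull("value")
    rows <- signature_rows(trig, p, baseline_creatinine = base_cr[1] %na% 70)
    if (trig == "L5" && length(base_cr) == 0) {
      # no renal baseline on record: provide one so the ratio rule can fire
      rows$labs <- dplyr::bind_rows(
        tibble::tibble(patient_id = patient_id, analyte = "creatinine",
                       value = 70, timestamp = day_ts(p$admission_date, 8)),
        dplyr::mutate(rows$labs, value = 70 * runif(1, 2.2, 4)))
    }
    streams <- list(labs = cohort$labs[names(empty_labs())],
                    medications = cohort$medications[names(empty_medications())],
                    events = cohort$events[names(empty_events())],
                    interventions = cohort$interventions[names(empty_interventions())])
    for (nm in names(rows)) {
      streams[[nm]] <- dplyr::bind_rows(streams[[nm]], rows[[nm]])
    }
    cohort <- ade_cohort(cohort$patients, streams$labs, streams$medications,
                         streams$events, streams$interventions)
  }
  list(cohort = cohort, ledger_entry = entry)
}
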