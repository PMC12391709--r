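# Builders for small hand-made cohorts.

make_patient <- function(id = "p1", age = 40, sex = "female",
                         admission = "2022-03-01", discharge = "2022-03-09",
                         comorbidities = 3L, prior = 1L,
                         drugs = "sildenafil") {
  tibble::tibble(
    patient_id = id, age_at_admission = age, sex = sex,
    admission_date = as.Date(admission), discharge_date = as.Date(discharge),
    n_comorbidities = comorbidities, n_prior_hospitalizations = prior,
    target_drug_classes = drugs)
}

ts_day <- function(date, hour = 12) {
  as.POSIXct(paste0(date, " ", sprintf("%02d", hour), ":00:00"), tz = "UTC")
}

make_lab <- function(id, analyte, value, date = "2022-03-02", hour = 12) {
  tibble::tibble(patient_id = id, analyte = analyte, value = value,
                 timestamp = ts_day(date, hour))
}

make_med <- function(id, drug, start = "2022-03-01", stop = "2022-03-05",
                     target = FALSE, abrupt = FALSE) {
  tibble::tibble(patient_id = id, drug_name = drug,
                 start = ts_day(start, 9), stop = ts_day(stop, 18),
                 is_target_pah_drug = target, stopped_abruptly = abrupt)
}

make_event <- function(id, term, date = "2022-03-03") {
  tibble::tibble(patient_id = id, term = term, timestamp = ts_day(date))
}

make_intervention <- function(id, kind, date = "2022-03-04") {
  tibble::tibble(patient_id = id, kind = kind, timestamp = ts_day(date))
}

# Independent brute-force trigger oracle: per-record loops with the 24 rules
# restated from scratch (thresholds hard-coded; no shared evaluation code).
oracle_screen <- function(cohort) {
  dict <- list(
    A1 = c("norepinephrine", "dobutamine", "mesalamine", "ephedrine",
           "dopamine", "phenylephrine"),
    A2 = c("metoclopramide", "tropisetron", "dolasetron", "palonosetron",
           "ondansetron", "fosaprepitant", "aprepitant", "phenformin"),
    A3 = c("montmorillonite powder", "bifidobacterium bifidum tetragonum",
           "live combined bifidobacterium and lactobacillus tablets",
           "bifidobacterium live bacteria", "loperamide",
           "saccharomyces boulardii", "live bacillus cereus bifidus"),
    A4 = c("glutathione", "diammonium glycyrrhizinate",
           "magnesium isoglycyrrhizinate", "compound glycyrrhizin",
           "monoammonium cysteine glycyrrhizinate",
           "polyene phosphatidylcholine", "ursodeoxycholic acid", "silymarin"),
    A5 = c("glycerine enema", "lactulose", "lactulose oral solution",
           "hemp nut soft gels", "bisacodyl", "bisacodyl enteric tablets",
           "senna"),
    A6 = c("loratadine", "ebastine", "chlorpheniramine maleate",
           "chlorpheniramine", "olopatadine", "cetirizine", "cyproheptadine",
           "promethazine", "diphenhydramine"))
  sets <- list(
    S1 = c("rectal_bleeding", "nosebleed", "eye_bleeding",
           "intraabdominal_bleeding", "hemorrhage", "bleeding_tendency",
           "severe_bleeding", "hematemesis", "gi_bleeding",
           "subcutaneous_bleeding", "urinary_bleeding"),
    S2 = c("nausea", "vomiting", "abdominal_pain", "diarrhea", "bloating"),
    S3 = c("arthralgia", "bone_pain", "jaw_pain", "back_pain", "neck_pain",
           "chest_pain"),
    S4 = c("flushing", "hot_flush", "rash", "itching", "hives", "eczema"),
    S5 = c("peripheral_edema", "puffiness", "edema", "swelling"),
    S6 = c("dizziness", "headache"),
    S7 = c("insomnia", "anxiety", "transient_amnesia", "depression",
           "drowsiness", "vertigo", "upright_vertigo", "fainting",
           "loss_of_consciousness", "numbness", "floating_sensation",
           "neuralgia"),
    S8 = c("kidney_injury", "acute_kidney_injury", "oliguria", "anuria",
           "acute_tubular_necrosis", "tubular_dysfunction", "proteinuria",
           "hematuria", "chronic_kidney_damage"))
  out <- list()
  for (i in seq_len(nrow(cohort$patients))) {
    p <- cohort$patients[i, ]
    labs <- cohort$labs[cohort$labs$patient_id == p$patient_id, ]
    meds <- cohort$medications[cohort$medications$patient_id == p$patient_id, ]
    evts <- cohort$events[cohort$events$patient_id == p$patient_id, ]
    ints <- cohort$interventions[cohort$interventions$patient_id == p$patient_id, ]
    val <- function(a) labs$value[labs$analyte == a]
    fired <- character()
    if (any(val("eosinophils_abs") > 0.3)) fired <- c(fired, "L1")
    if (any(val("platelets") < 50)) fired <- c(fired, "L2")
    if (any(val("leukocytes") < 3)) fired <- c(fired, "L3")
    if (any(val("alt") > 120) || any(val("ast") > 120) ||
        (any(val("total_bilirubin") > 42) && any(val("alp") > 250))) {
      fired <- c(fired, "L4")
    }
    for (a in c("bun", "creatinine")) {
      sub <- labs[labs$analyte == a, ]
      sub <- sub[order(sub$timestamp, sub$lab_id), ]
      if (nrow(sub) >= 2 && sub$value[1] > 0 &&
          any(sub$value[-1] > 2 * sub$value[1])) {
        fired <- c(fired, "L5")
        break
      }
    }
    hb_lim <- if (p$age_at_admission >= 0.5 && p$age_at_admission < 5) 110
      else if (p$age_at_admission >= 5 && p$age_at_admission < 12) 115
      else if (p$age_at_admission >= 12 && p$age_at_admission < 15) 120
      else if (p$age_at_admission >= 15 && p$sex == "male") 120
      else if (p$age_at_admission >= 15 && p$sex == "female") 110
      else NA
    if (!is.na(hb_lim) && any(val("hemoglobin") < hb_lim)) fired <- c(fired, "L6")
    if (any(val("sodium") > 145)) fired <- c(fired, "L7")
    nt <- meds[!meds$is_target_pah_drug, ]
    for (a in names(dict)) {
      if (any(tolower(trimws(nt$drug_name)) %in% dict[[a]])) fired <- c(fired, a)
    }
    for (s in names(sets)) {
      if (any(evts$code %in% sets[[s]])) fired <- c(fired, s)
    }
    if (any(ints$kind == "icu_transfer")) fired <- c(fired, "T1")
    if (any(ints$kind == "salvage")) fired <- c(fired, "T2")
    if (any(meds$is_target_pah_drug & meds$stopped_abruptly)) fired <- c(fired, "T3")
    if (length(fired) > 0) {
      out[[length(out) + 1]] <- tibble::tibble(patient_id = p$patient_id,
                                               trigger_id = unique(fired))
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(patient_id = character(), trigger_id = character()))
  }
  dplyr::arrange(res, patient_id, trigger_id)
}

hit_pairs <- function(screening) {
  dplyr::arrange(screening$hits[, c("patient_id", "trigger_id")],
                 patient_id, trigger_id)
}
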