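test_that("ppv follows its defining ratio with strict edge handling", {
  expect_equal(ppv(472, 143), 30.30)
  expect_equal(ppv(6, 4), 66.67)
  expect_equal(ppv(7, 7), 100)
  expect_true(is.na(ppv(0, 0)))        # undefined, not zero
  expect_error(ppv(3, 4), "exceed")
  expect_error(ppv(-1, 0), "non-negative")
})

test_that("confusion metrics match hand arithmetic and handle degenerate margins", {
  m <- confusion_metrics(confusion_matrix(8, 2, 2, 8))
  expect_equal(m$sensitivity, 80)
  expect_equal(m$specificity, 80)
  expect_equal(m$youden, 0.60)
  perfect <- confusion_metrics(confusion_matrix(5, 0, 0, 5))
  expect_equal(perfect$youden, 1)
  no_pos <- confusion_metrics(confusion_matrix(0, 3, 0, 7))
  expect_true(is.na(no_pos$sensitivity))
  expect_true(is.na(no_pos$youden))
})

test_that("rates are linear in the ADE count and zero ADEs give zero rates", {
  r1 <- ade_rates(10, 500, 100, 200, 8)
  r2 <- ade_rates(20, 500, 100, 200, 8)
  expect_equal(r2$rate_per_1000_patient_days, 2 * r1$rate_per_1000_patient_days)
  expect_equal(r2$rate_per_100_patients, 2 * r1$rate_per_100_patients)
  z <- ade_rates(0, 500, 100, 200, 0)
  expect_equal(unlist(z), c(rate_per_1000_patient_days = 0,
                            rate_per_100_patients = 0,
                            rate_per_1000_drugs = 0, prevalence = 0))
  expect_error(ade_rates(1, 0, 10, 10, 1), "positive")
})

test_that("utility classification uses the 50/20 cut points", {
  expect_equal(classify_utility(c(66.67, 35, 18.52, 50, 20, NA)),
               c("high", "moderate", "low", "high", "moderate", NA))
  expect_equal(classify_utility(60, high = 70), "moderate")
})

test_that("the published counts bundle reproduces every printed metric", {
  rep <- build_report(counts = published_counts())
  s <- rep$summary
  expect_equal(s$overall_ppv, 30.30)
  expect_equal(s$sensitivity, 98.21)
  expect_equal(s$specificity, 72.57)
  expect_equal(s$youden, 0.71)
  expect_equal(s$false_negative_rate, 0.53)
  expect_equal(s$prevalence, 17.57)
  expect_equal(s$rate_per_1000_patient_days, 25.75)
  expect_equal(s$rate_per_100_patients, 22.84)
  expect_equal(s$rate_per_1000_drugs, 11.84)
  # per-trigger PPVs row-wise, and the utility classification agrees with
  # every labelled row
  pt <- rep$per_trigger
  expect_equal(pt$ppv[pt$trigger_id == "L1"], 66.67)
  expect_equal(pt$ppv[pt$trigger_id == "A1"], 18.52)
  expect_equal(pt$ppv[pt$trigger_id == "S5"], 9.80)
  labelled <- !is.na(pt$printed_utility)
  expect_equal(pt$utility[labelled], pt$printed_utility[labelled])
  expect_equal(sum(pt$positives), 472L)
  expect_equal(sum(pt$true_ades), 143L)
})

test_that("overall PPV is the weighted ratio, not the mean of per-trigger PPVs", {
  rep <- build_report(counts = published_counts())
  expect_equal(rep$overall_ppv,
               ppv(sum(rep$per_trigger$positives),
                   sum(rep$per_trigger$true_ades)))
  expect_false(isTRUE(all.equal(rep$overall_ppv,
                                mean(rep$per_trigger$ppv))))
})

test_that("a report built from a screened synthetic cohort matches its ledger", {
  sim <- simulate_cohort(sim_config(n_patients = 120), seed = 21)
  scr <- screen_cohort(sim$cohort)
  rep <- build_report(scr, sim$ades, sim$cohort)
  led <- sim$ledger

  # brute-force recomputation from the ledger
  exp_per_trigger <- led$expected_hits |>
    dplyr::count(trigger_id, name = "positives")
  expect_equal(dplyr::arrange(rep$per_trigger[, c("trigger_id", "positives")],
                              trigger_id),
               dplyr::arrange(exp_per_trigger, trigger_id))
  ade_pat <- unique(led$ades$patient_id)
  flag_pat <- unique(led$expected_hits$patient_id)
  n <- nrow(sim$cohort$patients)
  expect_equal(rep$confusion$tp, length(intersect(ade_pat, flag_pat)))
  expect_equal(rep$confusion$fp, length(setdiff(flag_pat, ade_pat)))
  expect_equal(rep$confusion$fn, length(setdiff(ade_pat, flag_pat)))
  expect_equal(rep$confusion$tn,
               n - length(union(ade_pat, flag_pat)))
  expect_equal(rep$summary$prevalence,
               round(100 * length(ade_pat) / n, 2), tolerance = 1e-8)
})

test_that("a clean cohort yields zero prevalence and full specificity", {
  sim <- simulate_cohort(sim_config(n_patients = 60, prevalence = 0,
                                    noise_rate = 0), seed = 5)
  scr <- screen_cohort(sim$cohort)
  expect_equal(nrow(scr$hits), 0)
  rep <- build_report(scr, sim$ades, sim$cohort)
  expect_equal(rep$summary$prevalence, 0)
  expect_equal(rep$summary$specificity, 100)
  expect_true(is.na(rep$summary$sensitivity))
})
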