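# rebuild individual-level data from an r x 2 contingency table
counts_to_data <- function(levels_, without, with_) {
  tibble::tibble(
    bin = factor(rep(rep(levels_, 2), c(without, with_)), levels = levels_),
    ade = rep(c(FALSE, TRUE), c(sum(without), sum(with_))))
}

test_that("chi-square is zero with p = 1 on proportional rows", {
  d <- counts_to_data(c("a", "b"), c(30, 60), c(10, 20))
  res <- univariate_chisq(d["bin"], d$ade)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("published contingency rows give the printed significance pattern", {
  uni <- published_counts()$univariate
  p_of <- function(cov) {
    rows <- uni[uni$covariate == cov, ]
    d <- counts_to_data(rows$level, rows$without_ade, rows$with_ade)
    univariate_chisq(d["bin"], d$ade)$p_value
  }
  expect_lt(p_of("los_days"), 0.0005)
  expect_lt(p_of("comorbidities"), 0.0005)
  expect_lt(p_of("positive_triggers"), 0.0005)
  expect_equal(p_of("sex"), 0.972, tolerance = 0.001)
  expect_gt(p_of("age"), 0.05)
  expect_gt(p_of("prior_hospitalizations"), 0.05)
  expect_gt(p_of("target_drug_classes"), 0.05)
})

test_that("empty covariate levels are dropped with a warning", {
  d <- counts_to_data(c("a", "b", "c"), c(30, 60, 0), c(10, 20, 0))
  expect_warning(res <- univariate_chisq(d["bin"], d$ade), "empty level")
  expect_equal(res$df, 1)
})

test_that("logistic regression recovers a known generating coefficient", {
  sim <- simulate_cohort(sim_config(n_patients = 4000, emission_prob = 0,
                                    noise_rate = 0), seed = 31)
  flag <- sim$cohort$patients$patient_id %in% sim$ades$patient_id
  binned <- bin_cohort(sim$cohort)
  fit <- fit_logistic(binned, flag)
  co <- tidy(fit)
  true_beta <- 0.922  # generating coefficient for > 9 comorbidities
  row <- co[co$term == "comorbidities>9", ]
  expect_lt(abs(row$beta - true_beta), 2 * row$std_error + 1e-9)
  expect_equal(row$odds_ratio, round(exp(row$beta), 3), tolerance = 1e-2)
  expect_true(glance(fit)$converged)
})

test_that("a single-category cohort reduces to an intercept-only model", {
  pts <- dplyr::bind_rows(lapply(1:40, function(i) {
    make_patient(paste0("p", i), age = 30, sex = "male",
                 admission = "2022-01-01", discharge = "2022-01-05",
                 comorbidities = 2L, prior = 1L)
  }))
  coh <- ade_cohort(pts)
  fit <- fit_logistic(bin_cohort(coh), rep(c(TRUE, FALSE), 20))
  expect_equal(tidy(fit)$term, "(Intercept)")
  expect_equal(tidy(fit)$odds_ratio, 1)  # 50/50 events
})

test_that("estimates are invariant to covariate column order", {
  sim <- simulate_cohort(sim_config(n_patients = 800, emission_prob = 0,
                                    noise_rate = 0), seed = 13)
  flag <- sim$cohort$patients$patient_id %in% sim$ades$patient_id
  binned <- bin_cohort(sim$cohort)
  f1 <- tidy(fit_logistic(binned, flag))
  f2 <- tidy(fit_logistic(binned[, c("patient_id", "comorbidities", "sex",
                                     "age", "los_days", "target_drug_classes",
                                     "prior_hospitalizations")], flag))
  f2 <- f2[match(f1$term, f2$term), ]
  expect_equal(f1$beta, f2$beta)
  expect_equal(f1$odds_ratio, f2$odds_ratio)
})

test_that("paired method comparison reproduces the published discordance", {
  cmp <- compare_detection_methods(table = published_counts()$paired_detection)
  expect_equal(unname(cmp$discordant), c(108, 0))
  expect_lt(cmp$mcnemar_exact_p, 1e-30)
  expect_lt(cmp$chisq_p, 0.01)
})

test_that("identical flags give p = 1 and the null holds for independent flags", {
  flags <- rep(c(TRUE, FALSE), 50)
  cmp <- compare_detection_methods(flags, flags)
  expect_equal(cmp$mcnemar_exact_p, 1)
  set.seed(61)
  rej <- replicate(200, {
    a <- runif(300) < 0.2
    b <- runif(300) < 0.2
    compare_detection_methods(a, b)$mcnemar_exact_p < 0.05
  })
  expect_lte(mean(rej), 0.1)  # exact test is conservative under the null
})
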