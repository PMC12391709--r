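#' Covariate binning schemes for risk-factor analysis
#'
#' The categorical binnings used for both the univariate chi-square screen
#' and the multivariable logistic regression: age in years
#' \{0-17, 18-40, 41-60, >60\}, length of stay in days
#' \{1-10, 11-20, 21-30, >30\}, previous hospitalizations \{1-3, 4-6, >6\},
#' targeted drug classes \{1, 2, 3, >3\}, comorbidities
#' \{1-3, 4-6, 7-9, >9\} and positive trigger count \{0-1, 2-4, >=5\}
#' (labelled `>4` in the regression scheme; numerically identical for integer
#' counts). The first level of each scheme is the reference category.
#'
#' @return Named list of schemes, each with `breaks` and `labels` for
#'   [cut()].
#' @export
covariate_binnings <- function() {
  list(
    age = list(breaks = c(-Inf, 17, 40, 60, Inf),
               labels = c("0-17", "18-40", "41-60", ">60")),
    los_days = list(breaks = c(-Inf, 10, 20, 30, Inf),
                    labels = c("1-10", "11-20", "21-30", ">30")),
    prior_hospitalizations = list(breaks = c(-Inf, 3, 6, Inf),
                                  labels = c("1-3", "4-6", ">6")),
    target_drug_classes = list(breaks = c(-Inf, 1, 2, 3, Inf),
                               labels = c("1", "2", "3", ">3")),
    comorbidities = list(breaks = c(-Inf, 3, 6, 9, Inf),
                         labels = c("1-3", "4-6", "7-9", ">9")),
    positive_triggers = list(breaks = c(-Inf, 1, 4, Inf),
                             labels = c("0-1", "2-4", ">=5")),
    positive_triggers_regression = list(breaks = c(-Inf, 1, 4, Inf),
                                        labels = c("0-1", "2-4", ">4")))
}

bin_one <- function(x, scheme) {
  cut(x, breaks = scheme$breaks, labels = scheme$labels, right = TRUE)
}

#' Bin a cohort's covariates into the standard categories
#'
#' Produces the factor design used by [univariate_chisq()] and
#' [fit_logistic()]. Fractional ages are floored to whole years before
#' binning (a 4-month-old falls in the 0-17 band).
#'
#' @param cohort An [ade_cohort()].
#' @param screening Optional [screen_cohort()] result; when given, the
#'   positive-trigger count covariate is included.
#' @param trigger_scheme `"positive_triggers"` (univariate labels, `>=5`) or
#'   `"positive_triggers_regression"` (`>4`).
#' @return Tibble of `patient_id` plus one factor per covariate, reference
#'   level first.
#' @export
bin_cohort <- function(cohort, screening = NULL,
                       trigger_scheme = c("positive_triggers",
                                          "positive_triggers_regression")) {
  stopifnot(inherits(cohort, "ade_cohort"))
  trigger_scheme <- match.arg(trigger_scheme)
  b <- covariate_binnings()
  los <- length_of_stay(cohort)
  out <- cohort$patients |>
    dplyr::left_join(los, by = "patient_id") |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      age = bin_one(floor(.data$age_at_admission), b$age),
      sex = factor(.data$sex, levels = c("male", "female")),
      los_days = bin_one(.data$los_days, b$los_days),
      prior_hospitalizations = bin_one(.data$n_prior_hospitalizations,
                                       b$prior_hospitalizations),
      target_drug_classes = bin_one(
        lengths(strsplit(.data$target_drug_classes, ";", fixed = TRUE)),
        b$target_drug_classes),
      comorbidities = bin_one(.data$n_comorbidities, b$comorbidities))
  if (!is.null(screening)) {
    stopifnot(inherits(screening, "ade_screening"))
    out <- out |>
      dplyr::left_join(dplyr::select(screening$patients, "patient_id",
                                     "n_triggers"), by = "patient_id") |>
      dplyr::mutate(positive_triggers = bin_one(.data$n_triggers,
                                                b[[trigger_scheme]]),
                    n_triggers = NULL)
  }
  out
}

#' Univariate chi-square screen over binned covariates
#'
#' Pearson chi-square (no continuity correction) on the r x 2 contingency
#' table of each binned covariate against ADE status. Covariate levels with
#' no observations are dropped with a warning, never silently.
#'
#' @param binned Data frame of factor covariates (e.g. from [bin_cohort()];
#'   a `patient_id` column is ignored).
#' @param ade Logical vector of ADE status, one per row of `binned`.
#' @return Tibble with `covariate`, `statistic`, `df`, `p_value`.
#' @examples
#' # proportional rows carry no association
#' x <- factor(rep(c("a", "b"), each = 20))
#' univariate_chisq(data.frame(g = x), ade = rep(c(TRUE, FALSE), 20))
#' @export
univariate_chisq <- function(binned, ade) {
  binned <- dplyr::select(as.data.frame(binned), -dplyr::any_of("patient_id"))
  assert_that(nrow(binned) == length(ade),
              "ade must have one value per row of binned")
  purrr::map_dfr(names(binned), function(cv) {
    x <- binned[[cv]]
    tab <- table(x, factor(ade, levels = c(FALSE, TRUE)))
    empty <- rownames(tab)[rowSums(tab) == 0]
    if (length(empty) > 0) {
      warn(paste0("covariate '", cv, "': empty level(s) dropped: ",
                  paste(empty, collapse = ", ")))
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    }
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tibble::tibble(covariate = cv,
                   statistic = unname(ct$statistic),
                   df = unname(ct$parameter),
                   p_value = unname(ct$p.value))
  })
}

nagelkerke_r2 <- function(fit) {
  n <- length(fit$y)
  ll_null <- fit$null.deviance / -2
  ll_full <- fit$deviance / -2
  cox_snell <- 1 - exp(2 * (ll_null - ll_full) / n)
  cox_snell / (1 - exp(2 * ll_null / n))
}

#' Multivariable binary logistic regression on binned covariates
#'
#' Maximum-likelihood logistic regression of ADE status on the categorical
#' covariates, dummy-coded against the reference (first) level of each
#' scheme. Reports per-level coefficients, odds ratios and Wald p-values,
#' plus Nagelkerke's pseudo-R-squared as the model fit statistic. Quasi- or
#' complete separation is detected from diverging coefficients and reported
#' with the offending terms rather than returned silently.
#'
#' @inheritParams univariate_chisq
#' @return An object of class `ade_logistic` with a [glm()] `fit`, a broom-
#'   style coefficient table, and a one-row fit summary; see
#'   [tidy.ade_logistic()].
#' @export
fit_logistic <- function(binned, ade) {
  df <- dplyr::select(as.data.frame(binned), -dplyr::any_of("patient_id"))
  assert_that(nrow(df) == length(ade),
              "ade must have one value per row of binned")
  assert_that(sum(ade) > 0 && sum(!ade) > 0,
              "logistic fit needs at least one event and one non-event")
  df <- droplevels(df)
  keep <- vapply(df, function(x) !is.factor(x) || nlevels(x) > 1, logical(1))
  df <- df[keep]
  dat <- cbind(df, .ade = as.logical(ade))
  fit <- suppressWarnings(glm(.ade ~ ., family = binomial(), data = dat))
  co <- summary(fit)$coefficients
  separated <- rownames(co)[abs(co[, "Estimate"]) > 15]
  if (length(separated) > 0) {
    warn(paste0("possible separation; diverging coefficient(s): ",
                paste(separated, collapse = ", ")))
  }
  coefs <- tibble::tibble(
    term = rownames(co),
    beta = round_half_up(co[, "Estimate"], 3),
    odds_ratio = round_half_up(exp(co[, "Estimate"]), 3),
    std_error = co[, "Std. Error"],
    p_value = co[, "Pr(>|z|)"])
  structure(
    list(fit = fit, coefficients = coefs,
         separation = if (length(separated)) separated else NULL,
         fit_stats = tibble::tibble(
           n = length(fit$y),
           nagelkerke_r2 = round_half_up(nagelkerke_r2(fit), 3),
           aic = fit$aic,
           converged = fit$converged)),
    class = "ade_logistic")
}

#' @export
print.ade_logistic <- function(x, ...) {
  cat("<ade_logistic> n =", x$fit_stats$n,
      "| Nagelkerke R2 =", x$fit_stats$nagelkerke_r2, "\n")
  print(x$coefficients)
  invisible(x)
}

#' Tidy a fitted ADE risk model
#'
#' @param x An `ade_logistic` from [fit_logistic()].
#' @param ... Unused.
#' @return `tidy()`: the per-level coefficient table (`term`, `beta`,
#'   `odds_ratio`, `std_error`, `p_value`). `glance()`: one-row fit summary.
#' @exportS3Method generics::tidy
tidy.ade_logistic <- function(x, ...) x$coefficients

#' @rdname tidy.ade_logistic
#' @exportS3Method generics::glance
glance.ade_logistic <- function(x, ...) x$fit_stats

#' Compare two detection methods on paired per-patient flags
#'
#' Cross-tabulates two ADE-detection flags for the same patients (e.g.
#' trigger-based active surveillance vs spontaneous reporting) and tests
#' whether the two methods detect at the same rate. The primary test is the
#' exact McNemar test on discordant pairs (two-sided exact binomial at 0.5);
#' the Pearson chi-square p-value on the same 2 x 2 table is also reported
#' for comparability with reports that quote a chi-square.
#'
#' @param method_a,method_b Logical detection flags, one pair per patient, or
#'   pass a ready 2 x 2 matrix (rows = method A yes/no, cols = method B
#'   yes/no) as `table`.
#' @param table Optional 2 x 2 matrix of paired counts; overrides the flag
#'   vectors.
#' @return An object of class `detection_comparison`: list with the paired
#'   `table`, `discordant` counts, `mcnemar_exact_p` and `chisq_p`.
#' @export
compare_detection_methods <- function(method_a = NULL, method_b = NULL,
                                      table = NULL) {
  if (is.null(table)) {
    assert_that(length(method_a) == length(method_b) && length(method_a) > 0,
                "both flags must be defined for every patient")
    assert_that(!anyNA(method_a) && !anyNA(method_b),
                "both flags must be defined for every patient")
    table <- base::table(factor(method_a, levels = c(TRUE, FALSE)),
                         factor(method_b, levels = c(TRUE, FALSE)))
    dimnames(table) <- list(method_a = c("ade", "no_ade"),
                            method_b = c("ade", "no_ade"))
    table <- unclass(table)
  }
  assert_that(all(dim(table) == c(2, 2)), "paired table must be 2 x 2")
  b <- table[1, 2]; cc <- table[2, 1]
  mcnemar_p <- if (b + cc == 0) 1 else binom.test(b, b + cc, 0.5)$p.value
  chisq_p <- tryCatch(
    suppressWarnings(chisq.test(table, correct = FALSE)$p.value),
    error = function(e) NA_real_)
  structure(list(table = table,
                 discordant = c(a_only = unname(b), b_only = unname(cc)),
                 mcnemar_exact_p = mcnemar_p,
                 chisq_p = chisq_p),
            class = "detection_comparison")
}

#' @export
print.detection_comparison <- function(x, ...) {
  print(x$table)
  cat("exact McNemar p =", format(x$mcnemar_exact_p, digits = 3),
      "| chi-square p =", format(x$chisq_p, digits = 3), "\n")
  invisible(x)
}
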