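#' Per-item Delphi consultation statistics
#'
#' For an experts x items score matrix on a bounded integer scale, computes
#' for each item the mean importance score Mj, the frequency of full marks Kj
#' (percent of experts awarding the scale maximum) and the coefficient of
#' variation Vj (sample standard deviation over mean). A zero mean makes Vj
#' undefined (`NA`).
#'
#' @param scores Numeric matrix or data frame, one row per expert, one column
#'   per item.
#' @param full_mark The scale maximum counting as a full mark; defaults to
#'   the maximum of the scale, taken as `max(scores)` when not supplied.
#' @return Tibble with `item`, `Mj`, `Kj`, `Vj`.
#' @examples
#' m <- rbind(c(5, 4), c(4, 3), c(3, 5))
#' item_stats(m, full_mark = 5)
#' @export
item_stats <- function(scores, full_mark = NULL) {
  scores <- as.matrix(scores)
  assert_that(nrow(scores) >= 2 && ncol(scores) >= 2,
              "need at least 2 experts and 2 items")
  full_mark <- full_mark %||% max(scores)
  items <- colnames(scores) %||% paste0("item_", seq_len(ncol(scores)))
  mj <- colMeans(scores)
  kj <- 100 * colMeans(scores == full_mark)
  vj <- apply(scores, 2, sd) / mj
  vj[mj == 0] <- NA_real_
  tibble::tibble(item = items, Mj = unname(mj), Kj = unname(kj),
                 Vj = unname(vj))
}

#' Delphi retention cut-off values
#'
#' Cut-offs are computed across items: for Mj and Kj the cut is
#' `mean - standard deviation` (items at or above the cut pass); for Vj the
#' cut is `mean + standard deviation` (items at or below pass). Sample
#' (n - 1) standard deviations are used throughout. Equality counts as
#' passing, so a degenerate panel in which all items tie leaves every item
#' exactly on its cut and retained.
#'
#' @param stats Per-item statistics from [item_stats()].
#' @return One-row tibble with `Mj_cut`, `Kj_cut`, `Vj_cut`.
#' @export
delphi_cutoffs <- function(stats) {
  assert_that(nrow(stats) >= 2, "cut-offs need at least 2 items")
  tibble::tibble(
    Mj_cut = mean(stats$Mj) - sd(stats$Mj),
    Kj_cut = mean(stats$Kj) - sd(stats$Kj),
    Vj_cut = mean(stats$Vj, na.rm = TRUE) + sd(stats$Vj, na.rm = TRUE))
}

#' Three-criteria item selection
#'
#' An item passes the Mj criterion when `Mj >= Mj_cut`, the Kj criterion when
#' `Kj >= Kj_cut` and the Vj criterion when `Vj <= Vj_cut`. Items failing all
#' three are dropped; items passing all three are retained; anything in
#' between goes to panel discussion.
#'
#' @param stats Per-item statistics from [item_stats()].
#' @param cutoffs Cut-offs from [delphi_cutoffs()] (or externally supplied).
#' @return `stats` with logical `pass_Mj`, `pass_Kj`, `pass_Vj` and a
#'   `decision` column in `{"retain", "discuss", "drop"}`.
#' @export
select_items <- function(stats, cutoffs = delphi_cutoffs(stats)) {
  out <- stats |>
    dplyr::mutate(
      pass_Mj = .data$Mj >= cutoffs$Mj_cut,
      pass_Kj = .data$Kj >= cutoffs$Kj_cut,
      pass_Vj = !is.na(.data$Vj) & .data$Vj <= cutoffs$Vj_cut)
  n_pass <- rowSums(out[c("pass_Mj", "pass_Kj", "pass_Vj")])
  out$decision <- dplyr::case_when(n_pass == 3 ~ "retain",
                                   n_pass == 0 ~ "drop",
                                   TRUE ~ "discuss")
  out
}

#' Kendall's coefficient of concordance
#'
#' Tie-corrected Kendall's W across experts' within-expert rankings of the
#' items: W = 12 S / (m^2 (n^3 - n) - m sum(T)), with S the sum of squared
#' deviations of item rank sums from their mean, m experts, n items, and T
#' the usual tie correction per expert. W is 1 for identical rankings and 0
#' when rank sums are indistinguishable (e.g. two experts with exactly
#' reversed rankings).
#'
#' @param scores Experts x items score matrix; ranks are taken within each
#'   expert with average ranks for ties.
#' @return W in `[0, 1]`.
#' @examples
#' kendall_w(rbind(c(1, 2, 3), c(1, 2, 3)))  # 1
#' kendall_w(rbind(c(1, 2, 3), c(3, 2, 1)))  # 0
#' @export
kendall_w <- function(scores) {
  scores <- as.matrix(scores)
  assert_that(nrow(scores) >= 2, "concordance needs at least 2 experts")
  assert_that(ncol(scores) >= 2, "concordance needs at least 2 items")
  m <- nrow(scores); n <- ncol(scores)
  ranks <- t(apply(scores, 1, rank))
  rsum <- colSums(ranks)
  s <- sum((rsum - mean(rsum))^2)
  tie_corr <- sum(apply(ranks, 1, function(r) {
    t <- table(r)
    sum(t^3 - t)
  }))
  denom <- m^2 * (n^3 - n) - m * tie_corr
  if (denom == 0) return(NA_real_)  # all experts rank all items tied
  12 * s / denom
}

#' Panel-level Delphi statistics
#'
#' The positive coefficient is the share of invited experts who responded.
#' Each expert's authority coefficient is Cr = (Ca + Cs) / 2, the mean of the
#' judgement-basis coefficient Ca and the familiarity coefficient Cs; the
#' panel Cr is reported as mean and sample SD across responding experts.
#' When Ca/Cs are not supplied the authority coefficient is omitted with a
#' warning.
#'
#' @param responded Logical vector, one per invited expert.
#' @param ca,cs Optional numeric judgement-basis and familiarity coefficients
#'   in `[0, 1]`, one per responding expert.
#' @param w Optional Kendall's W from [kendall_w()], carried through.
#' @return One-row tibble with `n_invited`, `n_responded`,
#'   `positive_coefficient` (percent), `cr_mean`, `cr_sd`, `kendall_w`.
#' @export
panel_stats <- function(responded, ca = NULL, cs = NULL, w = NA_real_) {
  responded <- as.logical(responded)
  out <- tibble::tibble(
    n_invited = length(responded),
    n_responded = sum(responded),
    positive_coefficient = as_pct(sum(responded), length(responded)),
    cr_mean = NA_real_, cr_sd = NA_real_, kendall_w = w)
  if (is.null(ca) || is.null(cs)) {
    warn("Ca/Cs not supplied; authority coefficient Cr omitted")
    return(out)
  }
  assert_that(length(ca) == length(cs),
              "ca and cs must have one value per responding expert")
  cr <- (ca + cs) / 2
  out$cr_mean <- mean(cr)
  out$cr_sd <- sd(cr)
  out
}
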