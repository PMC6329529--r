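#' Phase-weighted fraction of correct responses per condition
#'
#' For one session, orders each condition's trials by occurrence and scores
#' an action as correct when it matches the condition's instrumental policy.
#' The \code{"early"} phase weights within-condition position \code{k} by
#' \code{max(0, (19 - k) / 18)} - a ramp decreasing linearly to zero at the
#' middle of the condition's 36 trials; \code{"late"} averages positions
#' 19..36 unweighted; \code{"all"} averages all positions.  Missing
#' responses are excluded from numerator and denominator (they still occupy
#' their position in the ramp); a condition whose responses are all missing
#' yields \code{NA}.
#'
#' @param session One participant-session tibble.
#' @param phase \code{"early"}, \code{"late"} or \code{"all"}.
#' @return Named numeric vector of per-condition fractions (G2W, NG2W,
#'   G2AL, NG2AL).
#' @export
weighted_performance <- function(session, phase = c("all", "early", "late")) {
  phase <- match.arg(phase)
  out <- setNames(rep(NA_real_, 4), GNG_CONDITIONS)
  for (cond in GNG_CONDITIONS) {
    tr <- session[session$condition == cond, ]
    tr <- tr[order(tr$trial_index), ]
    n <- nrow(tr)
    if (!n) next
    k <- seq_len(n)
    w <- switch(phase,
                early = pmax(0, (19 - k) / 18),
                late = as.numeric(k >= 19),
                all = rep(1, n))
    resp <- tr$action != "missing"
    correct <- tr$action == GNG_CORRECT[[cond]]
    denom <- sum(w[resp])
    out[cond] <- if (denom > 0) sum(w[resp] * correct[resp]) / denom else NA_real_
  }
  out
}

#' Per-participant performance summary for a cohort
#'
#' @param cohort A validated cohort.
#' @param phases Which phases to compute.
#' @return Tibble with one row per participant x session x phase and one
#'   column per condition, plus \code{pav_bias} (the descriptive Pavlovian
#'   bias index, see \code{\link{pav_bias_index}}).
#' @export
performance_summary <- function(cohort, phases = c("early", "late", "all")) {
  sess <- dplyr::group_split(dplyr::group_by(cohort, .data$participant_id,
                                             .data$session))
  purrr::map_dfr(sess, function(s) {
    purrr::map_dfr(phases, function(ph) {
      fr <- weighted_performance(s, ph)
      tibble::tibble(participant_id = s$participant_id[1],
                     session = s$session[1], phase = ph,
                     G2W = fr[["G2W"]], NG2W = fr[["NG2W"]],
                     G2AL = fr[["G2AL"]], NG2AL = fr[["NG2AL"]],
                     pav_bias = pav_bias_index(fr))
    })
  })
}

#' Descriptive Pavlovian-bias index
#'
#' The congruency interaction in per-condition fractions correct:
#' \deqn{((G2W - NG2W) + (NG2AL - G2AL)) / 2.}
#' Positive values mean better performance in Pavlovian-congruent than
#' incongruent conditions.
#'
#' @param fractions Named vector (or one-row data frame) with entries
#'   \code{G2W}, \code{NG2W}, \code{G2AL}, \code{NG2AL}.
#' @return The index; \code{NA} (with all four conditions required) if any
#'   condition is undefined.
#' @examples
#' pav_bias_index(c(G2W = 0.9, NG2W = 0.5, G2AL = 0.6, NG2AL = 0.8))
#' @export
pav_bias_index <- function(fractions) {
  if (is.data.frame(fractions)) fractions <- unlist(fractions[1, GNG_CONDITIONS])
  f <- fractions[GNG_CONDITIONS]
  unname(((f[["G2W"]] - f[["NG2W"]]) + (f[["NG2AL"]] - f[["G2AL"]])) / 2)
}

#' Paired per-condition change between two matched waves
#'
#' For participants present in both cohorts, computes the median of
#' within-subject differences (wave B minus wave A) in fraction correct per
#' condition, with paired Wilcoxon signed-rank tests Bonferroni-corrected
#' for the four conditions.
#'
#' @param cohortA,cohortB Cohorts for the two waves, matched by
#'   \code{participant_id}.
#' @param phase Performance phase (see \code{\link{weighted_performance}}).
#' @return Tibble per condition: \code{median_diff}, \code{wilcoxon_p},
#'   \code{p_corrected} (x4, capped at 1), \code{n}.
#' @export
condition_change_tests <- function(cohortA, cohortB, phase = "all") {
  a <- performance_summary(cohortA, phase)
  b <- performance_summary(cohortB, phase)
  m <- dplyr::inner_join(a, b, by = "participant_id", suffix = c("_a", "_b"))
  if (!nrow(m)) abort("no overlapping participants between waves")
  if (nrow(m) < 10) abort("need at least 10 matched participants")
  purrr::map_dfr(GNG_CONDITIONS, function(cond) {
    d <- m[[paste0(cond, "_b")]] - m[[paste0(cond, "_a")]]
    d <- d[!is.na(d)]
    p <- if (all(d == 0)) 1 else suppressWarnings(wilcox.test(d, correct = TRUE))$p.value
    tibble::tibble(condition = cond, median_diff = median(d),
                   wilcoxon_p = p, p_corrected = min(1, p * 4), n = length(d))
  })
}

#' Pairwise cross-condition performance differences within a wave
#'
#' Median within-subject differences between pairs of conditions, with
#' Wilcoxon signed-rank tests Bonferroni-corrected by a factor of 8 (the
#' study-wide count of condition contrasts across the two phases).
#'
#' @param cohort A validated cohort (one wave).
#' @param phase Performance phase.
#' @param pairs Optional list of condition pairs; default all 6.
#' @return Tibble per pair: \code{median_diff} (first minus second
#'   condition), \code{wilcoxon_p}, \code{p_corrected}, \code{n}.
#' @export
cross_condition_tests <- function(cohort, phase = "all", pairs = NULL) {
  s <- performance_summary(cohort, phase)
  if (is.null(pairs))
    pairs <- utils::combn(GNG_CONDITIONS, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    d <- s[[pr[1]]] - s[[pr[2]]]
    d <- d[!is.na(d)]
    p <- if (all(d == 0)) 1 else suppressWarnings(wilcox.test(d, correct = TRUE))$p.value
    tibble::tibble(condition_1 = pr[1], condition_2 = pr[2],
                   median_diff = median(d), wilcoxon_p = p,
                   p_corrected = min(1, p * 8), n = length(d))
  })
}
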