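#' Data-reduction and awareness-criterion thresholds
#'
#' @param dsc_mean_change_min Exclude a participant from the sugar-factory
#'   analyses when their mean circular change from the randomized start
#'   value is strictly below this many grid steps (response bias).
#' @param asrt_block_accuracy_min Exclude a participant from the ASRT
#'   analyses when any block's pooled percent correct is strictly below
#'   this value (task negligence).
#' @param awareness_alpha One-sided alpha for the per-participant Welch test
#'   of confidence on on-target vs off-target trials.
#' @param questionnaire_points_min Points on the "positions of the previous
#'   trials" aspect at or above which a participant counts as aware of the
#'   sequence.
#' @return An object of class `"screening_config"`.
#' @export
screening_config <- function(dsc_mean_change_min = 2,
                             asrt_block_accuracy_min = 75,
                             awareness_alpha = 0.05,
                             questionnaire_points_min = 5) {
  stopifnot(dsc_mean_change_min > 0, asrt_block_accuracy_min > 0,
            awareness_alpha > 0, awareness_alpha < 1,
            questionnaire_points_min > 0)
  structure(
    list(dsc_mean_change_min = dsc_mean_change_min,
         asrt_block_accuracy_min = asrt_block_accuracy_min,
         awareness_alpha = awareness_alpha,
         questionnaire_points_min = questionnaire_points_min),
    class = "screening_config"
  )
}

#' Response-bias screen for the sugar-factory task
#'
#' On every recorded trial the change from the randomized start value of the
#' worker counter to the chosen value is measured in the direction of least
#' circular distance; under input chosen independently of the start value
#' the expected mean change is 3 grid steps. A participant whose mean change
#' is strictly below the threshold is excluded as responding without
#' adjusting.
#'
#' @param records DSC trial records for one participant (`start_workforce`,
#'   `chosen_workforce`, `trial` columns).
#' @param cfg A [dsc_config()].
#' @param scr A [screening_config()].
#' @return List with `mean_change` (grid steps) and `excluded` (logical).
#' @export
dsc_response_bias_screen <- function(records, cfg = dsc_config(),
                                     scr = screening_config()) {
  rec <- records[records$trial <= cfg$recorded_trials_per_block, , drop = FALSE]
  mc <- mean(circular_distance(rec$start_workforce, rec$chosen_workforce, cfg))
  list(mean_change = mc, excluded = mc < scr$dsc_mean_change_min)
}

#' Zero-on-target block screen
#'
#' The confidence analyses compare on-target with off-target trials, so a
#' participant with any block in which no trial was on target has an
#' undefined cell and is excluded case-wise from those analyses.
#'
#' @param block_scores [score_dsc()] rows for one participant.
#' @return Logical: excluded from the confidence analyses?
#' @export
zero_target_block_screen <- function(block_scores) {
  any(block_scores$trials_on_target == 0)
}

#' Accuracy screen for the ASRT task
#'
#' With four equiprobable positions the chance accuracy level is 25 percent;
#' responding far below the threshold in any block indicates negligence. A
#' participant is excluded when the pooled (both trial types, warm-up
#' excluded) percent correct of any block is strictly below the threshold.
#'
#' @param block_scores [score_asrt()] rows for one participant.
#' @param scr A [screening_config()].
#' @return Logical: excluded from the ASRT analyses?
#' @export
asrt_accuracy_screen <- function(block_scores, scr = screening_config()) {
  any(block_scores$pct_correct_all < scr$asrt_block_accuracy_min)
}

#' Per-participant Welch awareness test on confidence ratings
#'
#' One-sided Welch unequal-variances t-test of the alternative that mean
#' confidence on on-target trials exceeds mean confidence on off-target
#' trials, with Welch-Satterthwaite degrees of freedom. Trials are pooled
#' across blocks. A participant significantly more confident when on target
#' is classified as at least partly aware of the regularity. With fewer than
#' two ratings in either group, or zero variance in both groups, the test is
#' undefined and the participant is not classifiable (`aware = NA`) rather
#' than silently aware or unaware.
#'
#' @param confidences_on,confidences_off Ordinal confidence ratings for
#'   on-target and off-target trials.
#' @param scr A [screening_config()].
#' @return List with `t`, `df`, `p`, `aware`.
#' @export
welch_awareness_test <- function(confidences_on, confidences_off,
                                 scr = screening_config()) {
  not_classifiable <- list(t = NA_real_, df = NA_real_, p = NA_real_,
                           aware = NA)
  if (length(confidences_on) < 2L || length(confidences_off) < 2L) {
    return(not_classifiable)
  }
  if (stats::var(confidences_on) == 0 && stats::var(confidences_off) == 0) {
    return(not_classifiable)
  }
  tt <- stats::t.test(confidences_on, confidences_off,
                      alternative = "greater", var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, aware = tt$p.value < scr$awareness_alpha)
}

#' Questionnaire criterion for conscious sequence knowledge
#'
#' In the forced weighted-choice questionnaire 12 points are assigned across
#' four aspects of the task; a participant allocating at least
#' `questionnaire_points_min` points to the "positions of the previous
#' trials" aspect (aspect 1) counts as aware of the sequence.
#'
#' @param points Numeric vector of length 4, points per aspect in aspect
#'   order; must sum to 12.
#' @param scr A [screening_config()].
#' @return Logical: aware?
#' @export
questionnaire_awareness <- function(points, scr = screening_config()) {
  if (length(points) != 4L || sum(points) != 12) {
    stop("questionnaire points must be 4 aspects summing to 12")
  }
  points[1] >= scr$questionnaire_points_min
}

#' Run every screen and awareness criterion over a cohort
#'
#' Applies, per participant: the circular response-bias screen and the
#' zero-on-target block screen on the sugar-factory data, the accuracy
#' screen on the ASRT data, the Welch confidence-by-outcome awareness test
#' (pooled across blocks), and the questionnaire criterion.
#'
#' @param cohort An `implearn_cohort` (see [generate_cohort()]) or a
#'   `session_logs` object (see [read_session_logs()]).
#' @param dsc_cfg,asrt_cfg,scr Task and screening configurations.
#' @return Data frame with one row per participant: `participant_id`,
#'   `condition`, `mean_change`, `excluded_dsc_bias`,
#'   `excluded_dsc_zero_target_block`, `excluded_asrt_accuracy`, `welch_t`,
#'   `welch_df`, `welch_p`, `aware_dsc`, `aware_asrt`.
#' @export
screen_cohort <- function(cohort, dsc_cfg = dsc_config(),
                          asrt_cfg = asrt_config(),
                          scr = screening_config()) {
  logs <- as_session_logs(cohort)
  ids <- unique(logs$participants$participant_id)
  out <- lapply(ids, function(id) {
    dsc <- logs$dsc[logs$dsc$participant_id == id, , drop = FALSE]
    asrt <- logs$asrt[logs$asrt$participant_id == id, , drop = FALSE]
    qn <- logs$questionnaire[logs$questionnaire$participant_id == id, ,
                             drop = FALSE]
    bias <- dsc_response_bias_screen(dsc, dsc_cfg, scr)
    dsc_sc <- score_dsc(dsc, dsc_cfg)
    zero <- zero_target_block_screen(dsc_sc)
    asrt_sc <- score_asrt(asrt)
    acc <- asrt_accuracy_screen(asrt_sc, scr)
    rec <- dsc[dsc$trial <= dsc_cfg$recorded_trials_per_block, , drop = FALSE]
    w <- welch_awareness_test(rec$confidence[rec$on_target],
                              rec$confidence[!rec$on_target], scr)
    qn <- qn[order(qn$aspect_id), ]
    aw_q <- questionnaire_awareness(qn$points, scr)
    data.frame(
      participant_id = id,
      condition = logs$participants$condition[
        logs$participants$participant_id == id][1],
      mean_change = bias$mean_change,
      excluded_dsc_bias = bias$excluded,
      excluded_dsc_zero_target_block = zero,
      excluded_asrt_accuracy = acc,
      welch_t = w$t, welch_df = w$df, welch_p = w$p,
      aware_dsc = w$aware,
      aware_asrt = aw_q
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
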