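#' Seizure annotation timeline
#'
#' Physician-style annotations: non-overlapping, sorted `[onset, offset)`
#' seizure intervals within a record of known duration.
#'
#' @param onset,offset Seizure interval bounds, seconds.
#' @param duration Record duration, seconds.
#' @return A tibble of class `seizure_timeline` with columns `onset`,
#'   `offset` and a `duration` attribute.
#' @export
seizure_timeline <- function(onset = numeric(), offset = numeric(),
                             duration) {
  if (length(onset) != length(offset)) {
    rlang::abort("`onset` and `offset` must have equal length.")
  }
  if (duration <= 0) rlang::abort("`duration` must be positive.")
  if (length(onset)) {
    ord <- order(onset)
    onset <- onset[ord]
    offset <- offset[ord]
    if (any(offset <= onset)) {
      rlang::abort("Each seizure must have offset > onset.")
    }
    if (any(onset < 0) || any(offset > duration)) {
      rlang::abort("Seizures must lie within (0, duration].")
    }
    if (length(onset) > 1 && any(onset[-1] < offset[-length(offset)])) {
      rlang::abort("Seizure intervals must not overlap.")
    }
  }
  out <- tibble::tibble(onset = as.numeric(onset),
                        offset = as.numeric(offset))
  attr(out, "duration") <- as.numeric(duration)
  class(out) <- c("seizure_timeline", class(out))
  out
}

#' Label windows with their ictal state
#'
#' Each window is labeled by its start time. The pre-ictal period of a
#' seizure is `[onset - pre_dur, onset)` and the post-ictal period
#' `[offset, offset + post_dur)`; when periods overlap, precedence is
#' ictal > pre-ictal > post-ictal > inter-ictal, so the approach to an
#' imminent seizure always dominates the tail of the previous one.
#'
#' @param windows Data frame with a `t_start` column (e.g. from
#'   [make_windows()] or [extract_features()]).
#' @param tl A [seizure_timeline()].
#' @param pre_dur,post_dur Pre-/post-ictal durations, seconds (1 h each by
#'   default).
#' @return `windows` with a `state` factor column (levels `inter_ictal`,
#'   `pre_ictal`, `ictal`, `post_ictal`).
#' @export
label_timeline <- function(windows, tl, pre_dur = 3600, post_dur = 3600) {
  stopifnot(inherits(tl, "seizure_timeline"))
  if (pre_dur < 0 || post_dur < 0) {
    rlang::abort("`pre_dur` and `post_dur` must be >= 0.")
  }
  t <- windows$t_start
  state <- rep("inter_ictal", length(t))
  for (i in seq_len(nrow(tl))) { # ascending precedence: post, pre, ictal
    state[t >= tl$offset[i] & t < tl$offset[i] + post_dur] <- "post_ictal"
  }
  for (i in seq_len(nrow(tl))) {
    state[t >= tl$onset[i] - pre_dur & t < tl$onset[i]] <- "pre_ictal"
  }
  for (i in seq_len(nrow(tl))) {
    state[t >= tl$onset[i] & t < tl$offset[i]] <- "ictal"
  }
  windows$state <- factor(state, levels = c("inter_ictal", "pre_ictal",
                                            "ictal", "post_ictal"))
  windows
}

#' Turn per-window predictions into alarms
#'
#' An alarm is raised on any window classified as the positive (pre-ictal)
#' class; with `m > 1`, only windows inside a run of at least `m`
#' consecutive positive windows raise alarms (simple debouncing).
#'
#' @param windows Data frame with a `.pred_class` column (from `predict()`).
#' @param positive Positive class label.
#' @param m Minimum consecutive positive windows.
#' @return `windows` with a logical `alarm` column.
#' @export
raise_alarms <- function(windows, positive = "pre_ictal", m = 1L) {
  pos <- windows$.pred_class == positive
  if (m > 1L) {
    r <- rle(pos)
    r$values <- r$values & r$lengths >= m
    pos <- inverse.rle(r)
  }
  windows$alarm <- pos
  windows
}

#' Alarm-based seizure prediction sensitivity
#'
#' A seizure counts as predicted when at least one alarm window starts in
#' its pre-ictal period; sensitivity is predicted / (predicted + missed).
#'
#' @param windows Data frame with `t_start` and logical `alarm` columns.
#' @param tl A [seizure_timeline()].
#' @param pre_dur Pre-ictal duration, seconds.
#' @return Sensitivity in `[0, 1]`; `NA` when the timeline has no seizures.
#' @export
alarm_sensitivity <- function(windows, tl, pre_dur = 3600) {
  counts <- seizure_prediction_counts(windows, tl, pre_dur)
  if (counts$n_seizures == 0) return(NA_real_)
  counts$predicted / counts$n_seizures
}

seizure_prediction_counts <- function(windows, tl, pre_dur = 3600) {
  stopifnot(inherits(tl, "seizure_timeline"))
  if (!"alarm" %in% names(windows)) {
    rlang::abort("`windows` needs a logical `alarm` column.")
  }
  t <- windows$t_start
  predicted <- 0L
  for (i in seq_len(nrow(tl))) {
    in_pre <- t >= tl$onset[i] - pre_dur & t < tl$onset[i]
    if (any(windows$alarm & in_pre)) predicted <- predicted + 1L
  }
  list(n_seizures = nrow(tl), predicted = predicted,
       missed = nrow(tl) - predicted)
}

#' Window-based specificity over inter-ictal time
#'
#' True negatives / (true negatives + false positives), counted over
#' inter-ictal windows only; ictal and post-ictal windows are irrelevant to
#' the wake-up decision and are excluded. This equals the fraction of
#' no-risk time the digital back-end stays idle.
#'
#' @param windows Data frame with `state` and logical `alarm` columns.
#' @return Specificity in `[0, 1]`; `NA` without inter-ictal windows.
#' @export
window_specificity <- function(windows) {
  if (!all(c("state", "alarm") %in% names(windows))) {
    rlang::abort("`windows` needs `state` and `alarm` columns.")
  }
  inter <- windows$state == "inter_ictal"
  if (!any(inter)) return(NA_real_)
  mean(!windows$alarm[inter])
}

#' Duty-cycled system power model
#'
#' The digital back-end runs during pre-ictal time and during inter-ictal
#' false alarms: `duty = pre_frac + (1 - pre_frac) * (1 - specificity)`;
#' total power is the always-on analog front-end plus the duty-cycled
#' digital engine.
#'
#' @param p_analog Analog front-end power, watts (180 nW by default).
#' @param p_digital Digital back-end power, watts.
#' @param specificity Front-end specificity in `[0, 1]`.
#' @param pre_frac Fraction of time spent in pre-ictal periods.
#' @return Tibble with `duty_cycle` and `power` (watts).
#' @export
system_power <- function(p_analog = 180e-9, p_digital = 3.07e-6,
                         specificity, pre_frac = 0) {
  if (any(specificity < 0 | specificity > 1) ||
      any(pre_frac < 0 | pre_frac > 1)) {
    rlang::abort("`specificity` and `pre_frac` must lie in [0, 1].")
  }
  duty <- pre_frac + (1 - pre_frac) * (1 - specificity)
  tibble::tibble(specificity = specificity, duty_cycle = duty,
                 power = p_analog + duty * p_digital)
}

#' Full evaluation report
#'
#' Combines alarm-based sensitivity, window specificity, the prediction and
#' window counts, and the duty-cycled power estimate into one object.
#'
#' @param windows Data frame with `t_start`, `state` and `alarm` columns.
#' @param tl A [seizure_timeline()].
#' @param pre_dur Pre-ictal duration, seconds.
#' @param p_analog,p_digital Power constants, watts.
#' @return An object of class `eval_report`.
#' @export
eval_report <- function(windows, tl, pre_dur = 3600,
                        p_analog = 180e-9, p_digital = 3.07e-6) {
  counts <- seizure_prediction_counts(windows, tl, pre_dur)
  inter <- windows$state == "inter_ictal"
  tn <- sum(inter & !windows$alarm)
  fp <- sum(inter & windows$alarm)
  sens <- if (counts$n_seizures == 0) NA_real_ else
    counts$predicted / counts$n_seizures
  spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  pre_frac <- mean(windows$state == "pre_ictal")
  pw <- if (is.na(spec)) {
    tibble::tibble(specificity = NA_real_, duty_cycle = NA_real_,
                   power = NA_real_)
  } else {
    system_power(p_analog, p_digital, spec, pre_frac)
  }
  structure(list(sensitivity = sens, specificity = spec,
                 predicted_seizures = counts$predicted,
                 missed_seizures = counts$missed,
                 true_negatives = tn, false_positives = fp,
                 pre_ictal_fraction = pre_frac,
                 duty_cycle = pw$duty_cycle, system_power = pw$power,
                 p_analog = p_analog, p_digital = p_digital),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  sensitivity: %s (%d predicted / %d missed)\n",
              if (is.na(x$sensitivity)) "NA" else
                sprintf("%.1f%%", 100 * x$sensitivity),
              x$predicted_seizures, x$missed_seizures))
  cat(sprintf("  specificity: %s (TN %d / FP %d)\n",
              if (is.na(x$specificity)) "NA" else
                sprintf("%.2f%%", 100 * x$specificity),
              x$true_negatives, x$false_positives))
  cat(sprintf("  duty cycle: %s, system power: %s\n",
              if (is.na(x$duty_cycle)) "NA" else
                sprintf("%.1f%%", 100 * x$duty_cycle),
              if (is.na(x$system_power)) "NA" else
                sprintf("%.3g W", x$system_power)))
  invisible(x)
}

#' @rdname eval_report
#' @param x An `eval_report`.
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(
    sensitivity = x$sensitivity, specificity = x$specificity,
    predicted_seizures = x$predicted_seizures,
    missed_seizures = x$missed_seizures,
    true_negatives = x$true_negatives, false_positives = x$false_positives,
    pre_ictal_fraction = x$pre_ictal_fraction,
    duty_cycle = x$duty_cycle, system_power = x$system_power
  )
}
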