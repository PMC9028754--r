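#' Architecture, operation and power accounting
#'
#' Desk accounting for a classifier architecture: controlling-parameter and
#' per-classification operation counts, energy per classification and per
#' operation at the given power and throughput, and a duty-cycled system
#' power sweep against front-end specificity.
#'
#' @param arch An [architecture_spec()].
#' @param p_analog Analog classifier power, watts (180 nW default).
#' @param rate Classification throughput, 1/s (166 kHz default).
#' @param p_digital Digital back-end power, watts.
#' @param pre_frac Pre-ictal time fraction used in the sweep.
#' @param spec_grid Specificity grid for the sweep.
#' @return List of class `accounting_report` with scalar accounting fields
#'   and a `power_sweep` tibble.
#' @export
accounting_report <- function(arch, p_analog = 180e-9, rate = 166e3,
                              p_digital = 3.07e-6, pre_frac = 0.05,
                              spec_grid = seq(0, 1, by = 0.05)) {
  n_par <- count_parameters(arch)
  n_ops <- count_operations(arch)
  e_class <- p_analog / rate
  structure(list(
    arch = arch,
    n_parameters = n_par,
    n_operations = n_ops,
    energy_per_classification = e_class,
    energy_per_operation = e_class / n_ops,
    power_sweep = system_power(p_analog, p_digital, spec_grid, pre_frac)
  ), class = "accounting_report")
}

#' @export
print.accounting_report <- function(x, ...) {
  a <- x$arch
  cat(sprintf("<accounting_report> C=%d K=%d N=%d\n",
              a$n_classes, a$n_clusters, a$n_dims))
  cat(sprintf("  parameters: %d, operations/classification: %d\n",
              x$n_parameters, x$n_operations))
  cat(sprintf("  energy: %.3g J/classification, %.3g J/operation\n",
              x$energy_per_classification, x$energy_per_operation))
  invisible(x)
}

#' @rdname accounting_report
#' @param x An `accounting_report`.
#' @param ... Unused.
#' @export
tidy.accounting_report <- function(x, ...) x$power_sweep

#' @rdname accounting_report
#' @export
glance.accounting_report <- function(x, ...) {
  tibble::tibble(
    n_classes = x$arch$n_classes, n_clusters = x$arch$n_clusters,
    n_dims = x$arch$n_dims, n_parameters = x$n_parameters,
    n_operations = x$n_operations,
    energy_per_classification = x$energy_per_classification,
    energy_per_operation = x$energy_per_operation
  )
}

#' Repeated software training iterations
#'
#' Re-trains the classifier under different EM seeds on the training split
#' and scores each candidate's specificity (and sensitivity) on the test
#' split, summarizing the spread of the software baseline across restarts.
#'
#' @param windows Labeled feature windows carrying a `.set` column (see
#'   [split_windows()]).
#' @param tl The matching [seizure_timeline()].
#' @param K Clusters per class.
#' @param n_iter Number of training iterations.
#' @param seed Base seed; iteration `i` trains with `seed + 100 * i`.
#' @param pre_dur Pre-ictal duration, seconds.
#' @return Tibble with one row per iteration: `iteration`, `seed`,
#'   `loglik`, `specificity`, `sensitivity`.
#' @export
training_iterations <- function(windows, tl, K = 2, n_iter = 20, seed = 1L,
                                pre_dur = 3600) {
  train <- windows[windows$.set == "train" &
                     windows$state %in% c("pre_ictal", "inter_ictal"), ]
  test <- windows[windows$.set == "test", ]
  purrr::map_dfr(seq_len(n_iter), function(i) {
    s <- seed + 100L * i
    clf <- fit_gmm_classifier(train, K = K, seed = s)
    scored <- raise_alarms(dplyr::bind_cols(test, predict(clf, test)))
    tibble::tibble(
      iteration = i, seed = s,
      loglik = glance(clf)$loglik,
      specificity = window_specificity(scored),
      sensitivity = alarm_sensitivity(scored, tl, pre_dur)
    )
  })
}

#' Evaluate a classifier over labeled feature windows
#'
#' Runs ideal or analog inference over the (test) windows, raises alarms on
#' pre-ictal predictions, and assembles the full [eval_report()].
#'
#' @param clf A [gmm_classifier()].
#' @param windows Labeled feature windows (`t_start`, `state`, features).
#' @param tl The matching [seizure_timeline()].
#' @param mode `"ideal"` (software likelihoods) or `"analog"` (behavioral
#'   circuit model mapped from `clf`).
#' @param pre_dur Pre-ictal duration, seconds.
#' @param m Alarm debouncing length, windows.
#' @param analog_cfg Optional pre-built [map_gmm_to_analog()] result; when
#'   omitted in analog mode the mapping is derived from `windows`.
#' @param ... Passed to [map_gmm_to_analog()].
#' @return An [eval_report()]; the scored window tibble is attached as
#'   attribute `"windows"`.
#' @export
evaluate_windows <- function(clf, windows, tl, mode = c("ideal", "analog"),
                             pre_dur = 3600, m = 1L, analog_cfg = NULL,
                             ...) {
  mode <- match.arg(mode)
  model <- if (mode == "ideal") {
    clf
  } else {
    analog_cfg %||% map_gmm_to_analog(clf, scaler = feature_scaler(windows),
                                      ...)
  }
  scored <- raise_alarms(dplyr::bind_cols(windows, predict(model, windows)),
                         m = m)
  rep <- eval_report(scored, tl, pre_dur = pre_dur)
  attr(rep, "windows") <- scored
  rep
}

#' End-to-end synthetic experiment
#'
#' Generates a timeline and labeled feature windows, splits them, trains the
#' two-class GMM classifier on the training half (pre-ictal vs inter-ictal
#' windows only), and evaluates on the held-out half.
#'
#' @param seed Master seed for the whole experiment.
#' @param duration Record duration, seconds.
#' @param n_seizures Seizure count.
#' @param truth Ground-truth feature mixtures.
#' @param K Clusters per class.
#' @param mode `"ideal"` or `"analog"`.
#' @param pre_dur,post_dur Labeling durations, seconds.
#' @param win_len,stride Window geometry, seconds.
#' @param min_gap Minimum pre-seizure gap, seconds.
#' @param ... Passed to [evaluate_windows()].
#' @return List with `timeline`, `windows`, `classifier` and `report`.
#' @export
run_experiment <- function(seed = 1L, duration = 86400, n_seizures = 4,
                           truth = default_feature_truth(), K = 2,
                           mode = "ideal", pre_dur = 3600, post_dur = 3600,
                           win_len = 4, stride = 2, min_gap = 9000, ...) {
  tl <- generate_timeline(duration = duration, n_seizures = n_seizures,
                          min_gap = min_gap, seed = seed)
  windows <- simulate_feature_scenario(tl, truth = truth,
                                       win_len = win_len, stride = stride,
                                       pre_dur = pre_dur,
                                       post_dur = post_dur,
                                       seed = seed + 1L)
  windows <- split_windows(windows, prop = 0.5, seed = seed + 2L)
  train <- windows[windows$.set == "train" &
                     windows$state %in% c("pre_ictal", "inter_ictal"), ]
  clf <- fit_gmm_classifier(train, K = K, seed = seed + 3L)
  test <- windows[windows$.set == "test", ]
  rep <- evaluate_windows(clf, test, tl, mode = mode, pre_dur = pre_dur, ...)
  list(timeline = tl, windows = windows, classifier = clf, report = rep)
}
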