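windows_at <- function(t_start) tibble::tibble(t_start = t_start)

test_that("timeline construction validates its invariants", {
  expect_error(seizure_timeline(100, 50, duration = 1000), "offset > onset")
  expect_error(seizure_timeline(c(10, 50), c(60, 90), duration = 1000),
               "overlap")
  expect_error(seizure_timeline(10, 2000, duration = 1000), "within")
  tl <- seizure_timeline(c(500, 100), c(550, 150), duration = 1000)
  expect_equal(tl$onset, c(100, 500)) # sorted on construction
})

test_that("windows are labeled by start time with the stated precedence", {
  tl <- seizure_timeline(7200, 7260, duration = 20000)
  w <- label_timeline(windows_at(c(3650, 7230, 7300, 100, 12000)), tl)
  expect_equal(as.character(w$state),
               c("pre_ictal", "ictal", "post_ictal", "inter_ictal",
                 "inter_ictal"))
  # no seizures: everything inter-ictal
  w0 <- label_timeline(windows_at(c(0, 500, 900)),
                       seizure_timeline(duration = 1000))
  expect_true(all(w0$state == "inter_ictal"))
  # two seizures 30 min apart: the gap is pre-ictal of the second
  tl2 <- seizure_timeline(c(7200, 9060), c(7260, 9120), duration = 20000)
  gap <- label_timeline(windows_at(c(7500, 8000, 9000)), tl2)
  expect_true(all(gap$state == "pre_ictal"))
})

test_that("boundary windows fall on the half-open side", {
  tl <- seizure_timeline(7200, 7260, duration = 20000)
  w <- label_timeline(windows_at(c(7200 - 3600, 7200, 7260,
                                   7260 + 3600)), tl)
  expect_equal(as.character(w$state),
               c("pre_ictal", "ictal", "post_ictal", "inter_ictal"))
})

test_that("alarm sensitivity counts seizures with a pre-ictal alarm", {
  tl <- seizure_timeline(c(7200, 14400, 18000), c(7260, 14460, 18060),
                         duration = 30000)
  t <- seq(0, 29996, by = 4)
  w <- label_timeline(windows_at(t), tl)
  # alarms only inside the first seizure's pre-ictal hour
  w$alarm <- t >= 4000 & t < 4100
  expect_equal(alarm_sensitivity(w, tl), 1 / 3)
  # alarms everywhere pre-ictal: full sensitivity
  w$alarm <- w$state == "pre_ictal"
  expect_equal(alarm_sensitivity(w, tl), 1)
  # no seizures: undefined
  w0 <- windows_at(t)
  w0$alarm <- FALSE
  expect_true(is.na(alarm_sensitivity(w0,
                                      seizure_timeline(duration = 30000))))
})

test_that("alarm sensitivity equals a brute-force per-seizure scan", {
  set.seed(23)
  tl <- seizure_timeline(c(5000, 12000, 20000, 26000),
                         c(5060, 12060, 20060, 26060), duration = 30000)
  t <- seq(0, 29996, by = 4)
  for (i in 1:20) {
    w <- windows_at(t)
    w$alarm <- runif(length(t)) < 0.002
    brute <- mean(vapply(seq_len(nrow(tl)), function(s) {
      any(w$alarm[t >= tl$onset[s] - 3600 & t < tl$onset[s]])
    }, logical(1)))
    expect_equal(alarm_sensitivity(w, tl), brute)
  }
})

test_that("specificity is the inter-ictal true-negative fraction", {
  w <- tibble::tibble(
    state = factor(rep("inter_ictal", 100)),
    alarm = c(rep(TRUE, 31), rep(FALSE, 69))
  )
  expect_equal(window_specificity(w), 0.69)
  w$alarm <- FALSE
  expect_equal(window_specificity(w), 1)
  # ictal / post-ictal windows are excluded from the count
  w2 <- tibble::tibble(
    state = factor(c(rep("inter_ictal", 10), rep("ictal", 5),
                     rep("post_ictal", 5))),
    alarm = c(rep(FALSE, 10), rep(TRUE, 10))
  )
  expect_equal(window_specificity(w2), 1)
  # no inter-ictal windows: undefined
  w3 <- tibble::tibble(state = factor(rep("ictal", 4)), alarm = FALSE)
  expect_true(is.na(window_specificity(w3)))
  # random patterns vs a direct count
  set.seed(9)
  for (i in 1:20) {
    st <- sample(c("inter_ictal", "pre_ictal", "post_ictal"), 200,
                 replace = TRUE)
    al <- runif(200) < 0.3
    w4 <- tibble::tibble(state = factor(st), alarm = al)
    inter <- st == "inter_ictal"
    expect_equal(window_specificity(w4),
                 sum(inter & !al) / sum(inter))
  }
})

test_that("specificity never rises when inter-ictal alarms are added", {
  set.seed(41)
  st <- factor(sample(c("inter_ictal", "pre_ictal"), 300, replace = TRUE,
                      prob = c(0.8, 0.2)))
  alarm <- runif(300) < 0.1
  w <- tibble::tibble(state = st, alarm = alarm)
  s0 <- window_specificity(w)
  idle <- which(st == "inter_ictal" & !alarm)
  w$alarm[sample(idle, 10)] <- TRUE
  expect_lt(window_specificity(w), s0)
})

test_that("metrics are invariant to stride refinement", {
  # period boundaries are multiples of both strides, so refinement
  # preserves alarm/label content at period granularity
  tl <- seizure_timeline(7200, 7264, duration = 14400)
  coarse_t <- seq(0, 14392, by = 8)
  w <- label_timeline(windows_at(coarse_t), tl)
  set.seed(2)
  w$alarm <- runif(nrow(w)) < 0.05
  # split every window into two half-stride windows carrying the same alarm
  fine <- tibble::tibble(t_start = rep(coarse_t, each = 2) + c(0, 4))
  fine <- label_timeline(fine, tl)
  fine$alarm <- rep(w$alarm, each = 2)
  expect_equal(alarm_sensitivity(fine, tl), alarm_sensitivity(w, tl))
  expect_equal(window_specificity(fine), window_specificity(w))
})

test_that("system power follows the duty-cycle model", {
  # perfect specificity, no pre-ictal time: analog power only
  p <- system_power(180e-9, 3.07e-6, specificity = 1, pre_frac = 0)
  expect_equal(p$power, 180e-9)
  expect_equal(p$duty_cycle, 0)
  # zero specificity: always-on digital engine
  p0 <- system_power(180e-9, 3.07e-6, specificity = 0, pre_frac = 0.2)
  expect_equal(p0$duty_cycle, 1)
  expect_equal(p0$power, 180e-9 + 3.07e-6)
  # the worked mid-range point by direct arithmetic
  p69 <- system_power(180e-9, 3.07e-6, specificity = 0.69, pre_frac = 0.05)
  duty <- 0.05 + 0.95 * 0.31
  expect_equal(p69$duty_cycle, duty)
  expect_equal(p69$power, 180e-9 + duty * 3.07e-6)
  # monotone decreasing in specificity
  sweep <- system_power(specificity = seq(0, 1, by = 0.1), pre_frac = 0.05)
  expect_true(all(diff(sweep$power) < 0))
  expect_error(system_power(specificity = 1.2), "0, 1")
})

test_that("eval_report assembles consistent counts and rates", {
  tl <- seizure_timeline(c(7200, 12000), c(7260, 12060), duration = 18000)
  t <- seq(0, 17996, by = 4)
  w <- label_timeline(windows_at(t), tl)
  set.seed(5)
  w$alarm <- w$state == "pre_ictal" | runif(nrow(w)) < 0.02
  rep <- eval_report(w, tl)
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$specificity,
               rep$true_negatives /
                 (rep$true_negatives + rep$false_positives))
  expect_equal(rep$predicted_seizures + rep$missed_seizures, 2)
  td <- tidy(rep)
  expect_equal(nrow(td), 1)
  expect_equal(td$specificity, rep$specificity)
  expect_equal(td$system_power,
               system_power(specificity = rep$specificity,
                            pre_frac = rep$pre_ictal_fraction)$power)
})

test_that("alarm debouncing requires m consecutive positive windows", {
  w <- tibble::tibble(
    .pred_class = c("pre_ictal", "inter_ictal", "pre_ictal", "pre_ictal",
                    "pre_ictal", "inter_ictal")
  )
  expect_equal(raise_alarms(w, m = 1)$alarm,
               c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(raise_alarms(w, m = 3)$alarm,
               c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(raise_alarms(w, m = 4)$alarm, rep(FALSE, 6))
})

test_that("timeline CSV round-trips", {
  tl <- seizure_timeline(c(100, 900), c(160, 960), duration = 2000)
  path <- withr::local_tempfile(fileext = ".csv")
  write_timeline_csv(tl, path)
  back <- read_timeline_csv(path)
  expect_equal(back$onset, tl$onset)
  expect_equal(back$offset, tl$offset)
  expect_equal(attr(back, "duration"), 2000)
})
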