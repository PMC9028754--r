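#' Ground-truth feature mixtures for the default synthetic scenario
#'
#' Two 4-D, two-cluster mixtures over the classifier's feature space
#' (peak-to-peak amplitude in microvolts; alpha, lower-gamma and upper-gamma
#' energy fractions). The pre-ictal class shifts power from alpha into the
#' gamma bands and raises the amplitude; every dimension separates the
#' nearest cross-class cluster means by at least four standard deviations,
#' emulating a well-separated recording.
#'
#' @return Named list with `pre_ictal` and `inter_ictal` [class_gmm()]s and
#'   a `feature_names` attribute.
#' @export
default_feature_truth <- function() {
  v <- c(100, 2.5e-3, 2.5e-3, 2.5e-3) # sd: 10 uV, 0.05 per fraction
  inter <- class_gmm(list(
    gaussian_component(c(55, 0.55, 0.08, 0.04), v, 0.6),
    gaussian_component(c(70, 0.62, 0.12, 0.08), v, 0.4)
  ), label = "inter_ictal")
  pre <- class_gmm(list(
    gaussian_component(c(115, 0.25, 0.32, 0.28), v, 0.5),
    gaussian_component(c(130, 0.32, 0.40, 0.33), v, 0.5)
  ), label = "pre_ictal")
  out <- list(pre_ictal = pre, inter_ictal = inter)
  attr(out, "feature_names") <- eeg_feature_names()
  out
}

# n i.i.d. draws from one mixture; component choice then per-dim normals.
sample_class_gmm <- function(gmm, n, feature_names = NULL) {
  m <- gmm_matrices(gmm)
  K <- nrow(m$mean)
  comp <- sample.int(K, n, replace = TRUE, prob = m$weight)
  X <- m$mean[comp, , drop = FALSE] +
    matrix(stats::rnorm(n * ncol(m$mean)), n) *
      sqrt(m$var[comp, , drop = FALSE])
  colnames(X) <- feature_names %||% paste0("x", seq_len(ncol(X)))
  tibble::as_tibble(X)
}

#' Draw labeled feature vectors from ground-truth mixtures
#'
#' @param truth Named list of [class_gmm()]s (one per class), e.g.
#'   [default_feature_truth()].
#' @param n_per_class Draws per class (recycled over classes).
#' @param seed Integer seed; same seed, same table.
#' @return Tibble with a `class` column and one column per feature.
#' @export
generate_features <- function(truth = default_feature_truth(),
                              n_per_class = 1000, seed = 1L) {
  fn <- attr(truth, "feature_names") %||%
    paste0("x", seq_len(gmm_dim(truth[[1]])))
  n_per_class <- rep_len(n_per_class, length(truth))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  purrr::imap_dfr(truth, function(gmm, name) {
    dplyr::bind_cols(
      tibble::tibble(class = name),
      sample_class_gmm(gmm, n_per_class[[match(name, names(truth))]], fn)
    )
  })
}

#' Generate a random seizure timeline
#'
#' Places `n_seizures` non-overlapping seizures of fixed duration with at
#' least `min_gap` seconds before each one (including the first), the
#' remaining slack spread randomly; with the default `min_gap` of 2.5 h and
#' hour-long pre/post-ictal spans, every labeled period is unambiguous.
#'
#' @param duration Record duration, seconds (24 h by default).
#' @param n_seizures Seizure count.
#' @param seizure_dur Seizure duration, seconds.
#' @param min_gap Minimum seizure-free time preceding each seizure, seconds.
#' @param seed Integer seed.
#' @return A [seizure_timeline()].
#' @export
generate_timeline <- function(duration = 86400, n_seizures = 4,
                              seizure_dur = 60, min_gap = 9000, seed = 1L) {
  if (n_seizures == 0) return(seizure_timeline(duration = duration))
  if (n_seizures * (seizure_dur + min_gap) > duration) {
    rlang::abort("Infeasible packing: seizures plus gaps exceed duration.")
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  slack <- duration - n_seizures * (seizure_dur + min_gap)
  u <- stats::runif(n_seizures + 1)
  extra <- slack * u / sum(u)
  onsets <- numeric(n_seizures)
  t <- 0
  for (i in seq_len(n_seizures)) {
    t <- t + min_gap + extra[i]
    onsets[i] <- t
    t <- t + seizure_dur
  }
  seizure_timeline(onsets, onsets + seizure_dur, duration = duration)
}

#' Per-state spectral profiles for synthetic EEG
#'
#' Target RMS amplitude (signal units, microvolts by convention) and band
#' energy fractions per ictal state; power not assigned to the three
#' classifier bands lands in a low-frequency residual band.
#'
#' @param inter_ictal,pre_ictal,ictal,post_ictal Named numeric vectors with
#'   entries `amp_rms`, `alpha_frac`, `gamma_lo_frac`, `gamma_hi_frac`.
#' @return Tibble with one row per state, class `state_profiles`.
#' @export
state_profiles <- function(
    inter_ictal = c(amp_rms = 20, alpha_frac = 0.55,
                    gamma_lo_frac = 0.08, gamma_hi_frac = 0.05),
    pre_ictal = c(amp_rms = 35, alpha_frac = 0.25,
                  gamma_lo_frac = 0.30, gamma_hi_frac = 0.28),
    ictal = c(amp_rms = 80, alpha_frac = 0.20,
              gamma_lo_frac = 0.30, gamma_hi_frac = 0.30),
    post_ictal = c(amp_rms = 20, alpha_frac = 0.50,
                   gamma_lo_frac = 0.10, gamma_hi_frac = 0.08)) {
  rows <- list(inter_ictal = inter_ictal, pre_ictal = pre_ictal,
               ictal = ictal, post_ictal = post_ictal)
  out <- purrr::imap_dfr(rows, function(p, name) {
    fr <- p[c("alpha_frac", "gamma_lo_frac", "gamma_hi_frac")]
    if (any(fr < 0) || sum(fr) > 1) {
      rlang::abort("Band fractions must be >= 0 and sum to <= 1.")
    }
    tibble::tibble(state = name, amp_rms = p[["amp_rms"]],
                   alpha_frac = fr[[1]], gamma_lo_frac = fr[[2]],
                   gamma_hi_frac = fr[[3]],
                   residual_frac = 1 - sum(fr))
  })
  class(out) <- c("state_profiles", class(out))
  out
}

#' Synthesize state-dependent band-limited EEG
#'
#' The record is a sum of unit-variance band-limited Gaussian noise
#' processes (alpha, split gamma, and a 2-7 Hz residual band), each scaled
#' by a per-sample gain so that the local band-power fractions and RMS
#' amplitude track the profile of the ictal state active at that time.
#' State transitions are smoothed with cosine crossfades so spectra blend
#' over `crossfade` seconds rather than switching instantaneously.
#'
#' @param tl A [seizure_timeline()].
#' @param fs Sampling rate, Hz.
#' @param profiles A [state_profiles()] tibble.
#' @param bands A [band_spec()].
#' @param pre_dur,post_dur Labeling durations used to decide which state is
#'   active, seconds.
#' @param crossfade Transition smoothing time, seconds.
#' @param residual_band Edges of the residual low-frequency band, Hz.
#' @param seed Integer seed.
#' @return An [eeg_signal()].
#' @export
generate_eeg <- function(tl, fs = 256, profiles = state_profiles(),
                         bands = band_spec(), pre_dur = 3600,
                         post_dur = 3600, crossfade = 10,
                         residual_band = c(2, 7), seed = 1L) {
  stopifnot(inherits(tl, "seizure_timeline"))
  duration <- attr(tl, "duration")
  n <- round(duration * fs)
  if (fs < 2 * max_band_edge(bands)) {
    rlang::abort("Sampling rate too low for the requested bands.")
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  band_edges <- list(residual = residual_band, alpha = bands$alpha,
                     gamma_lo = bands$gamma_lo, gamma_hi = bands$gamma_hi)
  band_noise <- lapply(band_edges, function(e) {
    bf <- signal::butter(4, e / (fs / 2), type = "pass")
    x <- signal::filtfilt(bf, stats::rnorm(n))
    x / stats::sd(x)
  })

  # per-sample state, then smoothed one-hot weights (cosine-equivalent via
  # moving average), then per-sample fraction/amplitude targets
  t_samp <- (seq_len(n) - 1) / fs
  st <- label_timeline(tibble::tibble(t_start = t_samp), tl,
                       pre_dur = pre_dur, post_dur = post_dur)$state
  states <- levels(st)
  wlen <- max(1L, round(crossfade * fs))
  kernel <- rep(1 / wlen, wlen)
  smooth1 <- function(ind) {
    as.numeric(stats::filter(ind, kernel, sides = 2, circular = TRUE))
  }
  W <- vapply(states, function(s) smooth1(as.numeric(st == s)),
              numeric(n))
  W <- W / rowSums(W)

  prof <- profiles[match(states, profiles$state), ]
  frac_cols <- c("residual_frac", "alpha_frac", "gamma_lo_frac",
                 "gamma_hi_frac")
  amp <- as.numeric(W %*% prof$amp_rms)
  sig <- numeric(n)
  for (b in seq_along(band_noise)) {
    frac_t <- as.numeric(W %*% prof[[frac_cols[b]]])
    sig <- sig + sqrt(pmax(frac_t, 0)) * band_noise[[b]]
  }
  eeg_signal(amp * sig, fs = fs)
}

#' Simulate a labeled feature scenario directly in feature space
#'
#' Lays analysis windows over a timeline, labels their ictal state, and
#' draws each window's feature vector from the matching ground-truth
#' mixture: pre-ictal windows from the pre-ictal mixture, all others from
#' the inter-ictal one (ictal and post-ictal windows never enter training or
#' scoring, so their features are irrelevant). This is the fast path for
#' classifier-level experiments; [generate_eeg()] exercises the full
#' signal-level loop.
#'
#' @param tl A [seizure_timeline()].
#' @param truth Ground-truth mixtures, as in [default_feature_truth()].
#' @param win_len,stride Window geometry, seconds.
#' @param pre_dur,post_dur Labeling durations, seconds.
#' @param seed Integer seed.
#' @return Tibble with `window`, `t_start`, `state` and the feature columns.
#' @export
simulate_feature_scenario <- function(tl, truth = default_feature_truth(),
                                      win_len = 4, stride = 2,
                                      pre_dur = 3600, post_dur = 3600,
                                      seed = 1L) {
  stopifnot(inherits(tl, "seizure_timeline"))
  duration <- attr(tl, "duration")
  if (duration < win_len) {
    rlang::abort("Record shorter than one window.")
  }
  t_start <- seq(0, duration - win_len, by = stride)
  windows <- tibble::tibble(window = seq_along(t_start), t_start = t_start)
  windows <- label_timeline(windows, tl, pre_dur, post_dur)
  fn <- attr(truth, "feature_names") %||% eeg_feature_names()
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  X <- sample_class_gmm(truth$inter_ictal, nrow(windows), fn)
  pre <- which(windows$state == "pre_ictal")
  if (length(pre)) {
    X[pre, ] <- sample_class_gmm(truth$pre_ictal, length(pre), fn)
  }
  dplyr::bind_cols(windows, X)
}

#' Split windows into training and test halves
#'
#' @param windows Feature window tibble.
#' @param prop Training fraction.
#' @param seed Integer seed.
#' @return `windows` with a `.set` column (`"train"` / `"test"`).
#' @export
split_windows <- function(windows, prop = 0.5, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- nrow(windows)
  train <- sample.int(n, size = floor(prop * n))
  windows$.set <- ifelse(seq_len(n) %in% train, "train", "test")
  windows
}
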