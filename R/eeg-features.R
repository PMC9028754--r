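#' Sampled single-channel EEG signal
#'
#' Light container pairing a sample vector with its sampling rate. Signal
#' units are whatever the caller uses (microvolts throughout the package's
#' examples); features inherit them.
#'
#' @param samples Numeric sample vector.
#' @param fs Sampling rate, Hz.
#' @param t_start Start time of the first sample, seconds.
#' @return An object of class `eeg_signal`.
#' @export
eeg_signal <- function(samples, fs, t_start = 0) {
  if (fs <= 0) rlang::abort("`fs` must be positive.")
  if (length(samples) == 0) rlang::abort("`samples` must be nonempty.")
  structure(list(samples = as.numeric(samples), fs = fs, t_start = t_start),
            class = "eeg_signal")
}

#' @export
print.eeg_signal <- function(x, ...) {
  cat("<eeg_signal>", length(x$samples), "samples @", x$fs, "Hz (",
      signif(length(x$samples) / x$fs, 6), "s )\n")
  invisible(x)
}

#' Analysis band edges
#'
#' The classifier uses the alpha band plus the gamma band split into lower
#' and upper halves; the split point must be shared so the two gamma bands
#' tile the full gamma range.
#'
#' @param alpha,gamma_lo,gamma_hi Band edges `c(lo, hi)` in Hz.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(alpha = c(8, 13), gamma_lo = c(30, 65),
                      gamma_hi = c(65, 100)) {
  for (b in list(alpha, gamma_lo, gamma_hi)) {
    if (length(b) != 2 || b[1] <= 0 || b[2] <= b[1]) {
      rlang::abort("Each band must be c(lo, hi) with 0 < lo < hi.")
    }
  }
  if (gamma_lo[2] != gamma_hi[1]) {
    rlang::abort("gamma_lo's upper edge must equal gamma_hi's lower edge.")
  }
  structure(list(alpha = alpha, gamma_lo = gamma_lo, gamma_hi = gamma_hi),
            class = "band_spec")
}

max_band_edge <- function(bands) {
  max(bands$alpha[2], bands$gamma_lo[2], bands$gamma_hi[2])
}

#' Slice a signal into analysis windows
#'
#' Half-open windows `[t, t + win_len)` advanced by `stride`; a trailing
#' partial window is dropped, so a record of duration `T >= win_len` yields
#' `floor((T - win_len) / stride) + 1` windows.
#'
#' @param sig An [eeg_signal()], or a numeric vector (then pass `fs`).
#' @param fs Sampling rate when `sig` is a bare vector.
#' @param win_len Window length, seconds.
#' @param stride Hop between window starts, seconds.
#' @return Tibble with `window`, `t_start`, `fs` and a `samples`
#'   list-column; zero rows when the record is shorter than one window.
#' @export
make_windows <- function(sig, fs = NULL, win_len = 4, stride = 2) {
  if (inherits(sig, "eeg_signal")) {
    fs <- sig$fs
    x <- sig$samples
  } else {
    if (is.null(fs)) rlang::abort("Pass `fs` with a bare sample vector.")
    x <- as.numeric(sig)
  }
  if (win_len <= 0 || stride <= 0) {
    rlang::abort("`win_len` and `stride` must be positive.")
  }
  win_n <- round(win_len * fs)
  stride_n <- round(stride * fs)
  if (length(x) < win_n) {
    return(tibble::tibble(window = integer(), t_start = numeric(),
                          fs = numeric(), samples = list()))
  }
  starts <- seq(1L, length(x) - win_n + 1L, by = stride_n)
  tibble::tibble(
    window = seq_along(starts),
    t_start = (starts - 1) / fs,
    fs = fs,
    samples = lapply(starts, function(s) x[s:(s + win_n - 1L)])
  )
}

# Hann-tapered periodogram band fractions + peak-to-peak of one window.
window_features <- function(x, fs, bands) {
  vpp <- max(x) - min(x)
  n <- length(x)
  h <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  p <- Mod(stats::fft(x * h))^2
  f <- (seq_len(n) - 1) * fs / n
  keep <- f > 0 & f <= fs / 2 # DC excluded from total power
  p <- p[keep]
  f <- f[keep]
  total <- sum(p)
  frac <- function(edges) {
    if (total == 0) return(0)
    sum(p[f > edges[1] & f <= edges[2]]) / total
  }
  c(vpp = vpp, alpha_frac = frac(bands$alpha),
    gamma_lo_frac = frac(bands$gamma_lo),
    gamma_hi_frac = frac(bands$gamma_hi))
}

#' Extract the four classification features per window
#'
#' Per window: peak-to-peak amplitude plus the fractions of total spectral
#' power (Hann-tapered periodogram, DC excluded) falling in the alpha,
#' lower-gamma and upper-gamma bands.
#'
#' @param windows Output of [make_windows()].
#' @param bands A [band_spec()].
#' @return The window tibble (minus the raw samples) with columns `vpp`,
#'   `alpha_frac`, `gamma_lo_frac`, `gamma_hi_frac` appended.
#' @export
extract_features <- function(windows, bands = band_spec()) {
  if (nrow(windows) == 0) {
    return(tibble::tibble(window = integer(), t_start = numeric(),
                          fs = numeric(), vpp = numeric(),
                          alpha_frac = numeric(), gamma_lo_frac = numeric(),
                          gamma_hi_frac = numeric()))
  }
  if (any(windows$fs < 2 * max_band_edge(bands))) {
    rlang::abort("Sampling rate too low for the requested bands.")
  }
  feats <- t(mapply(function(x, fs) window_features(x, fs, bands),
                    windows$samples, windows$fs))
  dplyr::bind_cols(
    dplyr::select(windows, -"samples"),
    tibble::as_tibble(feats)
  )
}
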