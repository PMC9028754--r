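#' Write a GMM classifier to JSON
#'
#' Serializes `C`, `K`, `N` and every component's mean/variance/weight at
#' full double precision, so that [read_gmm_json()] round-trips losslessly.
#'
#' @param clf A [gmm_classifier()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmm_json <- function(clf, path) {
  stopifnot(inherits(clf, "gmm_classifier"))
  payload <- list(
    format = "gmmwake-model",
    n_classes = length(clf$classes),
    n_clusters = n_components(clf$classes[[1]]),
    n_dims = clf$n_dims,
    feature_names = clf$feature_names,
    classes = lapply(seq_along(clf$classes), function(i) {
      g <- clf$classes[[i]]
      list(
        label = clf$labels[i],
        components = lapply(g$components, function(co) {
          list(mean = co$mean, var = co$var, weight = co$weight)
        })
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a GMM classifier from JSON
#'
#' @param path File produced by [write_gmm_json()].
#' @return A [gmm_classifier()].
#' @export
read_gmm_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(p$classes)) rlang::abort("Not a gmmwake model file.")
  classes <- lapply(p$classes, function(cl) {
    comps <- lapply(cl$components, function(co) {
      gaussian_component(unlist(co$mean), unlist(co$var), co$weight)
    })
    class_gmm(comps, label = cl$label)
  })
  fn <- if (is.null(p$feature_names)) NULL else unlist(p$feature_names)
  gmm_classifier(classes, feature_names = fn)
}

#' Read and write seizure timelines as CSV
#'
#' The on-disk format is a two-column CSV `onset_s, offset_s`; the record
#' duration is carried in a commented header line.
#'
#' @param tl A [seizure_timeline()].
#' @param path CSV path.
#' @return `write_timeline_csv()` returns `path` invisibly;
#'   `read_timeline_csv()` returns a [seizure_timeline()].
#' @export
write_timeline_csv <- function(tl, path) {
  stopifnot(inherits(tl, "seizure_timeline"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration_s=%.10g", attr(tl, "duration")), con)
  utils::write.csv(
    data.frame(onset_s = tl$onset, offset_s = tl$offset),
    con, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_timeline_csv
#' @param duration Record duration in seconds; overrides any duration stored
#'   in the file header.
#' @export
read_timeline_csv <- function(path, duration = NULL) {
  first <- readLines(path, n = 1)
  if (is.null(duration)) {
    m <- regmatches(first, regexec("duration_s=([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 2) duration <- as.numeric(m[2])
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("onset_s", "offset_s") %in% names(df))) {
    rlang::abort("Timeline CSV needs columns onset_s, offset_s.")
  }
  if (is.null(duration)) {
    rlang::abort("Record duration not found in file; pass `duration`.")
  }
  seizure_timeline(df$onset_s, df$offset_s, duration = duration)
}

#' Read and write window feature tables as CSV
#'
#' Columns: `t_start`, the four features, and any label columns present.
#'
#' @param features A data frame of per-window features.
#' @param path CSV path.
#' @return `write_features_csv()` returns `path` invisibly;
#'   `read_features_csv()` returns a tibble.
#' @export
write_features_csv <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read a sampled signal from CSV
#'
#' Expects columns `time` (seconds, uniformly sampled) and `value`.
#'
#' @param path CSV path.
#' @return An `eeg_signal` (samples plus sampling rate).
#' @export
read_signal_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time", "value") %in% names(df))) {
    rlang::abort("Signal CSV needs columns time, value.")
  }
  dt <- diff(df$time)
  if (length(dt) < 1 || any(dt <= 0)) {
    rlang::abort("`time` must be strictly increasing.")
  }
  fs <- 1 / stats::median(dt)
  eeg_signal(df$value, fs = fs)
}

#' @rdname read_signal_csv
#' @param sig An `eeg_signal`.
#' @export
write_signal_csv <- function(sig, path) {
  stopifnot(inherits(sig, "eeg_signal"))
  n <- length(sig$samples)
  readr::write_csv(
    tibble::tibble(time = (seq_len(n) - 1) / sig$fs, value = sig$samples),
    path
  )
  invisible(path)
}
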