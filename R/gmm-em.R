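#' Fit one class-conditional mixture by expectation-maximization
#'
#' Diagonal-covariance EM with k-means seeding, a variance floor against
#' singular components, and a relative log-likelihood stopping rule. All
#' randomness (seeding) flows from `seed`, so fits are reproducible.
#'
#' @param data Numeric matrix or data frame of observations (rows) by
#'   dimensions (columns).
#' @param K Number of mixture components (clusters); `1 <= K <= nrow(data)`.
#' @param seed Integer seed controlling the k-means initialization.
#' @param tol Relative log-likelihood change below which EM stops.
#' @param max_iter Iteration cap.
#' @param var_floor Lower bound applied elementwise to the fitted variances
#'   (feature units squared); prevents collapse onto single points.
#' @param label Optional class label stored on the result.
#' @return A [class_gmm()] with attributes `loglik` (final value),
#'   `loglik_trace` (per-iteration values), `iterations` and `converged`.
#' @export
fit_em <- function(data, K, seed = 1L, tol = 1e-6, max_iter = 500L,
                   var_floor = 1e-6, label = NULL) {
  X <- as.matrix(data)
  storage.mode(X) <- "double"
  n <- nrow(X)
  N <- ncol(X)
  if (n < 1) rlang::abort("`data` must be nonempty.")
  if (K < 1 || K != round(K)) rlang::abort("`K` must be a positive integer.")
  if (K > n) rlang::abort("`K` cannot exceed the number of data points.")

  assign <- em_seed_assignment(X, K, seed)
  mu <- matrix(0, K, N)
  va <- matrix(0, K, N)
  w <- numeric(K)
  for (k in seq_len(K)) {
    idx <- which(assign == k)
    mu[k, ] <- colMeans(X[idx, , drop = FALSE])
    va[k, ] <- pmax(colMeans(sweep(X[idx, , drop = FALSE], 2, mu[k, ])^2),
                    var_floor)
    w[k] <- length(idx) / n
  }

  const <- -0.5 * N * log(2 * pi)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E-step in the log domain
    lp <- matrix(0, n, K)
    for (k in seq_len(K)) {
      lp[, k] <- log(w[k]) + const - 0.5 * sum(log(va[k, ])) -
        0.5 * rowSums(sweep(sweep(X, 2, mu[k, ])^2, 2, va[k, ], "/"))
    }
    mx <- apply(lp, 1, max)
    lse <- mx + log(rowSums(exp(lp - mx)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (iter > 1) {
      prev <- trace[iter - 1L]
      if (abs(ll - prev) <= tol * abs(prev) || iter >= max_iter) {
        converged <- abs(ll - prev) <= tol * abs(prev)
        break
      }
    } else if (max_iter == 1L) {
      break
    }
    resp <- exp(lp - lse)
    nk <- colSums(resp)
    nk <- pmax(nk, .Machine$double.xmin)
    w <- nk / n
    mu <- (t(resp) %*% X) / nk
    va <- pmax((t(resp) %*% X^2) / nk - mu^2, var_floor)
  }

  comps <- lapply(seq_len(K), function(k) {
    gaussian_component(mu[k, ], va[k, ], w[k])
  })
  out <- class_gmm(comps, label = label)
  attr(out, "loglik") <- trace[length(trace)]
  attr(out, "loglik_trace") <- trace
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  out
}

# k-means-style seeding; falls back to a balanced random partition when the
# data have too few distinct points for kmeans (e.g. all-identical input).
em_seed_assignment <- function(X, K, seed) {
  if (K == 1L) return(rep(1L, nrow(X)))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  km <- tryCatch(
    stats::kmeans(X, centers = K, nstart = 10, iter.max = 100),
    error = function(e) NULL, warning = function(w2) NULL
  )
  if (!is.null(km) && all(tabulate(km$cluster, K) > 0)) return(km$cluster)
  sample(rep_len(seq_len(K), nrow(X)))
}

#' Fit the full classifier from a labeled feature table
#'
#' Data-frame-first wrapper around [fit_em()]: fits one mixture per class
#' (all sharing `K`) and assembles a [gmm_classifier()].
#'
#' @param data Data frame holding the features and a class column.
#' @param class_col Name of the class column (default `"state"`).
#' @param feature_cols Names of the feature columns; defaults to the four
#'   EEG features used by the wake-up classifier.
#' @param classes Which class labels to fit, in classifier order. The first
#'   listed label becomes class index 1. Defaults to the labels present, with
#'   `"pre_ictal"` first when applicable.
#' @param K Clusters per class.
#' @param seed,tol,max_iter,var_floor Passed to [fit_em()].
#' @return A [gmm_classifier()] whose classes carry the fitted labels.
#' @export
fit_gmm_classifier <- function(data, class_col = "state",
                               feature_cols = eeg_feature_names(),
                               classes = NULL, K = 2, seed = 1L,
                               tol = 1e-6, max_iter = 500L,
                               var_floor = 1e-6) {
  if (!class_col %in% names(data)) {
    rlang::abort(paste0("Column `", class_col, "` not found."))
  }
  missing_f <- setdiff(feature_cols, names(data))
  if (length(missing_f)) {
    rlang::abort(paste0("Missing feature columns: ",
                        paste(missing_f, collapse = ", ")))
  }
  lab <- as.character(data[[class_col]])
  if (is.null(classes)) {
    classes <- sort(unique(lab))
    if (all(c("pre_ictal", "inter_ictal") %in% classes)) {
      classes <- c("pre_ictal", "inter_ictal")
    }
  }
  fits <- lapply(seq_along(classes), function(i) {
    sub <- data[lab == classes[i], feature_cols, drop = FALSE]
    if (nrow(sub) == 0) {
      rlang::abort(paste0("No rows for class `", classes[i], "`."))
    }
    fit_em(sub, K = K, seed = seed + i, tol = tol, max_iter = max_iter,
           var_floor = var_floor, label = classes[i])
  })
  gmm_classifier(fits, feature_names = feature_cols)
}

#' Canonical EEG feature names
#'
#' Peak-to-peak voltage plus the alpha, lower-gamma and upper-gamma energy
#' fractions.
#' @return Character vector of length four.
#' @export
eeg_feature_names <- function() {
  c("vpp", "alpha_frac", "gamma_lo_frac", "gamma_hi_frac")
}

#' Predict classes for a feature table
#'
#' @param object A [gmm_classifier()].
#' @param newdata Data frame containing the classifier's feature columns, or
#'   a numeric matrix with one row per observation.
#' @param ... Unused.
#' @return A tibble with the winning label `.pred_class`, its index
#'   `.pred_index`, and one `.loglik_<label>` column per class.
#' @export
predict.gmm_classifier <- function(object, newdata, ...) {
  X <- classifier_matrix(object, newdata)
  ll <- vapply(object$classes, function(g) mixture_loglik_matrix(X, g),
               numeric(nrow(X)))
  ll <- matrix(ll, nrow = nrow(X))
  idx <- max.col(ll, ties.method = "first")
  out <- tibble::tibble(
    .pred_class = object$labels[idx],
    .pred_index = as.integer(idx)
  )
  for (j in seq_along(object$labels)) {
    out[[paste0(".loglik_", object$labels[j])]] <- ll[, j]
  }
  out
}

classifier_matrix <- function(clf, newdata) {
  if (is.matrix(newdata)) {
    X <- newdata
  } else {
    cols <- clf$feature_names
    if (is.null(cols)) cols <- names(newdata)[seq_len(clf$n_dims)]
    missing_f <- setdiff(cols, names(newdata))
    if (length(missing_f)) {
      rlang::abort(paste0("Missing feature columns: ",
                          paste(missing_f, collapse = ", ")))
    }
    X <- as.matrix(newdata[, cols, drop = FALSE])
  }
  if (ncol(X) != clf$n_dims) {
    rlang::abort("Dimension mismatch between `newdata` and classifier.")
  }
  storage.mode(X) <- "double"
  X
}

#' @export
print.gmm_classifier <- function(x, ...) {
  cat("<gmm_classifier> C =", length(x$classes),
      "classes, K =", n_components(x$classes[[1]]),
      "clusters, N =", x$n_dims, "dims\n")
  cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted mixture
#'
#' @param x A [class_gmm()].
#' @param ... Unused.
#' @return A tibble with one row per component and dimension: `component`,
#'   `dimension`, `weight`, `mean`, `variance`.
#' @export
tidy.class_gmm <- function(x, ...) {
  purrr::imap_dfr(x$components, function(co, i) {
    tibble::tibble(
      component = i,
      dimension = seq_along(co$mean),
      weight = co$weight,
      mean = co$mean,
      variance = co$var
    )
  })
}

#' @rdname tidy.class_gmm
#' @export
glance.class_gmm <- function(x, ...) {
  tibble::tibble(
    K = n_components(x),
    n_dims = gmm_dim(x),
    loglik = attr(x, "loglik") %||% NA_real_,
    iterations = attr(x, "iterations") %||% NA_integer_,
    converged = attr(x, "converged") %||% NA
  )
}

#' Tidy a full classifier
#'
#' @param x A [gmm_classifier()].
#' @param ... Unused.
#' @return Per-class component table with a `class` column; dimensions carry
#'   the classifier's feature names when available.
#' @export
tidy.gmm_classifier <- function(x, ...) {
  out <- purrr::imap_dfr(x$classes, function(g, i) {
    dplyr::mutate(tidy(g), class = x$labels[i], .before = 1)
  })
  if (!is.null(x$feature_names)) {
    out$dimension <- x$feature_names[out$dimension]
  }
  out
}

#' @rdname tidy.gmm_classifier
#' @export
glance.gmm_classifier <- function(x, ...) {
  tibble::tibble(
    C = length(x$classes),
    K = n_components(x$classes[[1]]),
    n_dims = x$n_dims,
    loglik = sum(vapply(x$classes,
                        function(g) attr(g, "loglik") %||% NA_real_,
                        numeric(1)))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
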