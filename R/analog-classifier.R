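#' Per-dimension affine feature-to-voltage scaler
#'
#' Maps each feature's central quantile range onto a symmetric voltage span
#' inside the rails, so every bump center and the bulk of the inputs stay
#' within the circuit's operating window.
#'
#' @param data Data frame or matrix of training features (rows = windows).
#' @param feature_cols Feature columns to scale (ignored for matrices).
#' @param v_range Target voltage span, volts.
#' @param probs Lower/upper quantiles of the training data mapped onto
#'   `v_range`.
#' @return An object of class `feature_scaler`.
#' @export
feature_scaler <- function(data, feature_cols = eeg_feature_names(),
                           v_range = c(-0.15, 0.15), probs = c(0.01, 0.99)) {
  X <- if (is.matrix(data)) data else {
    as.matrix(data[, intersect(feature_cols, colnames(data)), drop = FALSE])
  }
  q <- apply(X, 2, stats::quantile, probs = probs, names = FALSE)
  span <- q[2, ] - q[1, ]
  if (any(span <= 0)) {
    rlang::abort("Degenerate feature range; cannot build scaler.")
  }
  gain <- (v_range[2] - v_range[1]) / span
  center <- (q[1, ] + q[2, ]) / 2
  structure(list(center = center, gain = gain,
                 v_range = v_range, domain = q,
                 feature_names = colnames(X)),
            class = "feature_scaler")
}

# Feature matrix -> voltage matrix. Values outside the scaler domain map
# outside v_range and are later clamped at the rails.
scale_features <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$center), 2, scaler$gain, "*")
}

#' Map a trained GMM onto analog circuit parameters
#'
#' Translates each component mean into a mean-control voltage through the
#' feature scaler, each standard deviation into a width-control voltage
#' through the inverse width calibration, and each mixing weight into a
#' first-stage bias current (largest cluster current normalized to
#' `full_scale`). `tied_weights = TRUE` mirrors the hardware, which shares
#' one bias current per class and therefore equal within-class cluster
#' weights.
#'
#' @param clf A [gmm_classifier()].
#' @param device A [device_model()].
#' @param calibration A [calibrate_width()] result for `device`; computed on
#'   the fly when omitted.
#' @param scaler A [feature_scaler()] built from the training features.
#' @param tied_weights Force equal within-class bias currents
#'   (hardware-faithful mode).
#' @param full_scale Peak cluster bias current, amperes (12 nA by default).
#' @param wta_bias WTA bias current, amperes.
#' @return An object of class `analog_classifier`.
#' @export
map_gmm_to_analog <- function(clf, device = device_model(),
                              calibration = NULL, scaler,
                              tied_weights = FALSE, full_scale = 12e-9,
                              wta_bias = 12e-9) {
  stopifnot(inherits(clf, "gmm_classifier"), inherits(scaler, "feature_scaler"))
  if (is.null(calibration)) calibration <- calibrate_width(device)
  K <- n_components(clf$classes[[1]])
  weights <- lapply(clf$classes, function(g) gmm_matrices(g)$weight)
  if (tied_weights) weights <- lapply(weights, function(w) rep(1 / K, K))
  w_max <- max(unlist(weights))
  classes <- lapply(seq_along(clf$classes), function(ci) {
    m <- gmm_matrices(clf$classes[[ci]])
    clusters <- lapply(seq_len(K), function(k) {
      v_r <- (m$mean[k, ] - scaler$center) * scaler$gain
      sigma_v <- sqrt(m$var[k, ]) * abs(scaler$gain)
      v_c <- calibration$inverse(sigma_v)
      lapply(seq_along(v_r), function(n) {
        bump_params(v_r = v_r[n], v_c = v_c[n],
                    i_bias = if (n == 1)
                      full_scale * weights[[ci]][k] / w_max else 0)
      })
    })
    list(label = clf$labels[ci], clusters = clusters)
  })
  structure(list(classes = classes, wta_bias = wta_bias, scaler = scaler,
                 device = device, calibration = calibration,
                 tied_weights = tied_weights,
                 feature_names = clf$feature_names,
                 labels = clf$labels,
                 n_dims = clf$n_dims),
            class = "analog_classifier")
}

#' @export
print.analog_classifier <- function(x, ...) {
  cat("<analog_classifier> C =", length(x$classes),
      "classes, K =", length(x$classes[[1]]$clusters),
      "clusters, N =", x$n_dims, "dims;",
      if (x$tied_weights) "tied" else "free", "weights\n")
  invisible(x)
}

#' Classify one feature vector through the analog model
#'
#' Scales the features to voltages (clamping to the rails, with a warning,
#' when a feature falls outside the scaler domain), evaluates every class
#' current, and resolves the winner through the WTA stage.
#'
#' @param x Numeric feature vector.
#' @param cfg An [map_gmm_to_analog()] result.
#' @return Winning class index (integer).
#' @export
classify_analog <- function(x, cfg) {
  stopifnot(inherits(cfg, "analog_classifier"))
  if (length(x) != cfg$n_dims) {
    rlang::abort("Dimension mismatch between `x` and analog classifier.")
  }
  v <- clamp_to_rails(scale_features(cfg$scaler, matrix(x, nrow = 1)),
                      cfg$device)[1, ]
  currents <- vapply(cfg$classes,
                     function(cl) class_current(v, cl$clusters, cfg$device),
                     numeric(1))
  wta(currents, cfg$wta_bias)$winner
}

clamp_to_rails <- function(V, d) {
  out <- pmin(pmax(V, d$supply_neg), d$supply_pos)
  if (any(out != V)) {
    rlang::warn("Input outside scaler domain; clamped to supply rails.")
  }
  out
}

#' Predict classes for a feature table through the analog model
#'
#' Vectorized equivalent of [classify_analog()] over the rows of a feature
#' table.
#'
#' @param object An `analog_classifier`.
#' @param newdata Data frame with the classifier's feature columns, or a
#'   numeric matrix.
#' @param ... Unused.
#' @return Tibble with `.pred_class`, `.pred_index` and one
#'   `.current_<label>` column (amperes) per class.
#' @export
predict.analog_classifier <- function(object, newdata, ...) {
  cols <- object$feature_names
  X <- if (is.matrix(newdata)) newdata else
    as.matrix(newdata[, cols, drop = FALSE])
  storage.mode(X) <- "double"
  V <- suppressWarnings(clamp_to_rails(scale_features(object$scaler, X),
                                       object$device))
  d <- object$device
  cur <- vapply(object$classes, function(cl) {
    cls_cur <- numeric(nrow(V))
    for (cluster in cl$clusters) {
      logshape <- 0
      for (n in seq_along(cluster)) {
        p <- cluster[[n]]
        u <- (V[, n] - p$v_r) / bump_scale(p, d)
        logshape <- logshape + 2 * log(1 / cosh(u))
      }
      cls_cur <- cls_cur + cluster[[1]]$i_bias * exp(logshape)
    }
    cls_cur + d$leakage_floor
  }, numeric(nrow(V)))
  cur <- matrix(cur, nrow = nrow(V))
  idx <- max.col(cur, ties.method = "first")
  out <- tibble::tibble(
    .pred_class = object$labels[idx],
    .pred_index = as.integer(idx)
  )
  for (j in seq_along(object$labels)) {
    out[[paste0(".current_", object$labels[j])]] <- cur[, j]
  }
  out
}

#' Device-mismatch specification
#'
#' Abstraction of process variation for Monte-Carlo analysis: independent
#' Gaussian perturbations of every bump's mean-control voltage (additive),
#' width (multiplicative) and bias current (multiplicative).
#'
#' @param sigma_vr Standard deviation of the Vr offset, volts.
#' @param sigma_width Relative standard deviation of the width gain.
#' @param sigma_current Relative standard deviation of the bias-current gain.
#' @param n_runs Monte-Carlo run count.
#' @param seed Integer seed; together with the run index it fully determines
#'   each perturbation.
#' @return An object of class `mismatch_spec`.
#' @export
mismatch_spec <- function(sigma_vr = 2e-3, sigma_width = 0.02,
                          sigma_current = 0.02, n_runs = 100, seed = 1L) {
  if (any(c(sigma_vr, sigma_width, sigma_current) < 0)) {
    rlang::abort("Mismatch sigmas must be >= 0.")
  }
  if (n_runs < 1) rlang::abort("`n_runs` must be >= 1.")
  structure(list(sigma_vr = sigma_vr, sigma_width = sigma_width,
                 sigma_current = sigma_current,
                 n_runs = as.integer(n_runs), seed = as.integer(seed)),
            class = "mismatch_spec")
}

#' Apply one Monte-Carlo mismatch draw to an analog configuration
#'
#' @param cfg An `analog_classifier`.
#' @param spec A [mismatch_spec()].
#' @param run Run index (1-based); the same `(seed, run)` pair always yields
#'   the same perturbation.
#' @return A perturbed `analog_classifier`.
#' @export
apply_mismatch <- function(cfg, spec, run = 1L) {
  stopifnot(inherits(cfg, "analog_classifier"), inherits(spec, "mismatch_spec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed((spec$seed * 10007 + as.integer(run)) %% 2147483647L)
  cfg$classes <- lapply(cfg$classes, function(cl) {
    cl$clusters <- lapply(cl$clusters, function(cluster) {
      lapply(cluster, function(p) {
        p$v_r <- p$v_r + stats::rnorm(1, 0, spec$sigma_vr)
        p$width_gain <- (p$width_gain %||% 1) *
          max(1 + stats::rnorm(1, 0, spec$sigma_width), 1e-3)
        p$i_bias <- p$i_bias *
          max(1 + stats::rnorm(1, 0, spec$sigma_current), 0)
        p
      })
    })
    cl
  })
  cfg
}

#' Monte-Carlo robustness analysis of the analog classifier
#'
#' Repeatedly perturbs the configuration per the mismatch specification,
#' classifies the labeled windows, and reports the specificity distribution
#' (per-run values, mean and standard deviation) over inter-ictal windows.
#'
#' @param cfg An `analog_classifier`.
#' @param spec A [mismatch_spec()].
#' @param windows Data frame with the feature columns and a `state` column;
#'   specificity is computed over its `inter_ictal` rows.
#' @param positive Label whose prediction raises an alarm.
#' @return An object of class `mc_result`: list with `runs` (tibble of
#'   `run`, `specificity`), `mean` and `sd`.
#' @export
monte_carlo_eval <- function(cfg, spec, windows, positive = "pre_ictal") {
  if (nrow(windows) == 0) rlang::abort("`windows` must be nonempty.")
  if (!"state" %in% names(windows)) {
    rlang::abort("`windows` needs a `state` column.")
  }
  inter <- windows[windows$state == "inter_ictal", , drop = FALSE]
  if (nrow(inter) == 0) rlang::abort("No inter-ictal windows to score.")
  specs <- vapply(seq_len(spec$n_runs), function(r) {
    pert <- apply_mismatch(cfg, spec, run = r)
    pred <- predict(pert, inter)
    mean(pred$.pred_class != positive)
  }, numeric(1))
  structure(list(runs = tibble::tibble(run = seq_len(spec$n_runs),
                                       specificity = specs),
                 mean = mean(specs),
                 sd = stats::sd(specs),
                 spec = spec),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat("<mc_result>", nrow(x$runs), "runs: mean specificity",
      sprintf("%.2f%%", 100 * x$mean), "sd",
      sprintf("%.2f%%", 100 * x$sd), "\n")
  invisible(x)
}

#' @rdname monte_carlo_eval
#' @param x An `mc_result`.
#' @param ... Unused.
#' @export
tidy.mc_result <- function(x, ...) x$runs

#' @rdname monte_carlo_eval
#' @export
glance.mc_result <- function(x, ...) {
  tibble::tibble(n_runs = nrow(x$runs), mean_specificity = x$mean,
                 sd_specificity = x$sd)
}

#' Serialize an analog configuration to JSON
#'
#' Stores the per-bump voltages and currents, the device constants, the
#' feature scaler and the width-calibration table.
#'
#' @param cfg An `analog_classifier`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_analog_json <- function(cfg, path) {
  stopifnot(inherits(cfg, "analog_classifier"))
  payload <- list(
    format = "gmmwake-analog",
    wta_bias = cfg$wta_bias,
    tied_weights = cfg$tied_weights,
    labels = as.list(cfg$labels),
    n_dims = cfg$n_dims,
    feature_names = cfg$feature_names,
    device = unclass(cfg$device),
    scaler = list(center = cfg$scaler$center, gain = cfg$scaler$gain,
                  v_range = cfg$scaler$v_range,
                  feature_names = cfg$scaler$feature_names),
    calibration_table = as.list(cfg$calibration$table),
    classes = lapply(cfg$classes, function(cl) {
      list(label = cl$label, clusters = lapply(cl$clusters, function(cluster) {
        lapply(cluster, function(p) unclass(p))
      }))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
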