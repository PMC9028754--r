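#' Univariate Gaussian density
#'
#' Density of the normal distribution with mean `mean` and *variance* `var`
#' (not standard deviation), the scalar building block of every mixture
#' component in the classifier.
#'
#' @param x Numeric vector of evaluation points.
#' @param mean Mean of the Gaussian.
#' @param var Variance; must be strictly positive.
#' @return Non-negative densities, same length as `x`.
#' @examples
#' gaussian_pdf(0, 0, 1) # 1/sqrt(2*pi)
#' @export
gaussian_pdf <- function(x, mean, var) {
  if (any(!is.finite(var)) || any(var <= 0)) {
    rlang::abort("`var` must be strictly positive and finite.")
  }
  exp(-0.5 * (x - mean)^2 / var) / sqrt(2 * pi * var)
}

log_gaussian_pdf <- function(x, mean, var) {
  -0.5 * (log(2 * pi * var) + (x - mean)^2 / var)
}

#' Gaussian mixture component with diagonal covariance
#'
#' @param mean Numeric vector of per-dimension means (feature units).
#' @param var Numeric vector of per-dimension variances (feature units
#'   squared); strictly positive, same length as `mean`.
#' @param weight Mixing weight in `[0, 1]`.
#' @return An object of class `gmm_component`.
#' @export
gaussian_component <- function(mean, var, weight = 1) {
  mean <- as.numeric(mean)
  var <- as.numeric(var)
  if (length(mean) != length(var)) {
    rlang::abort("`mean` and `var` must have the same length.")
  }
  if (any(!is.finite(var)) || any(var <= 0)) {
    rlang::abort("`var` must be strictly positive elementwise.")
  }
  if (length(weight) != 1 || is.na(weight) || weight < 0 || weight > 1) {
    rlang::abort("`weight` must be a single value in [0, 1].")
  }
  structure(list(mean = mean, var = var, weight = as.numeric(weight)),
            class = "gmm_component")
}

#' Density of a single diagonal-covariance component
#'
#' The multivariate density factorizes into a product of `N` univariate
#' Gaussian densities, one per input dimension; this is the property the
#' cascaded analog bump stages exploit.
#'
#' @param x Numeric vector, one value per dimension.
#' @param comp A [gaussian_component()].
#' @return Non-negative scalar density.
#' @export
component_pdf <- function(x, comp) {
  if (length(x) != length(comp$mean)) {
    rlang::abort("Dimension mismatch between `x` and component.")
  }
  exp(sum(log_gaussian_pdf(x, comp$mean, comp$var)))
}

#' One class-conditional Gaussian mixture
#'
#' @param components List of [gaussian_component()] objects sharing one
#'   dimensionality; weights must sum to 1 (within 1e-9).
#' @param label Class label (character or integer-ish).
#' @return An object of class `class_gmm`.
#' @export
class_gmm <- function(components, label = NULL) {
  if (length(components) < 1) {
    rlang::abort("A mixture needs at least one component.")
  }
  dims <- vapply(components, function(co) length(co$mean), integer(1))
  if (length(unique(dims)) != 1) {
    rlang::abort("All components must share the same dimensionality.")
  }
  w <- vapply(components, function(co) co$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9) {
    rlang::abort("Component weights must sum to 1 (within 1e-9).")
  }
  structure(list(components = components, label = label),
            class = "class_gmm")
}

n_components <- function(gmm) length(gmm$components)
gmm_dim <- function(gmm) length(gmm$components[[1]]$mean)

# K x N matrices / K-vector views of a class_gmm, used by vectorized paths
gmm_matrices <- function(gmm) {
  list(
    mean = do.call(rbind, lapply(gmm$components, `[[`, "mean")),
    var = do.call(rbind, lapply(gmm$components, `[[`, "var")),
    weight = vapply(gmm$components, `[[`, numeric(1), "weight")
  )
}

#' Mixture likelihood of a feature vector
#'
#' Weighted sum of component densities, `sum_i w_i N(x | mu_i, Sigma_i)`.
#'
#' @param x Numeric vector, one value per dimension.
#' @param gmm A [class_gmm()].
#' @return Non-negative scalar likelihood.
#' @export
mixture_pdf <- function(x, gmm) {
  if (!inherits(gmm, "class_gmm")) rlang::abort("`gmm` must be a class_gmm.")
  sum(vapply(gmm$components,
             function(co) co$weight * component_pdf(x, co), numeric(1)))
}

# Row-wise mixture log-likelihood for an n x N matrix, by log-sum-exp.
mixture_loglik_matrix <- function(X, gmm) {
  m <- gmm_matrices(gmm)
  K <- nrow(m$mean)
  lp <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    lp[, k] <- log(m$weight[k]) +
      rowSums(sweep(sweep(X, 2, m$mean[k, ])^2, 2, -2 * m$var[k, ], "/")) -
      0.5 * sum(log(2 * pi * m$var[k, ]))
  }
  mx <- apply(lp, 1, max)
  mx + log(rowSums(exp(lp - mx)))
}

#' Full GMM classifier
#'
#' A set of `C >= 2` class-conditional mixtures sharing the same number of
#' clusters `K` and input dimensionality `N`; classification picks the class
#' with the highest mixture likelihood.
#'
#' @param classes List of [class_gmm()] objects.
#' @param feature_names Optional character vector naming the `N` input
#'   dimensions; used when predicting from data frames.
#' @return An object of class `gmm_classifier`.
#' @export
gmm_classifier <- function(classes, feature_names = NULL) {
  if (length(classes) < 2) rlang::abort("A classifier needs C >= 2 classes.")
  Ks <- vapply(classes, n_components, integer(1))
  if (length(unique(Ks)) != 1) {
    rlang::abort("All classes must share the same number of clusters K.")
  }
  Ns <- vapply(classes, gmm_dim, integer(1))
  if (length(unique(Ns)) != 1) {
    rlang::abort("All classes must share the same dimensionality N.")
  }
  if (!is.null(feature_names) && length(feature_names) != Ns[1]) {
    rlang::abort("`feature_names` must have one entry per dimension.")
  }
  labels <- lapply(seq_along(classes), function(i) {
    if (is.null(classes[[i]]$label)) i else classes[[i]]$label
  })
  structure(list(classes = classes, n_dims = Ns[1],
                 labels = vapply(labels, as.character, character(1)),
                 feature_names = feature_names),
            class = "gmm_classifier")
}

#' Maximum-likelihood class assignment
#'
#' Returns the index of the class whose mixture assigns `x` the highest
#' likelihood; ties are broken in favour of the lowest class index.
#'
#' @param x Numeric feature vector.
#' @param clf A [gmm_classifier()].
#' @return Integer class index (1-based).
#' @export
classify <- function(x, clf) {
  if (!inherits(clf, "gmm_classifier")) {
    rlang::abort("`clf` must be a gmm_classifier.")
  }
  if (length(x) != clf$n_dims) {
    rlang::abort("Dimension mismatch between `x` and classifier.")
  }
  X <- matrix(as.numeric(x), nrow = 1)
  ll <- vapply(clf$classes, function(g) mixture_loglik_matrix(X, g)[1],
               numeric(1))
  which.max(ll) # which.max returns the first (lowest-index) maximum
}

#' Architecture descriptor of the classifier
#'
#' @param n_classes Number of classes `C`.
#' @param n_clusters Clusters per class `K`.
#' @param n_dims Input dimensions `N`.
#' @return An object of class `architecture_spec`.
#' @export
architecture_spec <- function(n_classes, n_clusters, n_dims) {
  v <- c(n_classes, n_clusters, n_dims)
  if (any(v < 1) || any(v != round(v))) {
    rlang::abort("C, K and N must be positive integers.")
  }
  structure(list(n_classes = as.integer(n_classes),
                 n_clusters = as.integer(n_clusters),
                 n_dims = as.integer(n_dims)),
            class = "architecture_spec")
}

#' Count the analog classifier's controlling parameters
#'
#' One mean-control voltage (Vr) and one width-control voltage (Vc) per
#' univariate bump — `C*K*N` of each — plus one bias current per class:
#' `2*C*K*N + C`. The hardware ties the within-class cluster weights through
#' the shared per-class bias current; the software mixture keeps free
#' weights.
#'
#' @param arch An [architecture_spec()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(arch) {
  stopifnot(inherits(arch, "architecture_spec"))
  with(arch, 2L * n_classes * n_clusters * n_dims + n_classes)
}

#' Count scalar operations per classification
#'
#' Fixed accounting convention: 8 scalar operations per univariate Gaussian
#' evaluation (difference, square, scale by the precomputed inverse variance,
#' halve, negate, exponentiate, scale by the precomputed normalizer, multiply
#' into the running product), `K - 1` additions per class to sum cluster
#' likelihoods, and `C - 1` comparisons for the argmax:
#' `8*C*K*N + C*(K-1) + (C-1)`.
#'
#' @param arch An [architecture_spec()].
#' @return Integer operation count.
#' @export
count_operations <- function(arch) {
  stopifnot(inherits(arch, "architecture_spec"))
  with(arch,
       8L * n_classes * n_clusters * n_dims +
         n_classes * (n_clusters - 1L) + (n_classes - 1L))
}
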