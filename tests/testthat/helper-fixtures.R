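# Shared fixtures, built in code at test time.

# A random diagonal-covariance mixture in N dims with K components.
random_class_gmm <- function(K, N, seed) {
  set.seed(seed)
  w <- runif(K)
  w <- w / sum(w)
  comps <- lapply(seq_len(K), function(k) {
    gaussian_component(mean = rnorm(N, sd = 2),
                       var = runif(N, 0.2, 3),
                       weight = w[k])
  })
  class_gmm(comps)
}

# A random C-class classifier sharing K and N.
random_classifier <- function(C, K, N, seed) {
  gmm_classifier(lapply(seq_len(C), function(ci) {
    random_class_gmm(K, N, seed + 31 * ci)
  }))
}

# Brute-force likelihood oracle built on stats::dnorm, independent of the
# package's density code path.
oracle_mixture_pdf <- function(x, gmm) {
  sum(vapply(gmm$components, function(co) {
    co$weight * prod(dnorm(x, co$mean, sqrt(co$var)))
  }, numeric(1)))
}

oracle_classify <- function(x, clf) {
  which.max(vapply(clf$classes, function(g) oracle_mixture_pdf(x, g),
                   numeric(1)))
}

# Two overlapping classes (about 1.5 sigma apart) for tests that need a
# non-trivial error rate, e.g. mismatch Monte-Carlo spread.
overlapping_feature_truth <- function() {
  v <- c(100, 2.5e-3, 2.5e-3, 2.5e-3)
  inter <- class_gmm(list(
    gaussian_component(c(60, 0.50, 0.10, 0.08), v, 0.5),
    gaussian_component(c(70, 0.55, 0.13, 0.10), v, 0.5)
  ), label = "inter_ictal")
  pre <- class_gmm(list(
    gaussian_component(c(75, 0.43, 0.17, 0.14), v, 0.5),
    gaussian_component(c(85, 0.48, 0.20, 0.16), v, 0.5)
  ), label = "pre_ictal")
  out <- list(pre_ictal = pre, inter_ictal = inter)
  attr(out, "feature_names") <- eeg_feature_names()
  out
}

# Small labeled scenario in feature space.
small_scenario <- function(seed = 1, duration = 6 * 3600, n_seizures = 2,
                           truth = default_feature_truth(),
                           pre_dur = 1800, post_dur = 1800,
                           min_gap = 4500) {
  tl <- generate_timeline(duration = duration, n_seizures = n_seizures,
                          seizure_dur = 60, min_gap = min_gap, seed = seed)
  windows <- simulate_feature_scenario(tl, truth = truth, pre_dur = pre_dur,
                                       post_dur = post_dur, seed = seed + 1)
  list(tl = tl, windows = windows, pre_dur = pre_dur, post_dur = post_dur)
}

# Align estimated components to true ones by nearest mean (K small).
align_components <- function(est_means, true_means) {
  K <- nrow(true_means)
  perm <- integer(K)
  used <- logical(K)
  for (k in seq_len(K)) {
    d <- apply(est_means, 1, function(m) sum((m - true_means[k, ])^2))
    d[used] <- Inf
    perm[k] <- which.min(d)
    used[perm[k]] <- TRUE
  }
  perm
}
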