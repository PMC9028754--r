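dev <- device_model()

test_that("bump_current peaks at v_r, is symmetric, and scales with i_bias", {
  p <- bump_params(v_r = 0.05, v_c = 0, i_bias = 12e-9)
  expect_equal(bump_current(0.05, p, dev), 12e-9)
  # even symmetry about v_r
  for (d in c(0.01, 0.05, 0.12)) {
    expect_equal(bump_current(0.05 + d, p, dev),
                 bump_current(0.05 - d, p, dev), tolerance = 1e-12)
  }
  # peak proportional to bias
  p2 <- bump_params(v_r = 0.05, v_c = 0, i_bias = 24e-9)
  expect_equal(bump_current(0.05, p2, dev), 2 * bump_current(0.05, p, dev))
  # unimodal: strictly decreasing away from the center
  v <- seq(0.05, 0.3, length.out = 100)
  expect_true(all(diff(bump_current(v, p, dev)) < 0))
})

test_that("bump curves fit a Gaussian with R^2 above 0.99 across the Vc grid", {
  cal <- calibrate_width(dev)
  expect_true(all(cal$table$r_squared > 0.99))
})

test_that("width calibration is monotone, invertible, and clamps out of range", {
  cal <- calibrate_width(dev)
  expect_true(all(diff(cal$table$sigma) > 0))
  # round trip sigma -> vc -> sigma within 1%
  sig <- seq(min(cal$table$sigma) * 1.05, max(cal$table$sigma) * 0.95,
             length.out = 20)
  vc <- cal$inverse(sig)
  expect_equal(cal$forward(vc), sig, tolerance = 0.01)
  expect_warning(cal$inverse(max(cal$table$sigma) * 2), "clamped")
  expect_error(calibrate_width(dev, vc_grid = c(-1, 0, 1)), "rails")
})

test_that("non-positive bump width is a configuration error", {
  p <- bump_params(v_r = 0, v_c = 0, i_bias = 1e-9, width_gain = 1)
  p$width_gain <- -1
  expect_error(bump_current(0, p, dev), "width")
})

test_that("multivariate bump equals the closed-form product and the cascade", {
  # all inputs at centers -> first stage bias
  cluster <- lapply(1:4, function(n) {
    bump_params(v_r = 0.02 * n, v_c = 0, i_bias = if (n == 1) 5e-9 else 0)
  })
  centers <- 0.02 * (1:4)
  expect_equal(multivariate_bump(centers, cluster, dev), 5e-9)
  # one far-off dimension kills the product
  far <- centers
  far[3] <- 0.3
  expect_lt(multivariate_bump(far, cluster, dev), 1e-12)
  # explicit stage-by-stage cascade oracle on random configs
  set.seed(123)
  for (i in 1:1000) {
    N <- sample(1:6, 1)
    cl <- lapply(seq_len(N), function(n) {
      bump_params(v_r = runif(1, -0.15, 0.15), v_c = runif(1, -0.2, 0.2),
                  i_bias = if (n == 1) runif(1, 1e-10, 2e-8) else 0)
    })
    v <- runif(N, -0.25, 0.25)
    cascade <- cl[[1]]$i_bias
    for (n in seq_len(N)) { # stage n's output biases stage n + 1
      stage <- cl[[n]]
      stage$i_bias <- cascade
      cascade <- bump_current(v[n], stage, dev)
    }
    expect_equal(multivariate_bump(v, cl, dev), cascade,
                 tolerance = 1e-9)
  }
  expect_error(multivariate_bump(numeric(0), list(), dev), "nonempty")
})

test_that("class_current mirrors and sums cluster outputs", {
  mk_cluster <- function(seed) {
    set.seed(seed)
    lapply(1:4, function(n) {
      bump_params(v_r = runif(1, -0.1, 0.1), v_c = runif(1, -0.1, 0.1),
                  i_bias = if (n == 1) runif(1, 1e-9, 1e-8) else 0)
    })
  }
  c1 <- mk_cluster(1)
  v <- c(0.01, -0.02, 0.05, 0)
  expect_equal(class_current(v, list(c1), dev),
               multivariate_bump(v, c1, dev))
  expect_equal(class_current(v, list(c1, c1), dev),
               2 * multivariate_bump(v, c1, dev))
  c2 <- mk_cluster(2)
  c3 <- mk_cluster(3)
  expect_equal(class_current(v, list(c1, c2, c3), dev),
               multivariate_bump(v, c1, dev) +
                 multivariate_bump(v, c2, dev) +
                 multivariate_bump(v, c3, dev))
})

test_that("winner-take-all obeys the logical-one/zero contract", {
  out <- wta(c(5e-9, 1e-9), wta_bias = 12e-9)
  expect_identical(out$winner, 1L)
  expect_equal(out$outputs[1], 12e-9)
  expect_lt(out$outputs[2], 100e-12)
  # ties resolve to the lowest index
  tie <- wta(c(3e-9, 3e-9, 1e-9))
  expect_identical(tie$winner, 1L)
  # exactly one winner at the bias current; losers below 100 pA;
  # permutation equivariance
  set.seed(5)
  for (i in 1:50) {
    cur <- runif(4, 0, 1e-8)
    res <- wta(cur, wta_bias = 12e-9)
    expect_equal(sum(res$outputs == 12e-9), 1)
    expect_true(all(res$outputs[-res$winner] < 100e-12))
    perm <- sample(4)
    res_p <- wta(cur[perm], wta_bias = 12e-9)
    expect_equal(res_p$outputs, res$outputs[perm])
  }
  # soft mode keeps the loser contract
  soft <- wta(c(5e-9, 4.9e-9), mode = "soft")
  expect_identical(soft$winner, 1L)
  expect_lt(soft$outputs[2], 100e-12)
  expect_error(wta(5e-9), "C >= 2")
  expect_error(wta(c(-1e-9, 1e-9)), ">= 0")
})

test_that("GMM-to-analog mapping preserves centers and weight ratios", {
  sc <- small_scenario(seed = 8)
  w <- sc$windows[sc$windows$state %in% c("pre_ictal", "inter_ictal"), ]
  clf <- fit_gmm_classifier(w, K = 2, seed = 2)
  scl <- feature_scaler(w)
  cal <- calibrate_width(dev)
  cfg <- map_gmm_to_analog(clf, dev, cal, scaler = scl)
  # a feature at the center of the scaled range maps to v_r = 0
  mid_clf <- clf
  mid_clf$classes[[1]]$components[[1]]$mean <- as.numeric(scl$center)
  mid_cfg <- map_gmm_to_analog(mid_clf, dev, cal, scaler = scl)
  vr1 <- vapply(mid_cfg$classes[[1]]$clusters[[1]], `[[`, numeric(1), "v_r")
  expect_equal(vr1, rep(0, 4), tolerance = 1e-12)
  # untied mode: bias-current ratio preserves the weight ratio exactly
  for (ci in 1:2) {
    wts <- gmm_matrices(clf$classes[[ci]])$weight
    ib <- vapply(cfg$classes[[ci]]$clusters,
                 function(cl) cl[[1]]$i_bias, numeric(1))
    expect_equal(ib[1] / ib[2], wts[1] / wts[2], tolerance = 1e-9)
  }
  expect_equal(max(vapply(cfg$classes, function(cl) {
    max(vapply(cl$clusters, function(x) x[[1]]$i_bias, numeric(1)))
  }, numeric(1))), 12e-9)
  # tied mode equalizes within-class currents
  tied <- map_gmm_to_analog(clf, dev, cal, scaler = scl, tied_weights = TRUE)
  for (ci in 1:2) {
    ib <- vapply(tied$classes[[ci]]$clusters,
                 function(cl) cl[[1]]$i_bias, numeric(1))
    expect_equal(ib[1], ib[2])
  }
})

test_that("analog decisions track the ideal classifier on separated data", {
  sc <- small_scenario(seed = 12)
  w <- sc$windows[sc$windows$state %in% c("pre_ictal", "inter_ictal"), ]
  clf <- fit_gmm_classifier(w, K = 2, seed = 3)
  cfg <- map_gmm_to_analog(clf, scaler = feature_scaler(w))
  ideal <- predict(clf, w)
  analog <- predict(cfg, w)
  expect_gte(mean(ideal$.pred_class == analog$.pred_class), 0.95)
  # perfect agreement where the likelihood ratio is decisive (> 10)
  lr <- exp(abs(ideal$.loglik_pre_ictal - ideal$.loglik_inter_ictal))
  sure <- lr > 10
  expect_gt(sum(sure), 0)
  expect_equal(mean(ideal$.pred_class[sure] == analog$.pred_class[sure]), 1)
  # determinism and scalar path agreement
  x <- as.numeric(w[5, eeg_feature_names()])
  expect_identical(classify_analog(x, cfg), classify_analog(x, cfg))
  expect_identical(classify_analog(x, cfg), analog$.pred_index[5])
})

test_that("features outside the scaler domain clamp to the rails with a warning", {
  sc <- small_scenario(seed = 3)
  w <- sc$windows[sc$windows$state %in% c("pre_ictal", "inter_ictal"), ]
  clf <- fit_gmm_classifier(w, K = 2, seed = 1)
  cfg <- map_gmm_to_analog(clf, scaler = feature_scaler(w))
  x <- as.numeric(w[1, eeg_feature_names()])
  x[1] <- x[1] * 100
  expect_warning(classify_analog(x, cfg), "clamped")
})

test_that("mismatch perturbations are seeded, unbiased, and sized as specified", {
  sc <- small_scenario(seed = 6)
  w <- sc$windows[sc$windows$state %in% c("pre_ictal", "inter_ictal"), ]
  clf <- fit_gmm_classifier(w, K = 2, seed = 1)
  cfg <- map_gmm_to_analog(clf, scaler = feature_scaler(w))
  # zero sigmas: identity
  zero <- mismatch_spec(0, 0, 0, n_runs = 1, seed = 1)
  same <- apply_mismatch(cfg, zero, run = 1)
  expect_equal(same$classes, cfg$classes)
  # same (seed, run) twice: identical; different run: different
  spec <- mismatch_spec(seed = 9)
  a <- apply_mismatch(cfg, spec, run = 3)
  b <- apply_mismatch(cfg, spec, run = 3)
  c <- apply_mismatch(cfg, spec, run = 4)
  expect_equal(a$classes, b$classes)
  expect_false(identical(a$classes, c$classes))
  # sample moments of the Vr offsets match sigma_vr within 10% at 1e4 draws
  spec2 <- mismatch_spec(sigma_vr = 2e-3, sigma_width = 0.02,
                         sigma_current = 0.02, seed = 4)
  all_vr <- function(conf) {
    unlist(lapply(conf$classes, function(cl) {
      lapply(cl$clusters, function(cluster) {
        vapply(cluster, `[[`, numeric(1), "v_r")
      })
    }), use.names = FALSE)
  }
  orig_vr <- all_vr(cfg)
  n_bumps <- length(orig_vr)
  draws <- vapply(seq_len(ceiling(1e4 / n_bumps)), function(r) {
    all_vr(apply_mismatch(cfg, spec2, run = r)) - orig_vr
  }, numeric(n_bumps))
  offs <- as.numeric(draws)
  expect_equal(sd(offs), 2e-3, tolerance = 0.1)
  expect_lt(abs(mean(offs)), 3 * 2e-3 / sqrt(length(offs)) + 1e-4)
})

test_that("Monte-Carlo evaluation reports a seeded specificity distribution", {
  truth <- overlapping_feature_truth()
  sc <- small_scenario(seed = 15, truth = truth)
  w <- sc$windows[sc$windows$state %in% c("pre_ictal", "inter_ictal"), ]
  set.seed(77)
  w <- w[sample(nrow(w)) <= 600, ] # keep the run fast
  clf <- fit_gmm_classifier(w, K = 2, seed = 2)
  cfg <- map_gmm_to_analog(clf, scaler = feature_scaler(w))
  # zero mismatch reproduces the unperturbed specificity in every run
  base <- predict(cfg, w[w$state == "inter_ictal", ])
  spec0 <- mean(base$.pred_class != "pre_ictal")
  mc0 <- monte_carlo_eval(cfg, mismatch_spec(0, 0, 0, n_runs = 5), w)
  expect_equal(mc0$sd, 0)
  expect_true(all(mc0$runs$specificity == spec0))
  # perturbed runs stay valid fractions and fill n_runs rows
  mc <- monte_carlo_eval(cfg, mismatch_spec(n_runs = 12, seed = 2), w)
  expect_equal(nrow(mc$runs), 12)
  expect_true(all(mc$runs$specificity >= 0 & mc$runs$specificity <= 1))
  expect_equal(mc$mean, mean(mc$runs$specificity))
  # spread grows (weakly) when all sigmas scale by 4, averaged over seeds
  sds <- vapply(1:5, function(s) {
    small <- monte_carlo_eval(cfg, mismatch_spec(2e-3, 0.02, 0.02,
                                                 n_runs = 8, seed = s), w)
    big <- monte_carlo_eval(cfg, mismatch_spec(8e-3, 0.08, 0.08,
                                               n_runs = 8, seed = s), w)
    c(small$sd, big$sd)
  }, numeric(2))
  expect_gte(mean(sds[2, ]), mean(sds[1, ]))
})

test_that("analog configuration serializes to JSON", {
  sc <- small_scenario(seed = 5)
  w <- sc$windows[sc$windows$state %in% c("pre_ictal", "inter_ictal"), ]
  clf <- fit_gmm_classifier(w, K = 2, seed = 1)
  cfg <- map_gmm_to_analog(clf, scaler = feature_scaler(w))
  path <- withr::local_tempfile(fileext = ".json")
  write_analog_json(cfg, path)
  p <- jsonlite::read_json(path)
  expect_equal(p$format, "gmmwake-analog")
  expect_equal(p$wta_bias, 12e-9)
  expect_length(p$classes, 2)
  expect_length(p$classes[[1]]$clusters, 2)
  expect_length(p$classes[[1]]$clusters[[1]], 4)
})
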