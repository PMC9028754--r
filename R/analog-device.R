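#' Subthreshold device model for the behavioral classifier
#'
#' Collects the device constants behind the bump-circuit transfer law: the
#' thermal voltage, the subthreshold slope factor, the supply rails and the
#' width map translating the variance-control voltage Vc into a dimensionless
#' bump-width multiplier.
#'
#' @param thermal_voltage kT/q in volts (0.02585 V at 300 K).
#' @param slope_factor Subthreshold slope (capacitive divider) factor, in
#'   (0, 1].
#' @param supply_neg,supply_pos Negative and positive rails in volts; the
#'   classifier runs on a symmetric 0.6 V supply by default.
#' @param width_coeffs Coefficients `c(c0, c1)` of the width map
#'   `w(Vc) = exp((Vc - c0) / c1)`; monotone and strictly positive.
#' @param leakage_floor Additive output leakage in amperes.
#' @return An object of class `device_model`.
#' @export
device_model <- function(thermal_voltage = 0.02585, slope_factor = 0.7,
                         supply_neg = -0.3, supply_pos = 0.3,
                         width_coeffs = c(0, 0.3), leakage_floor = 0) {
  if (thermal_voltage <= 0) rlang::abort("`thermal_voltage` must be > 0.")
  if (slope_factor <= 0 || slope_factor > 1) {
    rlang::abort("`slope_factor` must lie in (0, 1].")
  }
  if (supply_pos <= supply_neg) {
    rlang::abort("`supply_pos` must exceed `supply_neg`.")
  }
  if (length(width_coeffs) != 2 || width_coeffs[2] == 0) {
    rlang::abort("`width_coeffs` must be c(c0, c1) with c1 != 0.")
  }
  structure(list(thermal_voltage = thermal_voltage,
                 slope_factor = slope_factor,
                 supply_neg = supply_neg, supply_pos = supply_pos,
                 width_coeffs = as.numeric(width_coeffs),
                 leakage_floor = leakage_floor),
            class = "device_model")
}

# Dimensionless width multiplier of a bump; width_gain carries mismatch.
width_multiplier <- function(v_c, d, width_gain = 1) {
  if (any(width_gain <= 0)) {
    rlang::abort("Non-positive bump width; check width gain/coefficients.")
  }
  width_gain * exp((v_c - d$width_coeffs[1]) / d$width_coeffs[2])
}

# Voltage scale s of the sech^2 argument; sigma_eff ~= 0.78 * s.
bump_scale <- function(p, d) {
  2 * d$slope_factor * d$thermal_voltage *
    width_multiplier(p$v_c, d, p$width_gain %||% 1)
}

#' Control parameters of one univariate bump stage
#'
#' @param v_r Mean-control voltage (volts).
#' @param v_c Width-control voltage (volts).
#' @param i_bias Bias current in amperes setting the bump height; meaningful
#'   only on the first stage of a cascaded cluster.
#' @param width_gain Multiplicative width perturbation (mismatch modeling);
#'   1 when matched.
#' @return An object of class `bump_params`.
#' @export
bump_params <- function(v_r, v_c, i_bias = 0, width_gain = 1) {
  if (i_bias < 0) rlang::abort("`i_bias` must be non-negative.")
  structure(list(v_r = v_r, v_c = v_c, i_bias = i_bias,
                 width_gain = width_gain),
            class = "bump_params")
}

# Unit-peak sech^2 transfer of one bump stage.
bump_shape <- function(v_in, p, d) {
  s <- bump_scale(p, d)
  u <- (v_in - p$v_r) / s
  (1 / cosh(u))^2
}

#' Output current of a single bump circuit
#'
#' Behavioral transfer of the subthreshold bump: a sech-squared curve of the
#' input voltage, centered at `v_r`, with width set by `v_c` through the
#' device width map and peak height equal to `i_bias`. The sech-squared law
#' is the classic response of a subthreshold differential pair feeding a
#' current correlator, and is Gaussian-like to better than R-squared 0.99
#' over four effective standard deviations.
#'
#' @param v_in Input voltage(s), volts.
#' @param p A [bump_params()].
#' @param d A [device_model()].
#' @return Output current(s) in amperes.
#' @export
bump_current <- function(v_in, p, d) {
  p$i_bias * bump_shape(v_in, p, d) + d$leakage_floor
}

#' Output current of a cascaded multivariate bump (one cluster)
#'
#' Stage `n + 1` is biased by stage `n`'s output current, so the cascade
#' output equals the first stage's bias current times the product of all
#' unit-peak stage shapes — the analog realization of a diagonal-covariance
#' multivariate Gaussian.
#'
#' @param v_in Numeric vector of input voltages, one per stage.
#' @param cluster List of [bump_params()], one per stage; only the first
#'   stage's `i_bias` is used.
#' @param d A [device_model()].
#' @return Output current in amperes.
#' @export
multivariate_bump <- function(v_in, cluster, d) {
  if (length(cluster) < 1) rlang::abort("`cluster` must be nonempty.")
  if (length(v_in) != length(cluster)) {
    rlang::abort("One input voltage per bump stage is required.")
  }
  shapes <- vapply(seq_along(cluster),
                   function(n) bump_shape(v_in[n], cluster[[n]], d),
                   numeric(1))
  cluster[[1]]$i_bias * prod(shapes) + d$leakage_floor
}

#' Summed cluster currents of one class
#'
#' Current mirrors add the cluster outputs, so the class current is the sum
#' of its cluster cascades — proportional to the class mixture likelihood up
#' to the voltage mapping distortion.
#'
#' @param v_in Numeric vector of input voltages.
#' @param clusters List of clusters, each a list of [bump_params()].
#' @param d A [device_model()].
#' @return Class output current in amperes.
#' @export
class_current <- function(v_in, clusters, d) {
  sum(vapply(clusters, function(cl) multivariate_bump(v_in, cl, d),
             numeric(1)))
}

#' Winner-take-all stage
#'
#' Behavioral model of the current-mode WTA: the largest input wins and
#' sources the circuit's bias current ("logical one"); every loser output is
#' logical zero, below 100 pA. Ties resolve to the lowest index. The
#' `"soft"` mode models finite gain by splitting the bias current with a
#' sharp power law, with losers still clamped under the logical-zero ceiling.
#'
#' @param currents Non-negative input currents, one per class (`C >= 2`).
#' @param wta_bias Bias current in amperes (default 12 nA).
#' @param mode `"ideal"` (default) or `"soft"`.
#' @param sharpness Exponent of the soft mode's power-law competition.
#' @return List with `winner` (index) and `outputs` (amperes).
#' @export
wta <- function(currents, wta_bias = 12e-9, mode = c("ideal", "soft"),
                sharpness = 40) {
  mode <- match.arg(mode)
  if (length(currents) < 2) rlang::abort("WTA needs C >= 2 input currents.")
  if (any(currents < 0)) rlang::abort("WTA input currents must be >= 0.")
  winner <- which.max(currents)
  if (mode == "ideal") {
    outputs <- numeric(length(currents))
    outputs[winner] <- wta_bias
  } else {
    z <- currents / max(currents, .Machine$double.xmin)
    share <- z^sharpness
    outputs <- wta_bias * share / sum(share)
    lose <- seq_along(outputs) != winner
    outputs[lose] <- pmin(outputs[lose], 99e-12)
    outputs[winner] <- wta_bias - sum(outputs[lose])
  }
  list(winner = winner, outputs = outputs)
}

#' Calibrate the Vc-to-width map
#'
#' Evaluates the bump over a grid of width-control voltages, least-squares
#' fits a unit-peak Gaussian to each curve, and tabulates the effective
#' standard deviation (in volts). Returns interpolating forward
#' (`Vc -> sigma`) and inverse (`sigma -> Vc`) maps; requests outside the
#' calibrated range are clamped with a warning.
#'
#' @param d A [device_model()].
#' @param vc_grid Grid of Vc values within the rails.
#' @return An object of class `width_calibration` with elements `table`
#'   (tibble of `v_c`, `sigma`, `r_squared`), `forward` and `inverse`
#'   (functions), and the device model used.
#' @export
calibrate_width <- function(d, vc_grid = seq(-0.3, 0.3, by = 0.02)) {
  if (any(vc_grid < d$supply_neg | vc_grid > d$supply_pos)) {
    rlang::abort("`vc_grid` must lie within the supply rails.")
  }
  fit_one <- function(vc) {
    p <- bump_params(v_r = 0, v_c = vc, i_bias = 1)
    s <- bump_scale(p, d)
    x <- seq(-4 * s, 4 * s, length.out = 201)
    y <- bump_shape(x, p, d)
    sse <- function(sig) sum((y - exp(-x^2 / (2 * sig^2)))^2)
    opt <- stats::optimize(sse, interval = c(s / 20, 5 * s))
    r2 <- 1 - opt$objective / sum((y - mean(y))^2)
    c(sigma = opt$minimum, r_squared = r2)
  }
  fits <- t(vapply(vc_grid, fit_one, numeric(2)))
  tab <- tibble::tibble(v_c = vc_grid, sigma = fits[, "sigma"],
                        r_squared = fits[, "r_squared"])
  if (any(diff(tab$sigma) <= 0)) {
    rlang::abort(c("Fitted widths are not strictly increasing over the grid.",
                   i = paste("Grid:", paste(signif(vc_grid, 3),
                                            collapse = ", "))))
  }
  fwd <- stats::approxfun(tab$v_c, tab$sigma)
  inv_raw <- stats::approxfun(tab$sigma, tab$v_c)
  rng <- range(tab$sigma)
  inverse <- function(sigma) {
    clamped <- pmin(pmax(sigma, rng[1]), rng[2])
    if (any(clamped != sigma)) {
      rlang::warn("Requested width outside calibrated range; clamped.")
    }
    inv_raw(clamped)
  }
  structure(list(table = tab, forward = fwd, inverse = inverse, device = d),
            class = "width_calibration")
}

#' @export
print.width_calibration <- function(x, ...) {
  rng <- range(x$table$sigma)
  cat("<width_calibration>", nrow(x$table), "grid points, sigma in [",
      signif(rng[1], 4), ",", signif(rng[2], 4), "] V\n")
  invisible(x)
}
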