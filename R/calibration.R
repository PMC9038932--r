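# Calibration constants for the two-energy linear attenuation model --------

#' Calibration constants of the two-energy decomposition model
#'
#' Bundles every material and energy-dependent constant of the linear
#' forward model that links the 90-kVp and Sn150-kVp Hounsfield intensities
#' of a trabecular-bone voxel to its matrix (bone mineral + collagen) volume
#' fraction \eqn{V_{TB}} and adipose volume fraction \eqn{V_F}:
#' \deqn{X^{lo} = (\mu_{lo} - \gamma_{lo} g)\,V_{TB} +
#'       (\beta_{lo} t - \gamma_{lo} g)\,V_F + \gamma_{lo} g + \delta_{lo},}
#' and analogously at the high energy. The material constants are
#' `t = 0.92`, `g = 1.02`, `l = 3.06` g/cm3 and `lam = 2.11`; the
#' energy-related constants (`mu`, `gamma`, `beta`, `delta` per energy) are
#' scanner/spectrum dependent configuration. The packaged defaults are a
#' synthetic, physically plausible set for a 90/Sn150-kVp dual-source
#' acquisition (see [default_constants()]), not vendor values.
#'
#' @param mu_lo,mu_hi HU response of pure matrix material at the low/high
#'   energy (HU per unit matrix fraction).
#' @param gamma_lo,gamma_hi Energy coefficients multiplying `g` (HU).
#' @param beta_lo,beta_hi Energy coefficients multiplying `t` (HU).
#' @param delta_lo,delta_hi HU offsets; default a shared value of 0.
#' @param t,g Dimensionless material constants (defaults 0.92 and 1.02).
#' @param l Matrix density constant in g/cm3 (default 3.06).
#' @param lam Dimensionless partition constant (default 2.11).
#' @param det_tol Singularity tolerance: the absolute determinant of the
#'   2x2 coefficient matrix must exceed this (HU^2 units; default 1e-6).
#' @return An object of class `dect_constants`.
#' @seealso [forward_model()], [invert_decomposition()],
#'   [coefficient_matrix()], [read_constants()]
#' @export
dect_constants <- function(mu_lo, mu_hi, gamma_lo, gamma_hi,
                           beta_lo, beta_hi,
                           delta_lo = 0, delta_hi = delta_lo,
                           t = 0.92, g = 1.02, l = 3.06, lam = 2.11,
                           det_tol = 1e-6) {
  vals <- list(mu_lo = mu_lo, mu_hi = mu_hi,
               gamma_lo = gamma_lo, gamma_hi = gamma_hi,
               beta_lo = beta_lo, beta_hi = beta_hi,
               delta_lo = delta_lo, delta_hi = delta_hi,
               t = t, g = g, l = l, lam = lam, det_tol = det_tol)
  for (nm in names(vals)) assert_finite(vals[[nm]], nm)
  if (t <= 0 || g <= 0 || l <= 0 || lam <= 0) {
    stop_dect("material constants t, g, l, lam must be strictly positive",
              "dectbmd_invalid_constants")
  }
  obj <- structure(vals, class = "dect_constants")
  d <- det(coefficient_matrix(obj))
  if (abs(d) < det_tol) {
    stop_dect(sprintf(
      "singular calibration: |det| = %.3g below tolerance %.3g", abs(d), det_tol),
      "dectbmd_singular_calibration", determinant = d)
  }
  obj
}

#' The 2x2 coefficient matrix of the decomposition system
#'
#' Row order (low energy, high energy); column order (`v_tb`, `v_f`). Entry
#' `[i, 1]` is `mu_i - gamma_i * g` and `[i, 2]` is `beta_i * t - gamma_i * g`.
#'
#' @param c A [dect_constants()] object.
#' @return A 2x2 numeric matrix.
#' @export
coefficient_matrix <- function(c) {
  stopifnot(inherits(c, "dect_constants"))
  matrix(c(c$mu_lo - c$gamma_lo * c$g, c$beta_lo * c$t - c$gamma_lo * c$g,
           c$mu_hi - c$gamma_hi * c$g, c$beta_hi * c$t - c$gamma_hi * c$g),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("lo", "hi"), c("v_tb", "v_f")))
}

# Baseline HU pair at v_tb = v_f = 0 (gamma*g + delta per energy).
baseline_hu <- function(c) {
  c(lo = c$gamma_lo * c$g + c$delta_lo,
    hi = c$gamma_hi * c$g + c$delta_hi)
}

#' @export
print.dect_constants <- function(x, ...) {
  cat("Dual-energy decomposition constants\n")
  cat(sprintf("  mu:    lo %10.3f  hi %10.3f (HU)\n", x$mu_lo, x$mu_hi))
  cat(sprintf("  gamma: lo %10.3f  hi %10.3f (HU)\n", x$gamma_lo, x$gamma_hi))
  cat(sprintf("  beta:  lo %10.3f  hi %10.3f (HU)\n", x$beta_lo, x$beta_hi))
  cat(sprintf("  delta: lo %10.3f  hi %10.3f (HU)\n", x$delta_lo, x$delta_hi))
  cat(sprintf("  t = %.3f, g = %.3f, l = %.3f g/cm3, lambda = %.3f\n",
              x$t, x$g, x$l, x$lam))
  cat(sprintf("  |det| = %.4g (tolerance %.3g)\n",
              abs(det(coefficient_matrix(x))), x$det_tol))
  invisible(x)
}

#' Packaged default calibration constants
#'
#' Reads the versioned defaults shipped with the package
#' (`inst/extdata/default_constants.yaml`): a synthetic but physically
#' plausible constant set for a 90/Sn150-kVp dual-source scan, chosen so
#' that pure matrix material maps to roughly 2000/1200 HU, pure adipose
#' tissue to about -110/-90 HU, and the fraction-free baseline to 15 HU at
#' both energies.
#'
#' @return A [dect_constants()] object.
#' @export
default_constants <- function() {
  read_constants(system.file("extdata", "default_constants.yaml",
                             package = "dectbmd", mustWork = TRUE))
}

#' Read or write calibration constants as a YAML config file
#'
#' The file stores the [dect_constants()] fields under their exact names.
#'
#' @param path File path.
#' @return `read_constants()` returns a [dect_constants()] object;
#'   `write_constants()` returns `path` invisibly.
#' @export
read_constants <- function(path) {
  vals <- yaml::read_yaml(path)
  needed <- c("mu_lo", "mu_hi", "gamma_lo", "gamma_hi", "beta_lo", "beta_hi")
  missing <- setdiff(needed, names(vals))
  if (length(missing)) {
    stop_dect(paste("constants file missing fields:",
                    paste(missing, collapse = ", ")),
              "dectbmd_invalid_constants")
  }
  do.call(dect_constants, vals[names(vals) %in% names(formals(dect_constants))])
}

#' @param c A [dect_constants()] object to write.
#' @rdname read_constants
#' @export
write_constants <- function(c, path) {
  stopifnot(inherits(c, "dect_constants"))
  yaml::write_yaml(unclass(c), path)
  invisible(path)
}

#' Least-squares calibration of the energy-dependent constants
#'
#' Fits, per energy, the three lumped coefficients of the linear model
#' (slope in `v_tb`, slope in `v_f`, intercept) to observed
#' (fractions, HU) pairs by ordinary least squares, then maps them back to
#' `(mu, beta, gamma, delta)` under the convention `delta = 0`,
#' `gamma = intercept / g` (with `t`, `g` fixed). This provides a working
#' calibration path for scanners whose energy-related constants are not
#' published.
#'
#' @param fractions Two-column matrix or data frame of (`v_tb`, `v_f`)
#'   observations (one row per measured region).
#' @param hu Two-column matrix or data frame of observed HU (`hu_lo`,
#'   `hu_hi`), same rows.
#' @param t,g,l,lam,det_tol Passed through to [dect_constants()].
#' @return A [dect_constants()] object with attributes `residual_rms`
#'   (length-2, per energy) and `lumped` (the fitted 2x3 coefficient
#'   matrix: slopes and intercept per energy).
#' @export
calibrate_constants <- function(fractions, hu, t = 0.92, g = 1.02,
                                l = 3.06, lam = 2.11, det_tol = 1e-6) {
  fractions <- as.matrix(fractions)
  hu <- as.matrix(hu)
  if (nrow(fractions) != nrow(hu) || ncol(fractions) != 2 || ncol(hu) != 2) {
    stop_dect("fractions and hu must be two-column with equal row counts",
              "dectbmd_invalid_input")
  }
  assert_finite(fractions, "fractions"); assert_finite(hu, "hu")
  n <- nrow(fractions)
  X <- cbind(fractions, 1)
  if (n < 3 || qr(X)$rank < 3) {
    stop_dect("calibration design is rank-deficient: need >= 3 non-collinear (v_tb, v_f, 1) observations",
              "dectbmd_calibration_design")
  }
  fit <- stats::lm.fit(X, hu)
  co <- t(fit$coefficients)               # 2 x 3: rows lo/hi
  rms <- sqrt(colMeans(as.matrix(fit$residuals)^2))
  # back out constants: slope_tb = mu - gamma*g; slope_f = beta*t - gamma*g;
  # intercept = gamma*g + delta, with delta = 0 by convention.
  gamma <- unname(co[, 3] / g)
  mu <- unname(co[, 1] + co[, 3])
  beta <- unname((co[, 2] + co[, 3]) / t)
  out <- dect_constants(mu_lo = mu[1], mu_hi = mu[2],
                        gamma_lo = gamma[1], gamma_hi = gamma[2],
                        beta_lo = beta[1], beta_hi = beta[2],
                        delta_lo = 0, delta_hi = 0,
                        t = t, g = g, l = l, lam = lam, det_tol = det_tol)
  attr(out, "residual_rms") <- stats::setNames(rms, c("lo", "hi"))
  attr(out, "lumped") <- matrix(co, 2, 3,
                                dimnames = list(c("lo", "hi"),
                                                c("slope_tb", "slope_f", "intercept")))
  out
}
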