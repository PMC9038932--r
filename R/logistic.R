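# Logistic regression by Newton-Raphson / IRLS, odds ratios, Nagelkerke ----

#' Multivariable logistic regression for fracture risk
#'
#' Fits a binary logistic model by Newton-Raphson (equivalently IRLS):
#' starting from zero coefficients, iterate
#' `beta <- beta + solve(X' W X, X' (y - mu))` with `mu = plogis(X beta)`
#' and `W = diag(mu (1 - mu))`, declaring convergence when the maximum
#' absolute score drops below 1e-8 or the relative log-likelihood change
#' below 1e-10 (cap 100 iterations). Wald standard errors come from the
#' inverse observed information, odds ratios as `exp(beta)` with
#' `exp(beta +/- z SE)` CIs; the likelihood-ratio chi-squared is against
#' the intercept-only model and the goodness of fit is Nagelkerke's R2.
#' The model AUC is the ROC of the fitted probabilities against the
#' outcome.
#'
#' Quasi-complete separation (a diverging coefficient with a still-rising
#' likelihood) triggers a warning and returns the partial fit flagged
#' `separation = TRUE`; failure to converge otherwise is an error.
#'
#' @param outcome 0/1 outcome vector (both classes required).
#' @param covariates Data frame or matrix of numeric covariates (an
#'   intercept column is added internally); typical columns `bmd`, `age`,
#'   `female`.
#' @param ci_level Confidence level for OR CIs (default 0.95).
#' @return An object of class `logistic_fit`: coefficients table
#'   (`estimate`, `se`, `z`, `p`, `or`, `or_lo`, `or_hi`), `loglik`,
#'   `loglik_null`, `lr_chisq`, `lr_df`, `lr_p`, `nagelkerke_r2`,
#'   `model_auc`, `fitted`, `iterations`, `converged`, `separation`.
#' @export
fit_logistic <- function(outcome, covariates, ci_level = 0.95) {
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) {
    stop_dect("outcome must be 0/1", "dectbmd_invalid_input")
  }
  if (length(unique(y)) < 2) {
    stop_dect("degenerate labels: both classes must be present",
              "dectbmd_degenerate_labels")
  }
  X <- cbind(intercept = 1, as.matrix(covariates))
  storage.mode(X) <- "double"
  assert_finite(X, "covariates")
  n <- nrow(X); k <- ncol(X)
  if (n <= k) stop_dect("need n > number of parameters", "dectbmd_invalid_input")
  beta <- rep(0, k)
  ll <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  ll_old <- ll(beta)
  converged <- FALSE; separation <- FALSE
  iter <- 0
  info <- NULL
  while (iter < 100) {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X, X * w)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) { separation <- TRUE; break }
    beta_new <- beta + step
    ll_new <- ll(beta_new)
    # step-halving if the full Newton step overshoots
    h <- 0
    while (ll_new < ll_old && h < 20) {
      step <- step / 2; beta_new <- beta + step; ll_new <- ll(beta_new); h <- h + 1
    }
    beta <- beta_new
    rel <- abs(ll_new - ll_old) / (abs(ll_old) + 1e-12)
    ll_old <- ll_new
    if (max(abs(drop(crossprod(X, y - stats::plogis(drop(X %*% beta)))))) < 1e-8 ||
        rel < 1e-10) {
      converged <- TRUE
      break
    }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  # separation: the likelihood plateaus while every observation is
  # predicted (numerically) perfectly, so the MLE lies at infinity
  if (!separation && all(abs(y - mu) < 1e-4)) separation <- TRUE
  if (separation) {
    warning("quasi-complete separation detected; returning partial fit")
  } else if (!converged) {
    stop_dect("logistic fit did not converge in 100 iterations",
              "dectbmd_nonconvergence")
  }
  info <- crossprod(X, X * (mu * (1 - mu)))
  vcov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, k, k))
  se <- sqrt(diag(vcov))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  zstat <- beta / se
  p0 <- mean(y)
  ll_null <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  ll_full <- ll_old
  lr <- 2 * (ll_full - ll_null)
  coefs <- data.frame(term = colnames(X),
                      estimate = beta, se = se, z = zstat,
                      p = 2 * stats::pnorm(-abs(zstat)),
                      or = exp(beta),
                      or_lo = exp(beta - z * se),
                      or_hi = exp(beta + z * se),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    coefficients = coefs,
    loglik = ll_full, loglik_null = ll_null,
    lr_chisq = lr, lr_df = k - 1,
    lr_p = stats::pchisq(lr, k - 1, lower.tail = FALSE),
    nagelkerke_r2 = nagelkerke_r2(ll_null, ll_full, n),
    model_auc = empirical_roc(mu, y, direction = "higher_positive")$auc,
    fitted = mu, n = n,
    iterations = iter, converged = converged, separation = separation
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic regression (n = %d, %d iterations%s)\n", x$n,
              x$iterations,
              if (x$separation) ", SEPARATION" else ""))
  print(transform(x$coefficients,
                  estimate = signif(estimate, 5), se = signif(se, 4),
                  z = signif(z, 4), p = signif(p, 4), or = signif(or, 5),
                  or_lo = signif(or_lo, 5), or_hi = signif(or_hi, 5)),
        row.names = FALSE)
  cat(sprintf("LR chi2 = %.3f (df %d, p = %.3g); Nagelkerke R2 = %.4f; AUC = %.3f\n",
              x$lr_chisq, x$lr_df, x$lr_p, x$nagelkerke_r2, x$model_auc))
  invisible(x)
}

#' Nagelkerke's rescaled R-squared
#'
#' `[1 - (L0/L1)^(2/n)] / [1 - L0^(2/n)]` with `L0`, `L1` the null and
#' full-model likelihoods, computed on the log scale for stability; 0 when
#' the likelihoods are equal, approaching 1 as the fit becomes perfect.
#'
#' @param loglik_null,loglik_full Null and full-model log-likelihoods
#'   (`loglik_full >= loglik_null`).
#' @param n Number of observations.
#' @return Value in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(loglik_null, loglik_full, n) {
  assert_finite(loglik_null, "loglik_null")
  assert_finite(loglik_full, "loglik_full")
  if (loglik_full < loglik_null - 1e-9) {
    stop_dect("loglik_full must be >= loglik_null", "dectbmd_invalid_input")
  }
  cox_snell <- 1 - exp(2 / n * (loglik_null - loglik_full))
  max_r2 <- 1 - exp(2 / n * loglik_null)
  if (max_r2 <= 0) return(0)
  min(1, max(0, cox_snell / max_r2))
}
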