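# ROC analysis, Youden cut-off, and diagnostic-accuracy metrics ------------

#' Empirical ROC curve with trapezoid AUC and DeLong CI
#'
#' Computes the full empirical ROC of a continuous score against a binary
#' outcome. Candidate thresholds are the midpoints between consecutive
#' sorted unique scores plus `-Inf`/`+Inf` sentinels. Under the default
#' `"lower_positive"` direction (low BMD flags the at-risk patient) a
#' subject is test-positive iff its score is strictly below the threshold.
#' The AUC is the trapezoid area under the curve, which equals the
#' Mann-Whitney concordance probability with ties counted 1/2. The CI is
#' DeLong's by default, or a seeded stratified bootstrap.
#'
#' @param scores Numeric scores (e.g. BMD in mg/cm3).
#' @param labels 0/1 or logical outcome (1 = event, e.g. fracture).
#' @param direction `"lower_positive"` (default) or `"higher_positive"`.
#' @param ci_level Confidence level for the AUC CI (default 0.95).
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param boot_reps,boot_seed Bootstrap replicates and seed (used only for
#'   `ci_method = "bootstrap"`).
#' @return An object of class `roc_result`: list with `thresholds`,
#'   `sensitivity`, `specificity`, `auc`, `auc_ci`
#'   (`level`, `lo`, `hi`), `direction`, `n_pos`, `n_neg`.
#' @export
empirical_roc <- function(scores, labels,
                          direction = c("lower_positive", "higher_positive"),
                          ci_level = 0.95,
                          ci_method = c("delong", "bootstrap"),
                          boot_reps = 2000, boot_seed = 1) {
  direction <- match.arg(direction)
  ci_method <- match.arg(ci_method)
  assert_finite(scores, "scores")
  labels <- as.integer(labels)
  if (length(labels) != length(scores) || !all(labels %in% c(0L, 1L))) {
    stop_dect("labels must be 0/1 and match scores in length", "dectbmd_invalid_input")
  }
  if (length(unique(labels)) < 2) {
    stop_dect("degenerate labels: both classes must be present",
              "dectbmd_degenerate_labels")
  }
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos); nn <- length(neg)
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  # cumulative class counts below each threshold (thresholds interleave the
  # unique scores, so "strictly below" vs "at or below" coincide here)
  cum_pos <- c(0, cumsum(tabulate(match(pos, u), nbins = length(u))))
  cum_neg <- c(0, cumsum(tabulate(match(neg, u), nbins = length(u))))
  if (direction == "lower_positive") {
    sens <- cum_pos / m
    spec <- 1 - cum_neg / nn
  } else {
    sens <- rev((m - cum_pos) / m)
    spec <- rev(cum_neg / nn)
    thr <- rev(thr)
  }
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  ci <- switch(ci_method,
    delong = delong_ci(pos, neg, direction, auc, ci_level),
    bootstrap = bootstrap_auc_ci(scores, labels, direction, ci_level,
                                 boot_reps, boot_seed))
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc,
                 auc_ci = list(level = ci_level, lo = ci[1], hi = ci[2]),
                 direction = direction,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "roc_result")
}

delong_ci <- function(pos, neg, direction, auc, level) {
  # midrank identity: sum_j psi(x_i, y_j) = rank of x_i in the pooled
  # sample minus its rank among the cases (Sun & Xu fast DeLong)
  if (direction == "lower_positive") { pos <- -pos; neg <- -neg }
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg))
  v10 <- (r_all[seq_len(m)] - rank(pos)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(neg)) / m
  v <- if (m > 1) stats::var(v10) / m else 0
  v <- v + if (n > 1) stats::var(v01) / n else 0
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(v)
  c(max(0, auc - z * se), min(1, auc + z * se))
}

bootstrap_auc_ci <- function(scores, labels, direction, level, reps, seed) {
  ip <- which(labels == 1); inn <- which(labels == 0)
  aucs <- with_stream_seed(seed, "auc_boot", vapply(seq_len(reps), function(r) {
    bp <- sample(ip, replace = TRUE)
    bn <- sample(inn, replace = TRUE)
    mw_auc(scores[bp], scores[bn], direction)
  }, numeric(1)))
  unname(stats::quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

# Mann-Whitney AUC via rank sums (O(n log n)); used by the bootstrap.
mw_auc <- function(pos, neg, direction) {
  if (direction == "lower_positive") { tmp <- pos; pos <- -tmp; neg <- -neg }
  r <- rank(c(pos, neg))
  m <- length(pos)
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * length(neg))
}

#' Youden-optimal cut-off of an ROC curve
#'
#' Maximises Youden's J = sensitivity + specificity - 1 over the ROC's
#' thresholds. Ties (within 1e-12) are broken toward higher sensitivity
#' (the screening context favours catching at-risk patients), then toward
#' the lower threshold.
#'
#' @param roc An [empirical_roc()] result.
#' @return List with `threshold`, `j`, `sensitivity`, `specificity`.
#' @export
youden_optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  j <- roc$sensitivity + roc$specificity - 1
  cand <- which(j >= max(j) - 1e-12)
  cand <- cand[roc$sensitivity[cand] >= max(roc$sensitivity[cand]) - 1e-12]
  best <- cand[which.min(roc$thresholds[cand])]
  list(threshold = roc$thresholds[best], j = j[best],
       sensitivity = roc$sensitivity[best],
       specificity = roc$specificity[best])
}

#' Confusion counts from a BMD cut-off
#'
#' Applies the at-risk rule (test-positive iff `bmd < cutoff`, strict, for
#' the lower-positive direction) and tabulates predictions against
#' observed outcomes.
#'
#' @param bmd Numeric BMD values.
#' @param cutoff Decision threshold (mg/cm3).
#' @param outcomes 0/1 outcome flags.
#' @param direction `"lower_positive"` (default) or `"higher_positive"`
#'   (positive iff `bmd > cutoff`).
#' @return List with `predicted` (0/1 vector) and `counts`
#'   (`tp`, `fn`, `fp`, `tn`).
#' @export
apply_cutoff <- function(bmd, cutoff, outcomes,
                         direction = c("lower_positive", "higher_positive")) {
  direction <- match.arg(direction)
  assert_finite(bmd, "bmd"); assert_finite(cutoff, "cutoff")
  outcomes <- as.integer(outcomes)
  predicted <- if (direction == "lower_positive") {
    as.integer(bmd < cutoff)
  } else {
    as.integer(bmd > cutoff)
  }
  list(predicted = predicted,
       counts = confusion_counts(tp = sum(predicted == 1 & outcomes == 1),
                                 fn = sum(predicted == 0 & outcomes == 1),
                                 fp = sum(predicted == 1 & outcomes == 0),
                                 tn = sum(predicted == 0 & outcomes == 0)))
}

#' @rdname apply_cutoff
#' @param tp,fn,fp,tn Non-negative integer cell counts.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  v <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(v < 0) || any(v != round(v))) {
    stop_dect("confusion counts must be non-negative integers",
              "dectbmd_invalid_input")
  }
  structure(as.list(v), class = "confusion_counts")
}

# Clopper-Pearson exact binomial CI (proportion scale).
clopper_pearson <- function(x, n, level = 0.95) {
  a <- 1 - level
  lo <- ifelse(x == 0, 0, stats::qbeta(a / 2, x, n - x + 1))
  hi <- ifelse(x == n, 1, stats::qbeta(1 - a / 2, x + 1, n - x))
  cbind(lo = lo, hi = hi)
}

#' Diagnostic-accuracy metrics with exact binomial CIs
#'
#' Sensitivity, specificity, PPV and NPV from a 2x2 confusion table, each
#' with its Clopper-Pearson exact CI, all on the percent scale. A
#' predictive value with a zero denominator is returned as `NA` (flagged
#' undefined) while the remaining metrics are still computed.
#'
#' @param counts A [confusion_counts()] object.
#' @param ci_level Confidence level (default 0.95).
#' @return A data frame with one row per metric: `metric`, `estimate_pct`,
#'   `ci_lo_pct`, `ci_hi_pct`, `numerator`, `denominator`.
#' @export
diagnostic_metrics <- function(counts, ci_level = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, {
    if (tp + fn < 1 || fp + tn < 1) {
      stop_dect("both outcome margins must be >= 1", "dectbmd_invalid_input")
    }
    num <- c(sensitivity = tp, specificity = tn, ppv = tp, npv = tn)
    den <- c(sensitivity = tp + fn, specificity = tn + fp,
             ppv = tp + fp, npv = tn + fn)
    est <- ifelse(den > 0, 100 * num / den, NA_real_)
    ci <- matrix(NA_real_, 4, 2)
    ok <- den > 0
    ci[ok, ] <- 100 * clopper_pearson(num[ok], den[ok], ci_level)
    data.frame(metric = names(num),
               estimate_pct = unname(est),
               ci_lo_pct = ci[, 1], ci_hi_pct = ci[, 2],
               numerator = unname(num), denominator = unname(den),
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

#' Classify a volumetric BMD value into ACR QCT bands
#'
#' Bands: below 80 mg/cm3 (osteoporosis range), 80-120 (osteopenia range,
#' boundaries inclusive), above 120 (normal). The inclusive-osteopenic
#' boundary convention is a documented choice; the guideline values name
#' the band edges without stating boundary handling.
#'
#' @param bmd Numeric BMD values (mg/cm3).
#' @return Factor with levels `below_80`, `osteopenic_80_120`,
#'   `above_120`.
#' @export
classify_acr <- function(bmd) {
  assert_finite(bmd, "bmd")
  factor(ifelse(bmd < 80, "below_80",
                ifelse(bmd <= 120, "osteopenic_80_120", "above_120")),
         levels = c("below_80", "osteopenic_80_120", "above_120"))
}

#' Welch / Student unpaired two-sample t-test
#'
#' Thin wrapper over [stats::t.test()] (Welch by default; the pooled
#' Student variant is retained for sensitivity analysis). When both groups
#' have zero variance the test is degenerate: equal means return `p = 1`,
#' unequal means `p = 0` (documented convention).
#'
#' @param a,b Numeric samples (each n >= 2).
#' @param variant `"welch"` (default) or `"student"`.
#' @return List with `t`, `df`, `p`.
#' @export
unpaired_t_test <- function(a, b, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  assert_finite(a, "a"); assert_finite(b, "b")
  if (length(a) < 2 || length(b) < 2) {
    stop_dect("each group needs n >= 2", "dectbmd_invalid_input")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (eq) 0 else Inf,
                df = length(a) + length(b) - 2,
                p = if (eq) 1 else 0))
  }
  tt <- stats::t.test(a, b, var.equal = (variant == "student"))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by summing all hypergeometric table probabilities not
#' exceeding the observed one (the standard convention, as implemented by
#' [stats::fisher.test()], which this wraps).
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return Two-sided p-value.
#' @export
fishers_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) ||
      any(table != round(table))) {
    stop_dect("need a 2x2 table of non-negative integers",
              "dectbmd_invalid_input")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_dect("undefined test: a table margin is zero", "dectbmd_invalid_input")
  }
  stats::fisher.test(table)$p.value
}
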