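# ROC analysis, Youden cut-off, diagnostic metrics, group tests

test_that("ROC handles perfect separation and all-tied scores", {
  roc <- empirical_roc(c(1, 2, 3, 4, 5), c(1, 1, 1, 0, 0))
  expect_equal(roc$auc, 1)
  opt <- youden_optimal_cutoff(roc)
  expect_equal(opt$j, 1)
  expect_equal(opt$threshold, 3.5)

  tied <- empirical_roc(rep(7, 10), rep(c(0, 1), 5))
  expect_equal(tied$auc, 0.5)

  expect_error(empirical_roc(1:5, rep(1, 5)),
               class = "dectbmd_degenerate_labels")
})

test_that("trapezoid AUC equals brute-force pairwise concordance", {
  set.seed(14)
  for (r in 1:12) {
    n <- sample(20:200, 1)
    scores <- round(rnorm(n, 100, 30), sample(0:2, 1))  # induce ties
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(labels)) < 2) next
    for (dir in c("lower_positive", "higher_positive")) {
      roc <- empirical_roc(scores, labels, direction = dir)
      oracle <- concordance_auc(scores[labels == 1], scores[labels == 0], dir)
      expect_equal(roc$auc, oracle, tolerance = 1e-12)
    }
  }
})

test_that("reversing the ROC direction maps AUC to 1 - AUC", {
  set.seed(15)
  scores <- round(rnorm(80, 100, 20), 1)
  labels <- rbinom(80, 1, 0.4)
  a_lo <- empirical_roc(scores, labels, "lower_positive")$auc
  a_hi <- empirical_roc(scores, labels, "higher_positive")$auc
  expect_equal(a_lo + a_hi, 1, tolerance = 1e-12)
})

test_that("AUC and DeLong CI agree with an independent implementation", {
  set.seed(16)
  scores <- rnorm(120, 100, 25)
  labels <- rbinom(120, 1, 0.5)
  roc <- empirical_roc(scores, labels, "higher_positive")
  pr <- suppressMessages(pROC::roc(labels, scores, direction = "<"))
  expect_equal(roc$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  ci <- suppressMessages(pROC::ci.auc(pr, method = "delong"))
  expect_equal(roc$auc_ci$lo, ci[1], tolerance = 1e-9)
  expect_equal(roc$auc_ci$hi, ci[3], tolerance = 1e-9)
  # bootstrap CI is seeded and reproducible
  b1 <- empirical_roc(scores, labels, "higher_positive",
                      ci_method = "bootstrap", boot_reps = 200, boot_seed = 3)
  b2 <- empirical_roc(scores, labels, "higher_positive",
                      ci_method = "bootstrap", boot_reps = 200, boot_seed = 3)
  expect_identical(b1$auc_ci, b2$auc_ci)
})

test_that("Youden argmax equals an exhaustive threshold scan", {
  set.seed(17)
  for (r in 1:8) {
    n <- sample(30:150, 1)
    scores <- round(rnorm(n, 95, 25), 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    roc <- empirical_roc(scores, labels)
    opt <- youden_optimal_cutoff(roc)
    # brute force over the same candidate thresholds
    j_all <- vapply(roc$thresholds, function(t) {
      mean(scores[labels == 1] < t) + mean(scores[labels == 0] >= t) - 1
    }, numeric(1))
    expect_equal(opt$j, max(j_all), tolerance = 1e-12)
    # the attained (sens, spec) realises the maximal J
    expect_equal(opt$sensitivity + opt$specificity - 1, opt$j)
  }
})

test_that("diagnostic metrics reproduce the study's confusion fractions", {
  m <- diagnostic_metrics(confusion_counts(tp = 47, fn = 8, fp = 4, tn = 33))
  est <- setNames(m$estimate_pct, m$metric)
  expect_equal(unname(est["sensitivity"]), 100 * 47 / 55, tolerance = 1e-12)
  expect_equal(unname(est["specificity"]), 100 * 33 / 37, tolerance = 1e-12)
  expect_equal(round(est[["sensitivity"]], 2), 85.45)
  expect_equal(round(est[["specificity"]], 2), 89.19)
  expect_equal(round(est[["ppv"]], 1), 92.2)
  expect_equal(round(est[["npv"]], 1), 80.5)
  # exact CIs agree with stats::binom.test (Clopper-Pearson)
  bt <- binom.test(47, 55)$conf.int
  expect_equal(m$ci_lo_pct[1], 100 * bt[1], tolerance = 1e-9)
  expect_equal(m$ci_hi_pct[1], 100 * bt[2], tolerance = 1e-9)
  # perfect classifier
  all100 <- diagnostic_metrics(confusion_counts(10, 0, 0, 7))
  expect_true(all(all100$estimate_pct == 100))
  # zero PPV denominator flagged undefined, others intact
  nopos <- diagnostic_metrics(confusion_counts(0, 5, 0, 5))
  expect_true(is.na(nopos$estimate_pct[nopos$metric == "ppv"]))
  expect_equal(nopos$estimate_pct[nopos$metric == "specificity"], 100)
})

test_that("Clopper-Pearson intervals reach nominal coverage", {
  set.seed(18)
  n <- 55; p <- 0.85
  x <- rbinom(1e4, n, p)
  lo <- ifelse(x == 0, 0, qbeta(0.025, x, n - x + 1))
  hi <- ifelse(x == n, 1, qbeta(0.975, x + 1, n - x))
  covered <- mean(lo <= p & p <= hi)
  expect_gte(covered, 0.95)
  # the package's metric CIs use exactly this construction
  m <- diagnostic_metrics(confusion_counts(tp = 47, fn = 8, fp = 4, tn = 33))
  expect_equal(m$ci_lo_pct[1], 100 * qbeta(0.025, 47, 9), tolerance = 1e-12)
})

test_that("cut-off application counts the confusion table correctly", {
  bmd <- c(60, 93.7, 94, 100, 85, 120)
  outc <- c(1, 1, 0, 0, 1, 0)
  res <- apply_cutoff(bmd, 93.7, outc)
  # strict rule: a value equal to the cut-off is test-negative
  expect_equal(res$predicted, c(1, 0, 0, 0, 1, 0))
  expect_equal(unclass(res$counts)[c("tp", "fn", "fp", "tn")],
               list(tp = 2, fn = 1, fp = 0, tn = 3))
  # all below the cut-off -> all positive
  expect_true(all(apply_cutoff(c(10, 20), 50, c(1, 0))$predicted == 1))
  # hand recount on a random cohort
  set.seed(19)
  b <- runif(200, 40, 180); y <- rbinom(200, 1, 0.4)
  cnt <- apply_cutoff(b, 93.7, y)$counts
  expect_equal(cnt$tp, sum(b < 93.7 & y == 1))
  expect_equal(cnt$tn, sum(b >= 93.7 & y == 0))
})

test_that("ACR band classification uses inclusive osteopenic boundaries", {
  expect_equal(as.character(classify_acr(76.3)), "below_80")
  expect_equal(as.character(classify_acr(123.9)), "above_120")
  expect_equal(as.character(classify_acr(c(80, 120))),
               rep("osteopenic_80_120", 2))
  expect_equal(as.character(classify_acr(119.99)), "osteopenic_80_120")
})

test_that("t-test matches the textbook Welch formulas", {
  set.seed(20)
  a <- rnorm(14, 100, 15); b <- rnorm(9, 90, 22)
  tt <- unpaired_t_test(a, b)
  se2 <- var(a) / length(a) + var(b) / length(b)
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / length(a))^2 / (length(a) - 1) +
                        (var(b) / length(b))^2 / (length(b) - 1))
  expect_equal(tt$t, t_hand, tolerance = 1e-10)
  expect_equal(tt$df, df_hand, tolerance = 1e-10)
  expect_equal(tt$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-10)
  # identical constant groups: p = 1 convention
  expect_equal(unpaired_t_test(rep(5, 4), rep(5, 4))$p, 1)
  # near-identical constants with separated means
  expect_lt(unpaired_t_test(c(0, 0, 0, 0), c(10, 10, 10, 10.0001))$p, 1e-6)
  # Student variant equals the pooled-variance formula
  ts <- unpaired_t_test(a, b, variant = "student")
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  expect_equal(ts$t, (mean(a) - mean(b)) /
                 sqrt(sp2 * (1 / length(a) + 1 / length(b))), tolerance = 1e-10)
})

test_that("Fisher's exact test equals hypergeometric enumeration", {
  # [[5,0],[0,5]]: only the two extreme tables have probability <= observed
  expect_equal(fishers_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fishers_exact_2x2(matrix(c(1, 1, 1, 1), 2)), 1)
  # brute-force enumeration oracle over all tables with fixed margins
  set.seed(22)
  for (r in 1:6) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
    p_obs <- dhyper(tab[1, 1], rs[1], rs[2], cs[1])
    ks <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
    probs <- dhyper(ks, rs[1], rs[2], cs[1])
    p_enum <- sum(probs[probs <= p_obs * (1 + 1e-7)])
    expect_equal(fishers_exact_2x2(tab), p_enum, tolerance = 1e-9)
  }
  expect_error(fishers_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               class = "dectbmd_invalid_input")
})
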