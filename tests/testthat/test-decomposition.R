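# Two-energy decomposition: forward model, inversion, BMD conversion

test_that("forward model reproduces hand-evaluated linear expressions", {
  c0 <- default_constants()
  # fraction-free baseline: all fraction terms vanish
  base <- forward_model(0, 0, c0)
  expect_equal(base$hu_lo, c0$gamma_lo * c0$g + c0$delta_lo)
  expect_equal(base$hu_hi, c0$gamma_hi * c0$g + c0$delta_hi)

  # identity-like constants at the low energy: unit slope in v_tb, zero
  # slope in v_f, zero baseline (the high-energy row just keeps the
  # system non-singular)
  ci <- dect_constants(mu_lo = 1 + 10 * 1.02, mu_hi = 2 + 10 * 1.02,
                       gamma_lo = 10, gamma_hi = 10,
                       beta_lo = 10 * 1.02 / 0.92,
                       beta_hi = (1 + 10 * 1.02) / 0.92,
                       delta_lo = -10 * 1.02)
  expect_equal(forward_model(0.25, 0.40, ci)$hu_lo, 0.25)

  # default constants at (0.25, 0.40): frozen independent evaluation of the
  # two linear expressions (slopes 1985/-125 and 1185/-105, baseline 15)
  hu <- forward_model(0.25, 0.40, c0)
  expect_equal(hu$hu_lo, 461.25, tolerance = 1e-12)
  expect_equal(hu$hu_hi, 269.25, tolerance = 1e-12)

  expect_error(forward_model(NA_real_, 0, c0), class = "dectbmd_invalid_input")
})

test_that("inversion solves the system and flags out-of-simplex solutions", {
  c0 <- default_constants()
  base <- forward_model(0, 0, c0)
  vf <- invert_decomposition(base$hu_lo, base$hu_hi, c0)
  expect_equal(vf$v_tb, 0, tolerance = 1e-12)
  expect_equal(vf$v_f, 0, tolerance = 1e-12)
  expect_true(vf$valid)

  # negative matrix fraction is returned but flagged, never clipped
  lowhu <- forward_model(-0.05, 0.3, c0)
  out <- invert_decomposition(lowhu$hu_lo, lowhu$hu_hi, c0)
  expect_false(out$valid)
  expect_equal(out$v_tb, -0.05, tolerance = 1e-9)

  expect_error(invert_decomposition(Inf, 0, c0), class = "dectbmd_invalid_input")
})

test_that("round-trip identity holds over the simplex for random constants", {
  set.seed(42)
  worst <- 0
  for (r in 1:10) {
    cc <- random_constants()
    u <- matrix(runif(2 * 100), ncol = 2)
    keep <- rowSums(u) <= 1
    v_tb <- u[keep, 1]; v_f <- u[keep, 2]
    hu <- forward_model(v_tb, v_f, cc)
    back <- invert_decomposition(hu$hu_lo, hu$hu_hi, cc, hu_range = NULL)
    worst <- max(worst, abs(back$v_tb - v_tb), abs(back$v_f - v_f))
    expect_true(all(back$valid))
  }
  expect_lt(worst, 1e-10)
})

test_that("singular calibrations are rejected everywhere", {
  # rank-1 coefficient matrix: high-energy row proportional to low-energy row
  expect_error(
    dect_constants(mu_lo = 100 + 10 * 1.02, mu_hi = 100 + 10 * 1.02,
                   gamma_lo = 10, gamma_hi = 10,
                   beta_lo = (50 + 10 * 1.02) / 0.92,
                   beta_hi = (50 + 10 * 1.02) / 0.92),
    class = "dectbmd_singular_calibration")
})

test_that("BMD conversion is the printed linear formula", {
  c0 <- default_constants()
  expect_equal(bmd_from_matrix_fraction(0, c0), 0)
  expect_equal(bmd_from_matrix_fraction(1, c0), 1000 * 3.06 / 3.11,
               tolerance = 1e-12)
  expect_equal(1000 * 3.06 / 3.11, 983.9228, tolerance = 1e-4)
  # algebraic inversion: the fraction that maps to the cohort mean 95.4
  v <- 95.4 * 3.11 / (3.06 * 1000)
  expect_equal(bmd_from_matrix_fraction(v, c0), 95.4, tolerance = 1e-12)
  # strictly increasing, slope 1000*l/(1+lam)
  x <- seq(0, 1, length.out = 11)
  b <- bmd_from_matrix_fraction(x, c0)
  expect_true(all(diff(b) > 0))
  expect_equal(b[11] - b[1], 1000 * c0$l / (1 + c0$lam))
})

test_that("ROI measurement equals truth on homogeneous noiseless input", {
  c0 <- default_constants()
  vols <- homogeneous_pair(0.097, 0.5, c0)
  m <- roi_bmd(vols, full_mask(vols$grid), c0)
  expect_equal(m$bmd_mg_cm3, bmd_from_matrix_fraction(0.097, c0),
               tolerance = 1e-12)
  expect_equal(m$n_voxels, prod(vols$grid$dims))
  expect_true(m$valid)

  # all-background (baseline HU) region decomposes to zero BMD at the
  # simplex boundary
  bg <- homogeneous_pair(0, 0, c0)
  mb <- roi_bmd(bg, full_mask(bg$grid), c0)
  expect_equal(mb$bmd_mg_cm3, 0, tolerance = 1e-9)
  expect_equal(mb$v_tb, 0, tolerance = 1e-12)

  # geometry / empty-VOI errors
  other <- voi_mask(array(TRUE, dim = c(5, 5, 5)), voxel_grid(c(5, 5, 5)))
  expect_error(roi_bmd(vols, other, c0), class = "dectbmd_geometry")
  empty <- voi_mask(array(FALSE, dim = vols$grid$dims), vols$grid)
  expect_error(roi_bmd(vols, empty, c0), class = "dectbmd_empty_voi")
})

test_that("noisy ROI estimate is unbiased with sd scaling as sigma/sqrt(N)", {
  c0 <- default_constants()
  sd_hu <- 10
  truth <- bmd_from_matrix_fraction(0.097, c0)
  hu <- forward_model(0.097, 0.5, c0)
  # within 3 propagated SE at N = 10^4
  se4 <- bmd_propagated_se(sd_hu, sd_hu, 1e4, c0)
  set.seed(11)
  est <- mean(bmd_from_matrix_fraction(invert_decomposition(
    mean(hu$hu_lo + rnorm(1e4, 0, sd_hu)),
    mean(hu$hu_hi + rnorm(1e4, 0, sd_hu)), c0)$v_tb, c0))
  expect_lt(abs(est - truth), 3 * se4)

  # Monte-Carlo log-sd vs log-N slope within 10% of -1/2
  Ns <- c(400, 1600, 6400)
  sds <- vapply(Ns, function(N) {
    reps <- vapply(1:300, function(r) {
      v <- invert_decomposition(mean(hu$hu_lo + rnorm(N, 0, sd_hu)),
                                mean(hu$hu_hi + rnorm(N, 0, sd_hu)), c0)
      bmd_from_matrix_fraction(v$v_tb, c0)
    }, numeric(1))
    sd(reps)
  }, numeric(1))
  slope <- coef(lm(log(sds) ~ log(Ns)))[2]
  expect_lt(abs(slope - (-0.5)), 0.05)
  # and each MC sd matches the analytic propagation within 15%
  ana <- vapply(Ns, function(N) bmd_propagated_se(sd_hu, sd_hu, N, c0),
                numeric(1))
  expect_true(all(abs(sds / ana - 1) < 0.15))
})

test_that("voxelwise map recovers plateaus and its mean matches the ROI value", {
  c0 <- default_constants()
  g <- voxel_grid(c(8, 8, 4))
  # two-compartment phantom: inner columns at v_tb 0.15, outer at 0.05
  inner <- array(FALSE, dim = g$dims); inner[3:6, 3:6, ] <- TRUE
  v_tb <- ifelse(inner, 0.15, 0.05)
  v_f <- array(0.4, dim = g$dims)
  hu <- forward_model(as.vector(v_tb), as.vector(v_f), c0)
  vols <- dect_volume_pair(array(hu$hu_lo, g$dims), array(hu$hu_hi, g$dims), g)
  map <- voxelwise_bmd_map(vols, full_mask(g), c0)
  expect_lt(max(abs(map[inner] - bmd_from_matrix_fraction(0.15, c0))), 1e-6)
  expect_lt(max(abs(map[!inner] - bmd_from_matrix_fraction(0.05, c0))), 1e-6)
  # linearity: in-mask mean of the map equals the ROI-mean measurement
  m <- roi_bmd(vols, full_mask(g), c0)
  expect_equal(mean(map), m$bmd_mg_cm3, tolerance = 1e-9)
  # homogeneous phantom: every in-mask voxel equals the ROI value
  vols2 <- homogeneous_pair(0.097, 0.5, c0)
  map2 <- voxelwise_bmd_map(vols2, full_mask(vols2$grid), c0)
  m2 <- roi_bmd(vols2, full_mask(vols2$grid), c0)
  expect_lt(max(abs(map2 - m2$bmd_mg_cm3)), 1e-9)
})
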