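# Shared fixtures and independent oracles for the test suite.

# Random well-conditioned calibration constants (rejection-sampled so the
# 2x2 coefficient matrix is comfortably non-singular).
random_constants <- function() {
  repeat {
    cc <- try(dect_constants(
      mu_lo = runif(1, 1500, 2500), mu_hi = runif(1, 800, 1600),
      gamma_lo = runif(1, 5, 25), gamma_hi = runif(1, 5, 25),
      beta_lo = runif(1, -150, -80), beta_hi = runif(1, -120, -60),
      delta_lo = runif(1, -5, 5), delta_hi = runif(1, -5, 5)),
      silent = TRUE)
    if (!inherits(cc, "try-error") &&
        abs(det(coefficient_matrix(cc))) > 1e3) {
      return(cc)
    }
  }
}

# O(m*n) pairwise Mann-Whitney concordance: the brute-force AUC oracle.
concordance_auc <- function(pos, neg, direction = "lower_positive") {
  s <- 0
  for (x in pos) {
    if (direction == "lower_positive") {
      s <- s + sum(x < neg) + 0.5 * sum(x == neg)
    } else {
      s <- s + sum(x > neg) + 0.5 * sum(x == neg)
    }
  }
  s / (length(pos) * length(neg))
}

# Brute-force morphological erosion by a physical ball (voxel-by-voxel).
erode_bruteforce <- function(mask, margin_mm) {
  d <- mask$grid$dims; sp <- mask$grid$spacing_mm
  r <- floor(margin_mm / sp)
  out <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask$voxels[i, j, k]) next
    keep <- TRUE
    for (dx in -r[1]:r[1]) for (dy in -r[2]:r[2]) for (dz in -r[3]:r[3]) {
      if ((dx * sp[1])^2 + (dy * sp[2])^2 + (dz * sp[3])^2 > margin_mm^2) next
      ii <- i + dx; jj <- j + dy; kk <- k + dz
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3] ||
          !mask$voxels[ii, jj, kk]) { keep <- FALSE; break }
    }
    if (!keep) out[i, j, k] <- FALSE else out[i, j, k] <- TRUE
  }
  out
}

# Small homogeneous noiseless volume pair from given fractions.
homogeneous_pair <- function(v_tb, v_f, cc, dims = c(6, 6, 4)) {
  g <- voxel_grid(dims)
  hu <- forward_model(v_tb, v_f, cc)
  dect_volume_pair(array(hu$hu_lo, dim = dims), array(hu$hu_hi, dim = dims), g)
}

full_mask <- function(grid) voi_mask(array(TRUE, dim = grid$dims), grid)

cohort_covariates <- function(cohort) {
  data.frame(bmd = cohort$bmd_mg_cm3, age = cohort$age_years,
             female = as.integer(cohort$sex == "female"))
}
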