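# Synthetic dual-energy phantoms emulating an L1 vertebra ------------------

#' Specify a synthetic dual-energy vertebra phantom
#'
#' Describes an elliptical-cylinder vertebral body: a homogeneous
#' trabecular interior of known composition, an optional dense cortical
#' shell, and a soft-tissue background, to be imaged through the linear
#' forward model with additive Gaussian HU noise. The defaults emulate an
#' L1-sized body (~21 x 15 mm interior semi-axes would be large for a
#' grid this size; we use 12 x 9 mm on a 48 x 48 x 16 grid at
#' 0.7 x 0.7 x 1 mm) whose interior matrix fraction 0.097 corresponds to
#' the study population's mean BMD of about 95 mg/cm3.
#'
#' @param grid A [voxel_grid()]; default 48 x 48 x 16 at 0.7 x 0.7 x 1 mm.
#' @param center_mm Ellipse centre (x, y) in mm; default grid centre.
#' @param semi_axes_mm Outer semi-axes (a, b) in mm of the vertebral body.
#' @param slices Integer range of axial slices spanned by the body.
#' @param shell_mm Cortical shell thickness (mm); the trabecular interior
#'   is the outer ellipse shrunk by this much.
#' @param shell_v_tb,shell_v_f Composition of the cortical shell.
#' @param v_tb,v_f Trabecular interior composition (volume fractions).
#' @param background_hu Length-2 HU pair (lo, hi) outside the body.
#' @param noise_sd Additive i.i.d. Gaussian HU noise sd (same both
#'   energies); >= 0.
#' @param seed Integer seed; the phantom is a pure function of
#'   (spec, seed).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = voxel_grid(c(48, 48, 16), c(0.7, 0.7, 1)),
                         center_mm = NULL,
                         semi_axes_mm = c(12, 9),
                         slices = 3:14,
                         shell_mm = 1.5,
                         shell_v_tb = 0.5, shell_v_f = 0.05,
                         v_tb = 0.097, v_f = 0.5,
                         background_hu = c(40, 40),
                         noise_sd = 10,
                         seed = 1) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(center_mm)) {
    center_mm <- grid$origin_mm[1:2] +
      (grid$dims[1:2] - 1) / 2 * grid$spacing_mm[1:2]
  }
  if (noise_sd < 0) stop_dect("noise_sd must be >= 0", "dectbmd_invalid_spec")
  fr <- c(shell_v_tb, shell_v_f, v_tb, v_f)
  if (any(fr < 0) || shell_v_tb + shell_v_f > 1 || v_tb + v_f > 1) {
    stop_dect("volume fractions must lie in the unit simplex",
              "dectbmd_invalid_spec")
  }
  # geometry must fit: outer ellipse within grid bounds, slices within range
  xr <- range(axis_coords(grid, 1)); yr <- range(axis_coords(grid, 2))
  if (center_mm[1] - semi_axes_mm[1] < xr[1] - grid$spacing_mm[1] / 2 ||
      center_mm[1] + semi_axes_mm[1] > xr[2] + grid$spacing_mm[1] / 2 ||
      center_mm[2] - semi_axes_mm[2] < yr[1] - grid$spacing_mm[2] / 2 ||
      center_mm[2] + semi_axes_mm[2] > yr[2] + grid$spacing_mm[2] / 2 ||
      min(slices) < 1 || max(slices) > grid$dims[3]) {
    stop_dect("phantom geometry extends outside the grid", "dectbmd_invalid_spec")
  }
  if (semi_axes_mm[1] <= shell_mm || semi_axes_mm[2] <= shell_mm) {
    stop_dect("shell thickness leaves no trabecular interior",
              "dectbmd_invalid_spec")
  }
  structure(list(grid = grid, center_mm = center_mm,
                 semi_axes_mm = semi_axes_mm, slices = as.integer(slices),
                 shell_mm = shell_mm, shell_v_tb = shell_v_tb,
                 shell_v_f = shell_v_f, v_tb = v_tb, v_f = v_f,
                 background_hu = background_hu, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# logical in-plane masks for the outer body and the trabecular interior
phantom_plane_masks <- function(spec) {
  g <- spec$grid
  px <- rep(axis_coords(g, 1), times = g$dims[2])
  py <- rep(axis_coords(g, 2), each = g$dims[1])
  ell <- function(a, b) {
    ((px - spec$center_mm[1]) / a)^2 + ((py - spec$center_mm[2]) / b)^2 <= 1
  }
  outer <- matrix(ell(spec$semi_axes_mm[1], spec$semi_axes_mm[2]),
                  nrow = g$dims[1])
  inner <- matrix(ell(spec$semi_axes_mm[1] - spec$shell_mm,
                      spec$semi_axes_mm[2] - spec$shell_mm),
                  nrow = g$dims[1])
  list(outer = outer, inner = inner)
}

#' Generate a synthetic dual-energy phantom
#'
#' Composes region-wise volume fractions (trabecular interior, cortical
#' shell), maps them to HU with [forward_model()] voxelwise, sets the
#' background to the specified HU pair, and adds i.i.d. Gaussian noise.
#' Deterministic given the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @param c A [dect_constants()] object (default the packaged defaults).
#' @return List with `volumes` (a `dect_volume_pair`), `mask` (the true
#'   trabecular `voi_mask`), and `truth` (interior fractions and the
#'   expected BMD in mg/cm3).
#' @export
generate_phantom <- function(spec, c = default_constants()) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  pm <- phantom_plane_masks(spec)
  lo <- array(spec$background_hu[1], dim = g$dims)
  hi <- array(spec$background_hu[2], dim = g$dims)
  hu_in <- forward_model(spec$v_tb, spec$v_f, c)
  hu_sh <- forward_model(spec$shell_v_tb, spec$shell_v_f, c)
  mask <- array(FALSE, dim = g$dims)
  shell <- pm$outer & !pm$inner
  for (k in spec$slices) {
    sl_lo <- lo[, , k]; sl_hi <- hi[, , k]
    sl_lo[shell] <- hu_sh$hu_lo; sl_hi[shell] <- hu_sh$hu_hi
    sl_lo[pm$inner] <- hu_in$hu_lo; sl_hi[pm$inner] <- hu_in$hu_hi
    lo[, , k] <- sl_lo; hi[, , k] <- sl_hi
    mask[, , k] <- pm$inner
  }
  if (spec$noise_sd > 0) {
    nv <- prod(g$dims)
    noise <- with_stream_seed(spec$seed, "phantom_noise",
                              stats::rnorm(2 * nv, 0, spec$noise_sd))
    lo <- lo + array(noise[seq_len(nv)], dim = g$dims)
    hi <- hi + array(noise[nv + seq_len(nv)], dim = g$dims)
  }
  list(volumes = dect_volume_pair(lo, hi, g),
       mask = voi_mask(mask, g),
       truth = list(v_tb = spec$v_tb, v_f = spec$v_f,
                    expected_bmd = bmd_from_matrix_fraction(spec$v_tb, c),
                    shell_v_tb = spec$shell_v_tb, shell_v_f = spec$shell_v_f))
}

#' Elliptical VOI contours for a phantom, with optional jitter
#'
#' Builds a per-slice delineation of the phantom's trabecular interior: a
#' regular polygon inscribed in the interior ellipse shrunk by
#' `margin_mm` (the reader draws inside the cortical rim), optionally with
#' independent radial Gaussian jitter on every vertex to emulate manual
#' delineation variability. Used by the repeatability experiments.
#'
#' @param spec A [phantom_spec()].
#' @param n_vertices Vertices per contour (default 24).
#' @param margin_mm Inward margin from the trabecular boundary (mm).
#' @param jitter_sd_mm Radial jitter sd (mm); 0 for the exact ellipse.
#' @param seed Seed for the jitter stream.
#' @return A [delineation_series()].
#' @export
phantom_voi_contours <- function(spec, n_vertices = 24, margin_mm = 1,
                                 jitter_sd_mm = 0, seed = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  a <- spec$semi_axes_mm[1] - spec$shell_mm - margin_mm
  b <- spec$semi_axes_mm[2] - spec$shell_mm - margin_mm
  if (a <= 0 || b <= 0) {
    stop_dect("margin leaves no contour area", "dectbmd_invalid_spec")
  }
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  nsl <- length(spec$slices)
  jit <- if (jitter_sd_mm > 0) {
    with_stream_seed(seed, "contour_jitter",
                     stats::rnorm(nsl * n_vertices, 0, jitter_sd_mm))
  } else rep(0, nsl * n_vertices)
  contours <- vector("list", nsl)
  for (i in seq_len(nsl)) {
    r <- 1 + jit[(i - 1) * n_vertices + seq_len(n_vertices)] /
      sqrt((a * cos(th))^2 + (b * sin(th))^2)
    contours[[i]] <- list(
      slice = spec$slices[i],
      vertices = cbind(spec$center_mm[1] + r * a * cos(th),
                       spec$center_mm[2] + r * b * sin(th)))
  }
  delineation_series(contours)
}
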