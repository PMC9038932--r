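# Voxel grids, dual-energy volume pairs, and NIfTI I/O ---------------------

#' Define a regular voxel grid
#'
#' @param dims Integer vector of 3 positive dimensions (voxels).
#' @param spacing_mm Numeric vector of 3 positive voxel spacings (mm).
#' @param origin_mm World coordinates (mm) of the centre of voxel
#'   `(1, 1, 1)`; default `c(0, 0, 0)`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(dims, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  dims <- as.integer(dims)
  if (length(dims) != 3 || any(dims < 1)) {
    stop_dect("dims must be 3 positive integers", "dectbmd_invalid_input")
  }
  assert_finite(spacing_mm, "spacing_mm"); assert_finite(origin_mm, "origin_mm")
  if (length(spacing_mm) != 3 || any(spacing_mm <= 0) || length(origin_mm) != 3) {
    stop_dect("spacing_mm must be 3 positive reals; origin_mm 3 reals",
              "dectbmd_invalid_input")
  }
  structure(list(dims = dims, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "voxel_grid")
}

# spacing/origin tolerances allow for the float32 storage of NIfTI headers
same_grid <- function(a, b) {
  isTRUE(all(a$dims == b$dims)) &&
    isTRUE(all(abs(a$spacing_mm - b$spacing_mm) < 1e-5)) &&
    isTRUE(all(abs(a$origin_mm - b$origin_mm) < 1e-4))
}

check_same_grid <- function(a, b) {
  if (!same_grid(a, b)) {
    stop_dect("geometry mismatch: volumes and mask must share one voxel grid",
              "dectbmd_geometry")
  }
  invisible(TRUE)
}

# World coordinates (mm) of voxel centres along one axis (1-based index).
axis_coords <- function(grid, axis) {
  grid$origin_mm[axis] + (seq_len(grid$dims[axis]) - 1) * grid$spacing_mm[axis]
}

#' Pair two co-registered HU volumes on one grid
#'
#' @param lo,hi 3D numeric arrays of HU at the low (90 kVp) and high
#'   (Sn150 kVp) energy; must share the grid's dimensions.
#' @param grid A [voxel_grid()].
#' @return An object of class `dect_volume_pair`.
#' @export
dect_volume_pair <- function(lo, hi, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!identical(dim(lo), as.integer(grid$dims)) ||
      !identical(dim(hi), as.integer(grid$dims))) {
    stop_dect("volume dimensions do not match the grid", "dectbmd_geometry")
  }
  structure(list(lo = lo, hi = hi, grid = grid), class = "dect_volume_pair")
}

grid_affine <- function(grid) {
  m <- diag(4)
  m[1, 1] <- grid$spacing_mm[1]
  m[2, 2] <- grid$spacing_mm[2]
  m[3, 3] <- grid$spacing_mm[3]
  m[1:3, 4] <- grid$origin_mm
  m
}

#' Write / read a volume on a grid as NIfTI-1
#'
#' The grid's spacing and origin are stored in the NIfTI sform. Masks are
#' written as 0/1 integer volumes and read back to logical.
#'
#' @param x A 3D array, or for `write_mask_nifti()` a `voi_mask`.
#' @param grid A [voxel_grid()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `write_*` return `path` invisibly; `read_volume_nifti()` returns
#'   `list(data, grid)`; `read_mask_nifti()` a `voi_mask`.
#' @export
write_volume_nifti <- function(x, grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- grid$spacing_mm
  RNifti::sform(img) <- structure(grid_affine(grid), code = 2L)
  RNifti::qform(img) <- structure(grid_affine(grid), code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  grid <- voxel_grid(dim(img)[1:3],
                     spacing_mm = abs(c(aff[1, 1], aff[2, 2], aff[3, 3])),
                     origin_mm = aff[1:3, 4])
  list(data = array(as.numeric(img), dim = dim(img)[1:3]), grid = grid)
}

#' @rdname write_volume_nifti
#' @export
write_mask_nifti <- function(x, path) {
  stopifnot(inherits(x, "voi_mask"))
  write_volume_nifti(array(as.integer(x$voxels), dim = x$grid$dims),
                     x$grid, path)
}

#' @rdname write_volume_nifti
#' @export
read_mask_nifti <- function(path) {
  v <- read_volume_nifti(path)
  voi_mask(array(v$data != 0, dim = v$grid$dims), v$grid)
}
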