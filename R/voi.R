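# Trabecular VOI masks: contours, rasterisation, erosion, repeatability ----

#' Construct a 3D VOI mask on a grid
#'
#' A boolean occupancy volume marking the trabecular volume of interest.
#' An empty mask is a valid object but is rejected by the analysis
#' functions ([roi_bmd()] and friends), which require at least one voxel.
#'
#' @param voxels Logical 3D array matching the grid's dimensions.
#' @param grid A [voxel_grid()].
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(voxels, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.logical(voxels) || !identical(dim(voxels), as.integer(grid$dims))) {
    stop_dect("voxels must be a logical array with the grid's dimensions",
              "dectbmd_geometry")
  }
  structure(list(voxels = voxels, grid = grid), class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  s <- mask_stats(x)
  cat(sprintf("VOI mask: %d / %d voxels set (%.3f cm3) on %dx%dx%d grid\n",
              s$n_voxels, prod(x$grid$dims), s$volume_cm3,
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3]))
  invisible(x)
}

#' Per-slice closed planar contours of a manual delineation
#'
#' Represents a stack of closed 2D polygons (one or more per slice) drawn
#' in world millimetres, the way a reader outlines trabecular bone slice by
#' slice. Contours must be simple polygons with at least 3 vertices.
#'
#' @param contours List of `list(slice = <1-based slice index>,
#'   vertices = <n x 2 matrix of (x, y) mm>)`.
#' @param axis Slice axis (only `3`, axial, is supported).
#' @return An object of class `delineation_series`.
#' @export
delineation_series <- function(contours, axis = 3) {
  if (axis != 3) stop_dect("only axis = 3 (axial slices) is supported",
                           "dectbmd_invalid_input")
  for (ct in contours) {
    v <- as.matrix(ct$vertices)
    if (nrow(v) < 3) {
      stop_dect("each contour needs >= 3 vertices", "dectbmd_invalid_contour")
    }
    assert_finite(v, "contour vertices")
    if (abs(polygon_area(v)) < 1e-12) {
      stop_dect("contour has zero area", "dectbmd_invalid_contour")
    }
    if (is_self_intersecting(v)) {
      stop_dect("contour is self-intersecting", "dectbmd_invalid_contour")
    }
  }
  structure(list(contours = contours, axis = axis),
            class = "delineation_series")
}

polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq_len(nrow(v))[-1], 1)
  sum(x * y[j] - x[j] * y) / 2
}

# Proper-intersection test over all non-adjacent edge pairs (O(E^2); fine
# for hand-drawn contours).
is_self_intersecting <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  for (a in seq_len(n - 2)) {
    for (b in (a + 1):n) {
      if (b == a + 1 || (a == 1 && b == n)) next
      p1 <- v[a, ]; p2 <- v[j[a], ]; p3 <- v[b, ]; p4 <- v[j[b], ]
      d1 <- orient(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
      d2 <- orient(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
      d3 <- orient(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
      d4 <- orient(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
      if (d1 != d2 && d3 != d4 && d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Even-odd (crossing-number) point-in-polygon, vectorised over points.
points_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  inside <- rep(FALSE, length(px))
  for (e in seq_len(n)) {
    x1 <- v[e, 1]; y1 <- v[e, 2]; x2 <- v[j[e], 1]; y2 <- v[j[e], 2]
    if (y1 == y2) next
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside
}

#' Rasterise a delineation series into a 3D VOI mask
#'
#' Scanline fill per slice: a voxel belongs to the VOI iff its centre lies
#' inside the contour polygon under the even-odd rule; multiple contours on
#' one slice are combined by union. An empty series yields a valid empty
#' mask (unusable for analysis until filled).
#'
#' @param series A [delineation_series()].
#' @param grid A [voxel_grid()].
#' @return A [voi_mask()].
#' @export
contours_to_mask <- function(series, grid) {
  stopifnot(inherits(series, "delineation_series"), inherits(grid, "voxel_grid"))
  vox <- array(FALSE, dim = grid$dims)
  if (length(series$contours) == 0) return(voi_mask(vox, grid))
  cx <- axis_coords(grid, 1)
  cy <- axis_coords(grid, 2)
  px <- rep(cx, times = grid$dims[2])
  py <- rep(cy, each = grid$dims[1])
  for (ct in series$contours) {
    k <- ct$slice
    if (k < 1 || k > grid$dims[3]) {
      stop_dect("contour slice index outside grid", "dectbmd_invalid_contour")
    }
    v <- as.matrix(ct$vertices)
    inside <- points_in_polygon(px, py, v)
    plane <- matrix(inside, nrow = grid$dims[1])
    vox[, , k] <- vox[, , k] | plane
  }
  voi_mask(vox, grid)
}

#' Read / write a delineation series as plain text
#'
#' Schema: lines `slice <k>` start a contour on 1-based slice `k`, followed
#' by one `x y` vertex pair (mm) per line; blank lines separate contours.
#'
#' @param series A [delineation_series()] (for writing).
#' @param path File path.
#' @return `read_contours()` returns a [delineation_series()].
#' @export
write_contours <- function(series, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (ct in series$contours) {
    writeLines(sprintf("slice %d", ct$slice), con)
    v <- as.matrix(ct$vertices)
    writeLines(sprintf("%.9g %.9g", v[, 1], v[, 2]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_contours
#' @export
read_contours <- function(path) {
  lines <- trimws(readLines(path))
  contours <- list(); cur <- NULL; verts <- NULL
  flush_ct <- function() {
    if (!is.null(cur) && !is.null(verts)) {
      contours[[length(contours) + 1]] <<- list(slice = cur, vertices = verts)
    }
  }
  for (ln in lines) {
    if (ln == "") next
    if (startsWith(ln, "slice")) {
      flush_ct()
      cur <- as.integer(strsplit(ln, "\\s+")[[1]][2]); verts <- NULL
    } else {
      xy <- as.numeric(strsplit(ln, "\\s+")[[1]])
      verts <- rbind(verts, xy)
    }
  }
  flush_ct()
  delineation_series(contours)
}

#' Morphological erosion of a VOI mask by a physical margin
#'
#' Erodes by a ball of the given radius in millimetres, respecting
#' anisotropic voxel spacing (the structuring element contains every voxel
#' offset whose physical displacement is within the margin). Voxels outside
#' the grid count as background. The canonical use is shrinking a
#' whole-vertebra outline inward so the cortical rim is excluded and only
#' trabecular bone remains. A margin of 0 is the identity.
#'
#' @param mask A [voi_mask()].
#' @param margin_mm Non-negative erosion radius (mm).
#' @return The eroded [voi_mask()].
#' @export
erode_mask <- function(mask, margin_mm) {
  stopifnot(inherits(mask, "voi_mask"))
  assert_finite(margin_mm, "margin_mm")
  if (margin_mm < 0) stop_dect("margin_mm must be >= 0", "dectbmd_invalid_input")
  if (margin_mm == 0) return(mask)
  sp <- mask$grid$spacing_mm
  r <- floor(margin_mm / sp)
  offs <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  keep <- (offs$dx * sp[1])^2 + (offs$dy * sp[2])^2 + (offs$dz * sp[3])^2 <=
    margin_mm^2
  offs <- offs[keep, , drop = FALSE]
  d <- mask$grid$dims
  out <- mask$voxels
  for (i in seq_len(nrow(offs))) {
    out <- out & shift_array(mask$voxels, c(offs$dx[i], offs$dy[i], offs$dz[i]))
    if (!any(out)) break
  }
  voi_mask(out, mask$grid)
}

# Shift a logical 3D array by integer voxel offsets, padding with FALSE.
shift_array <- function(a, off) {
  d <- dim(a)
  out <- array(FALSE, dim = d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (o >= 0) {
      if (o >= d[ax]) return(out)
      src[[ax]] <- seq_len(d[ax] - o) + o
      dst[[ax]] <- seq_len(d[ax] - o)
    } else {
      if (-o >= d[ax]) return(out)
      src[[ax]] <- seq_len(d[ax] + o)
      dst[[ax]] <- seq_len(d[ax] + o) - o
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Mask summary statistics
#'
#' @param mask A [voi_mask()].
#' @return List with `n_voxels` and `volume_cm3`
#'   (`n_voxels * voxel volume`).
#' @export
mask_stats <- function(mask) {
  stopifnot(inherits(mask, "voi_mask"))
  n <- sum(mask$voxels)
  list(n_voxels = n,
       volume_cm3 = n * prod(mask$grid$spacing_mm) / 1000)
}

#' Repeatability of replicate BMD measurements
#'
#' Summarises agreement across repeated delineations of one vertebra as the
#' coefficient of variation, `100 * sd / mean` with the sample (n-1)
#' standard deviation, together with the maximum pairwise relative
#' difference (largest `100 * |x_i - x_j| / mean(x_i, x_j)` over pairs).
#' Both are reported because "variability" between replicate measurements
#' can be read either way.
#'
#' @param measurements Numeric vector of >= 2 replicate BMD values
#'   (mg/cm3) with positive mean.
#' @return List with `cv_percent` and `max_pairwise_diff_percent`.
#' @export
repeatability_cv <- function(measurements) {
  assert_finite(measurements, "measurements")
  if (length(measurements) < 2) {
    stop_dect("need >= 2 replicate measurements", "dectbmd_insufficient_replicates")
  }
  m <- mean(measurements)
  if (m <= 0) stop_dect("mean of measurements must be positive",
                        "dectbmd_invalid_input")
  pr <- utils::combn(measurements, 2)
  maxrel <- max(200 * abs(pr[1, ] - pr[2, ]) / (pr[1, ] + pr[2, ]))
  list(cv_percent = 100 * stats::sd(measurements) / m,
       max_pairwise_diff_percent = maxrel)
}
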