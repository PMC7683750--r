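#' 3D image volume with voxel geometry
#'
#' A `volume_grid` is the basic image carrier of the package: a 3D scalar
#' array plus voxel spacing and origin in millimetres. The same container
#' holds CT numbers (HU), 511-keV attenuation coefficients (cm^-1), activity
#' concentrations (Bq/ml), reconstructed PET values and arbitrary MR
#' intensities; the `unit` attribute records which. The axial direction is
#' the last array index.
#'
#' @param values 3D numeric array.
#' @param spacing numeric(3), voxel size in mm per axis; strictly positive.
#' @param origin numeric(3), position of the first voxel centre in mm.
#' @param unit optional unit label ("HU", "cm^-1", "Bq/ml", ...).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        unit = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite numbers (mm)")
  structure(list(values = values, spacing = spacing, origin = origin,
                 unit = unit),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %s mm%s\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              if (is.null(x$unit)) "" else paste0(", unit ", x$unit)))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

#' Integer tissue segmentation on a volume lattice
#'
#' @param labels 3D integer array.
#' @param spacing,origin voxel geometry, as in [volume_grid()].
#' @param legend named integer vector mapping tissue name to label id.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      legend = tissue_legend()) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3D array")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), unname(legend))
  if (length(bad))
    stop("labels outside legend: ", paste(bad, collapse = ", "))
  structure(list(labels = labels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), legend = legend),
            class = "label_map")
}

#' Default tissue legend for the pelvis phantom
#'
#' Label ids for the structures the phantom draws and the synthetic-CT
#' pipeline votes over. Background outside the body is `air`.
#' @return Named integer vector.
#' @export
tissue_legend <- function() {
  c(air = 0L, fat = 1L, soft_tissue = 2L, bone_cortical = 3L,
    bone_trabecular = 4L, bladder = 5L, prostate = 6L, bowel_gas = 7L)
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_map> %d x %d x %d voxels, %d labels in legend\n",
              d[1], d[2], d[3], length(x$legend)))
  invisible(x)
}

#' @export
dim.label_map <- function(x) dim(x$labels)

#' Test that two volumes share one lattice
#'
#' @param a,b `volume_grid` or `label_map` objects.
#' @param tol tolerance on spacing/origin in mm.
#' @return Logical.
#' @export
same_lattice <- function(a, b, tol = 1e-6) {
  da <- if (inherits(a, "label_map")) dim(a$labels) else dim(a$values)
  db <- if (inherits(b, "label_map")) dim(b$labels) else dim(b$values)
  identical(da, db) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

stop_if_lattice_mismatch <- function(a, b, what = "volumes") {
  if (!same_lattice(a, b))
    stop(what, " must share the same lattice (shape, spacing, origin)")
  invisible(TRUE)
}

## ---- interpolation -------------------------------------------------------

## Gather arr at fractional 1-based voxel coordinates (n x 3 matrix).
## Coordinates are clamped to the valid range (replicate-edge behaviour).
interp_trilinear <- function(arr, coords) {
  d <- dim(arr)
  x <- pmin(pmax(coords[, 1], 1), d[1])
  y <- pmin(pmax(coords[, 2], 1), d[2])
  z <- pmin(pmax(coords[, 3], 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1L); x0[d[1] == 1L] <- 1
  y0 <- pmin(floor(y), d[2] - 1L); y0[d[2] == 1L] <- 1
  z0 <- pmin(floor(z), d[3] - 1L); z0[d[3] == 1L] <- 1
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  nxy <- d[1] * d[2]
  idx <- function(i, j, k) (k - 1) * nxy + (j - 1) * d[1] + i
  v <- as.vector(arr)
  (v[idx(x0, y0, z0)] * (1 - fx) * (1 - fy) * (1 - fz) +
   v[idx(x1, y0, z0)] * fx       * (1 - fy) * (1 - fz) +
   v[idx(x0, y1, z0)] * (1 - fx) * fy       * (1 - fz) +
   v[idx(x1, y1, z0)] * fx       * fy       * (1 - fz) +
   v[idx(x0, y0, z1)] * (1 - fx) * (1 - fy) * fz +
   v[idx(x1, y0, z1)] * fx       * (1 - fy) * fz +
   v[idx(x0, y1, z1)] * (1 - fx) * fy       * fz +
   v[idx(x1, y1, z1)] * fx       * fy       * fz)
}

## Precompute trilinear gather indices/weights for repeated interpolation of
## different arrays at the same coordinates.
precompute_interp <- function(coords, d) {
  x <- pmin(pmax(coords[, 1], 1), d[1])
  y <- pmin(pmax(coords[, 2], 1), d[2])
  z <- pmin(pmax(coords[, 3], 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1L); x0[d[1] == 1L] <- 1
  y0 <- pmin(floor(y), d[2] - 1L); y0[d[2] == 1L] <- 1
  z0 <- pmin(floor(z), d[3] - 1L); z0[d[3] == 1L] <- 1
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  nxy <- d[1] * d[2]
  idx <- function(i, j, k) (k - 1) * nxy + (j - 1) * d[1] + i
  list(i = cbind(idx(x0, y0, z0), idx(x1, y0, z0), idx(x0, y1, z0),
                 idx(x1, y1, z0), idx(x0, y0, z1), idx(x1, y0, z1),
                 idx(x0, y1, z1), idx(x1, y1, z1)),
       w = cbind((1 - fx) * (1 - fy) * (1 - fz), fx * (1 - fy) * (1 - fz),
                 (1 - fx) * fy * (1 - fz), fx * fy * (1 - fz),
                 (1 - fx) * (1 - fy) * fz, fx * (1 - fy) * fz,
                 (1 - fx) * fy * fz, fx * fy * fz))
}

apply_interp <- function(ip, arr) {
  v <- as.vector(arr)
  out <- ip$w[, 1] * v[ip$i[, 1]]
  for (c in 2:8) out <- out + ip$w[, c] * v[ip$i[, c]]
  out
}

interp_nearest <- function(arr, coords) {
  d <- dim(arr)
  i <- pmin(pmax(round(coords[, 1]), 1), d[1])
  j <- pmin(pmax(round(coords[, 2]), 1), d[2])
  k <- pmin(pmax(round(coords[, 3]), 1), d[3])
  arr[cbind(i, j, k)]
}

## 1-based voxel index grid as an (nvox x 3) matrix, column-major order.
voxel_index_grid <- function(d) {
  cbind(rep.int(seq_len(d[1]), d[2] * d[3]),
        rep.int(rep(seq_len(d[2]), each = d[1]), d[3]),
        rep(seq_len(d[3]), each = d[1] * d[2]))
}

## ---- displacement fields -------------------------------------------------

#' Apply a displacement field to a volume
#'
#' The field `u` (array of dim `c(dim(vol), 3)`, mm) is interpreted in the
#' pull-back convention: `out(x) = vol(x + u(x))`. Intensities use trilinear
#' interpolation, labels nearest-neighbour.
#'
#' @param vol `volume_grid` or `label_map`.
#' @param field displacement array, mm, dim `c(nx, ny, nz, 3)`.
#' @param interpolation "linear" or "nearest" (label maps always nearest).
#' @return Warped object of the same class.
#' @export
warp_volume <- function(vol, field, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  is_lab <- inherits(vol, "label_map")
  arr <- if (is_lab) vol$labels else vol$values
  d <- dim(arr)
  if (!identical(dim(field), c(d, 3L)))
    stop("field dimensions do not match the volume")
  ix <- voxel_index_grid(d)
  sp <- vol$spacing
  coords <- cbind(ix[, 1] + as.vector(field[, , , 1]) / sp[1],
                  ix[, 2] + as.vector(field[, , , 2]) / sp[2],
                  ix[, 3] + as.vector(field[, , , 3]) / sp[3])
  if (is_lab || interpolation == "nearest") {
    out <- array(interp_nearest(arr, coords), d)
  } else {
    out <- array(interp_trilinear(arr, coords), d)
  }
  if (is_lab) {
    label_map(out, vol$spacing, vol$origin, vol$legend)
  } else {
    volume_grid(out, vol$spacing, vol$origin, vol$unit)
  }
}

zero_field <- function(d) array(0, dim = c(d, 3L))

#' Jacobian determinant of the mapping x + u(x)
#'
#' Central finite differences on the grid; used to reject folding
#' deformations (non-positive determinant anywhere).
#'
#' @param field displacement array (mm), dim `c(nx, ny, nz, 3)`.
#' @param spacing voxel spacing in mm.
#' @return 3D array of determinants.
#' @export
jacobian_determinant <- function(field, spacing) {
  d <- dim(field)[1:3]
  J <- array(0, c(d, 3, 3))
  for (comp in 1:3) {
    u <- field[, , , comp]
    J[, , , comp, 1] <- central_diff(u, 1) / spacing[1]
    J[, , , comp, 2] <- central_diff(u, 2) / spacing[2]
    J[, , , comp, 3] <- central_diff(u, 3) / spacing[3]
  }
  (1 + J[, , , 1, 1]) * ((1 + J[, , , 2, 2]) * (1 + J[, , , 3, 3]) -
                         J[, , , 2, 3] * J[, , , 3, 2]) -
  J[, , , 1, 2] * (J[, , , 2, 1] * (1 + J[, , , 3, 3]) -
                   J[, , , 2, 3] * J[, , , 3, 1]) +
  J[, , , 1, 3] * (J[, , , 2, 1] * J[, , , 3, 2] -
                   (1 + J[, , , 2, 2]) * J[, , , 3, 1])
}

## Central difference along one axis with one-sided differences at edges,
## in voxel units (divide by spacing for mm^-1).
central_diff <- function(arr, axis) {
  d <- dim(arr)
  n <- d[axis]
  idx_p <- pmin(seq_len(n) + 1L, n)
  idx_m <- pmax(seq_len(n) - 1L, 1L)
  h <- idx_p - idx_m  # 2 interior, 1 at edges
  slice_axis <- function(a, i) {
    switch(axis, a[i, , , drop = FALSE], a[, i, , drop = FALSE],
           a[, , i, drop = FALSE])
  }
  out <- (slice_axis(arr, idx_p) - slice_axis(arr, idx_m))
  hh <- array(h[slice.index(arr, axis)], dim = d)
  out / hh
}

## ---- separable smoothing -------------------------------------------------

## Dense 1D Gaussian smoothing matrix (rows renormalised at the edges).
gauss_matrix <- function(n, sigma) {
  if (sigma <= 0 || n == 1L) return(diag(n))
  r <- ceiling(3 * sigma)
  i <- seq_len(n)
  S <- outer(i, i, function(a, b) {
    d <- abs(a - b)
    ifelse(d <= r, exp(-d^2 / (2 * sigma^2)), 0)
  })
  S / rowSums(S)
}

apply_axis <- function(arr, axis, M) {
  d <- dim(arr)
  if (axis == 1L) {
    array(M %*% matrix(arr, d[1]), d)
  } else if (axis == 2L) {
    p <- aperm(arr, c(2, 1, 3))
    aperm(array(M %*% matrix(p, d[2]), c(d[2], d[1], d[3])), c(2, 1, 3))
  } else {
    p <- aperm(arr, c(3, 1, 2))
    aperm(array(M %*% matrix(p, d[3]), c(d[3], d[1], d[2])), c(2, 3, 1))
  }
}

#' Separable Gaussian smoothing of a 3D array
#'
#' @param arr 3D array.
#' @param sigma_vox smoothing SD in voxels, scalar or per-axis.
#' @return Smoothed array of the same shape.
#' @export
gauss_smooth3 <- function(arr, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  d <- dim(arr)
  for (ax in 1:3) {
    if (sigma_vox[ax] > 0 && d[ax] > 1L)
      arr <- apply_axis(arr, ax, gauss_matrix(d[ax], sigma_vox[ax]))
  }
  arr
}

smooth_field <- function(field, sigma_vox) {
  for (comp in 1:3)
    field[, , , comp] <- gauss_smooth3(field[, , , comp], sigma_vox)
  field
}

## Block-mean downsample by integer factors (for multiresolution pyramids).
downsample_mean <- function(arr, f) {
  f <- rep_len(as.integer(f), 3L)
  d <- dim(arr)
  nd <- pmax(d %/% f, 1L)
  cropped <- arr[seq_len(nd[1] * f[1]), seq_len(nd[2] * f[2]),
                 seq_len(nd[3] * f[3]), drop = FALSE]
  a <- array(cropped, c(f[1], nd[1], f[2], nd[2], f[3], nd[3]))
  out <- apply(a, c(2, 4, 6), mean)
  array(out, nd)
}

## Trilinearly resample a 3D array to a new shape (index-space scaling).
resize_array <- function(arr, new_dim) {
  d <- dim(arr)
  if (identical(d, as.integer(new_dim))) return(arr)
  ix <- voxel_index_grid(as.integer(new_dim))
  coords <- cbind(scale_index(ix[, 1], new_dim[1], d[1]),
                  scale_index(ix[, 2], new_dim[2], d[2]),
                  scale_index(ix[, 3], new_dim[3], d[3]))
  array(interp_trilinear(arr, coords), new_dim)
}

## Map index 1..n_new onto 1..n_old preserving the centres of the extent.
scale_index <- function(i, n_new, n_old) {
  if (n_new == 1L) return(rep((n_old + 1) / 2, length(i)))
  (i - 1) * (n_old - 1) / (n_new - 1) + 1
}

#' Display an axial slice of a volume
#'
#' @param x `volume_grid`.
#' @param slice axial slice index (default middle).
#' @param ... passed to [graphics::image()].
#' @export
plot.volume_grid <- function(x, slice = NULL, ...) {
  d <- dim(x$values)
  if (is.null(slice)) slice <- (d[3] + 1L) %/% 2L
  graphics::image(x = seq_len(d[1]) * x$spacing[1],
                  y = seq_len(d[2]) * x$spacing[2],
                  z = x$values[, , slice],
                  col = grDevices::gray.colors(128), asp = 1,
                  xlab = "mm", ylab = "mm", ...)
  invisible(x)
}
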