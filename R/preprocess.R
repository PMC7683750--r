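#' Extract the body contour from a CT volume
#'
#' Thresholds at `hu_threshold`, keeps the largest 3D connected component,
#' and fills internal holes slice by slice, yielding a binary body mask.
#'
#' @param ct `volume_grid` in HU.
#' @param hu_threshold HU above which a voxel counts as body (default -400).
#' @return Logical 3D array (the contour mask).
#' @export
body_contour <- function(ct, hu_threshold = -400) {
  mask <- ct$values > hu_threshold
  if (!any(mask)) stop("no voxels above the body threshold: empty body mask")
  mask <- largest_component3(mask)
  d <- dim(mask)
  for (k in seq_len(d[3])) {
    sl <- mask[, , k]
    if (any(sl))
      mask[, , k] <- EBImage::fillHull(EBImage::Image(sl * 1)) > 0.5
  }
  mask
}

## Largest 3D 6-connected component: per-slice 2D labelling (EBImage) merged
## across adjacent slices with a union-find.
largest_component3 <- function(mask) {
  d <- dim(mask)
  labs <- array(0L, d)
  offset <- 0L
  for (k in seq_len(d[3])) {
    sl <- EBImage::bwlabel(EBImage::Image(mask[, , k] * 1))
    sl <- as.integer(sl)
    sl[sl > 0L] <- sl[sl > 0L] + offset
    labs[, , k] <- sl
    offset <- max(offset, max(sl))
  }
  if (offset == 0L) return(mask & FALSE)
  parent <- seq_len(offset)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  for (k in seq_len(d[3] - 1L)) {
    a <- labs[, , k]; b <- labs[, , k + 1L]
    both <- a > 0L & b > 0L
    if (any(both)) {
      pairs <- unique(cbind(a[both], b[both]))
      for (r in seq_len(nrow(pairs))) union2(pairs[r, 1], pairs[r, 2])
    }
  }
  roots <- vapply(seq_len(offset), find, integer(1))
  v <- as.vector(labs)
  comp <- ifelse(v > 0L, roots[pmax(v, 1L)], 0L)
  tab <- tabulate(comp[comp > 0L])
  best <- which.max(tab)
  array(comp == best, d)
}

#' Replace internal air pockets with water
#'
#' Voxels inside the body whose HU is below the air-pocket threshold are set
#' to 0 HU (water), emulating the harmonisation of bowel air that moves
#' between examinations. Voxels outside the body are untouched.
#'
#' @param ct `volume_grid` in HU.
#' @param body logical body mask from [body_contour()].
#' @param air_threshold HU below which an internal voxel counts as air.
#' @return `volume_grid` in HU.
#' @export
replace_air_pockets <- function(ct, body, air_threshold = -400) {
  v <- ct$values
  v[body & v < air_threshold] <- 0
  volume_grid(v, ct$spacing, ct$origin, ct$unit)
}

#' Harmonise a CT volume to a reference outer contour
#'
#' Voxels outside the reference contour are set to air (-1000 HU); voxels
#' inside the reference contour that look like air (HU below
#' `air_threshold`) are filled with water (0 HU); all other voxels are
#' unchanged. Applying the operation twice gives the same result as once.
#'
#' @param ct `volume_grid` in HU.
#' @param reference logical contour mask on the same lattice.
#' @param air_threshold HU below which an inside voxel counts as air.
#' @return `volume_grid` in HU.
#' @export
harmonize_contour <- function(ct, reference, air_threshold = -400) {
  if (!identical(dim(reference), dim(ct$values)))
    stop("reference contour must match the CT lattice")
  v <- ct$values
  v[!reference] <- -1000
  v[reference & v < air_threshold] <- 0
  volume_grid(v, ct$spacing, ct$origin, ct$unit)
}

#' Pad missing inferior slices by repetition
#'
#' Replicates the most inferior existing slice (index 1) `n` times to extend
#' the axial field of view, and returns a per-slice validity mask so that
#' analyses can exclude the padded slices.
#'
#' @param ct `volume_grid`.
#' @param n_missing_inferior number of slices to prepend.
#' @return `list(volume = padded volume_grid, valid_slices = logical vector)`.
#' @export
extend_fov_slices <- function(ct, n_missing_inferior = 0) {
  n <- as.integer(n_missing_inferior)
  if (n < 0) stop("'n_missing_inferior' must be non-negative")
  d <- dim(ct$values)
  if (n >= d[3]) stop("cannot pad by ", n, " slices: volume has only ",
                      d[3], " slices")
  if (n == 0)
    return(list(volume = ct, valid_slices = rep(TRUE, d[3])))
  pad <- array(rep(ct$values[, , 1], n), c(d[1], d[2], n))
  out <- array(0, c(d[1], d[2], d[3] + n))
  out[, , seq_len(n)] <- pad
  out[, , n + seq_len(d[3])] <- ct$values
  origin <- ct$origin - c(0, 0, n * ct$spacing[3])
  list(volume = volume_grid(out, ct$spacing, origin, ct$unit),
       valid_slices = c(rep(FALSE, n), rep(TRUE, d[3])))
}

#' Resample a volume onto a target lattice
#'
#' Physical-space resampling: each target voxel centre is mapped through the
#' shared world coordinates into the source volume and interpolated (linear
#' for intensities, nearest for labels). Resampling a volume onto its own
#' lattice returns it bit-identically.
#'
#' @param image `volume_grid` or `label_map`.
#' @param target_grid object carrying `spacing` and `origin` plus a lattice
#'   shape (a `volume_grid`/`label_map`), or a list with `dim`, `spacing`,
#'   `origin`.
#' @param interpolation "linear" or "nearest".
#' @return Resampled object of the same class as `image`.
#' @export
resample_to <- function(image, target_grid,
                        interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  is_lab <- inherits(image, "label_map")
  arr <- if (is_lab) image$labels else image$values
  td <- if (!is.null(target_grid$dim)) as.integer(target_grid$dim)
        else dim(target_grid)
  tsp <- target_grid$spacing
  tor <- target_grid$origin
  if (identical(td, dim(arr)) &&
      all(abs(tsp - image$spacing) < 1e-9) &&
      all(abs(tor - image$origin) < 1e-9))
    return(image)
  # world extent overlap check
  s_lo <- image$origin; s_hi <- image$origin + (dim(arr) - 1) * image$spacing
  t_lo <- tor; t_hi <- tor + (td - 1) * tsp
  if (any(t_hi < s_lo) || any(t_lo > s_hi))
    stop("target grid does not overlap the source volume")
  ix <- voxel_index_grid(td)
  world <- sweep(sweep(ix - 1, 2, tsp, `*`), 2, tor, `+`)
  coords <- sweep(sweep(world, 2, image$origin, `-`), 2, image$spacing, `/`) + 1
  if (is_lab || interpolation == "nearest") {
    out <- array(interp_nearest(arr, coords), td)
  } else {
    out <- array(interp_trilinear(arr, coords), td)
  }
  if (is_lab) label_map(out, tsp, tor, image$legend)
  else volume_grid(out, tsp, tor, image$unit)
}
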