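#' Registration settings
#'
#' Controls the in-package deformable registration engine: an affine stage
#' (Nelder-Mead over 12 parameters, translation-first) followed by a
#' multiresolution demons-type free-form stage driven by mean-squared
#' intensity difference on normalised images. All displacement fields are in
#' mm, pull-back convention: `warp_volume(moving, field)` aligns the moving
#' image onto the fixed one.
#'
#' @param levels downsampling factors of the multiresolution pyramid
#'   (coarse to fine).
#' @param iterations demons iterations per level.
#' @param max_step_mm cap on the per-iteration displacement update.
#' @param sigma_fluid_vox Gaussian smoothing of the update field (voxels).
#' @param sigma_elastic_vox Gaussian smoothing of the accumulated field.
#' @param sigma_image_vox Gaussian pre-smoothing of the images at each level.
#' @param noise_gate multiple of the estimated residual noise spread below
#'   which the demons force is zeroed (suppresses noise chasing in
#'   homogeneous regions).
#' @param affine_maxit Nelder-Mead iteration budget for the affine stage.
#' @param mi_bins joint-histogram bins for the mutual-information metric.
#' @return A settings list.
#' @export
register_settings <- function(levels = c(2, 1),
                              iterations = c(80, 60),
                              max_step_mm = 3,
                              sigma_fluid_vox = 3,
                              sigma_elastic_vox = 0.5,
                              sigma_image_vox = 0,
                              noise_gate = 3,
                              affine_maxit = 400,
                              mi_bins = 32) {
  list(levels = levels, iterations = iterations, max_step_mm = max_step_mm,
       sigma_fluid_vox = sigma_fluid_vox,
       sigma_elastic_vox = sigma_elastic_vox,
       sigma_image_vox = sigma_image_vox, noise_gate = noise_gate,
       affine_maxit = affine_maxit, mi_bins = mi_bins)
}

normalise_intensity <- function(arr) {
  s <- stats::sd(arr)
  if (s < 1e-12) return(arr - mean(arr))
  (arr - mean(arr)) / s
}

## ---- affine stage --------------------------------------------------------

## pars = c(t (mm, 3), vec(M - I) (9)); x centred world coordinates.
affine_field <- function(pars, d, spacing) {
  ix <- voxel_index_grid(d)
  ctr <- (d + 1) / 2
  X <- cbind((ix[, 1] - ctr[1]) * spacing[1],
             (ix[, 2] - ctr[2]) * spacing[2],
             (ix[, 3] - ctr[3]) * spacing[3])
  M <- matrix(pars[4:12], 3, 3)
  U <- X %*% t(M) + matrix(pars[1:3], nrow(X), 3, byrow = TRUE)
  array(U, c(d, 3L))
}

metric_msd <- function(a, b) mean((a - b)^2)

metric_neg_mi <- function(a, b, bins) {
  ra <- range(a); rb <- range(b)
  if (diff(ra) < 1e-12 || diff(rb) < 1e-12) return(0)
  ia <- pmin(floor((a - ra[1]) / diff(ra) * bins) + 1L, bins)
  ib <- pmin(floor((b - rb[1]) / diff(rb) * bins) + 1L, bins)
  joint <- tabulate((ib - 1L) * bins + ia, bins * bins) / length(a)
  pa <- rowSums(matrix(joint, bins)); pb <- colSums(matrix(joint, bins))
  nz <- joint > 0
  h_ab <- -sum(joint[nz] * log(joint[nz]))
  h_a <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  h_b <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  -(h_a + h_b - h_ab)
}

register_affine <- function(fixed_arr, moving_arr, spacing, metric, settings) {
  d <- dim(fixed_arr)
  f <- pmax(1L, pmin(2L, d %/% 24L))
  fl <- downsample_mean(fixed_arr, f)
  ml <- downsample_mean(moving_arr, f)
  if (metric == "mi") {
    # the histogram metric needs a smooth joint density to optimise over
    fl <- gauss_smooth3(fl, 1)
    ml <- gauss_smooth3(ml, 1)
  }
  dl <- dim(fl); spl <- spacing * f
  ixl <- voxel_index_grid(dl)
  ctr <- (dl + 1) / 2
  Xl <- cbind((ixl[, 1] - ctr[1]) * spl[1],
              (ixl[, 2] - ctr[2]) * spl[2],
              (ixl[, 3] - ctr[3]) * spl[3])
  cost <- function(pars) {
    M <- matrix(pars[4:12], 3, 3)
    U <- Xl %*% t(M) + matrix(pars[1:3], nrow(Xl), 3, byrow = TRUE)
    coords <- cbind(ixl[, 1] + U[, 1] / spl[1],
                    ixl[, 2] + U[, 2] / spl[2],
                    ixl[, 3] + U[, 3] / spl[3])
    w <- interp_trilinear(ml, coords)
    if (metric == "mi") metric_neg_mi(fl, w, settings$mi_bins)
    else metric_msd(fl, w)
  }
  zero12 <- rep(0, 12)
  o1 <- stats::optim(rep(0, 3), function(t3) cost(c(t3, zero12[4:12])),
                     method = "Nelder-Mead",
                     control = list(maxit = settings$affine_maxit))
  o2 <- stats::optim(c(o1$par, zero12[4:12]), cost, method = "Nelder-Mead",
                     control = list(maxit = settings$affine_maxit,
                                    reltol = 1e-9))
  pars <- if (o2$value <= o1$value) o2$par else c(o1$par, zero12[4:12])
  list(pars = pars, value = min(o1$value, o2$value),
       converged = (o2$convergence == 0 || o1$convergence == 0))
}

## ---- demons stage --------------------------------------------------------

## Multichannel demons at one resolution. fixed/moving: lists of arrays of a
## common shape; u0: initial field (mm) on that shape.
demons_level <- function(fixed, moving, spacing, u0, n_iter, settings) {
  d <- dim(fixed[[1]])
  u <- u0
  step2 <- settings$max_step_mm^2
  ix <- voxel_index_grid(d)
  gate <- NULL
  for (it in seq_len(n_iter)) {
    coords <- cbind(ix[, 1] + as.vector(u[, , , 1]) / spacing[1],
                    ix[, 2] + as.vector(u[, , , 2]) / spacing[2],
                    ix[, 3] + as.vector(u[, , , 3]) / spacing[3])
    ip <- precompute_interp(coords, d)
    fx <- fy <- fz <- denom <- array(0, d)
    for (ch in seq_along(fixed)) {
      w <- array(apply_interp(ip, moving[[ch]]), d)
      diff <- fixed[[ch]] - w
      gx <- central_diff(w, 1) / spacing[1]
      gy <- central_diff(w, 2) / spacing[2]
      gz <- central_diff(w, 3) / spacing[3]
      if (is.null(gate)) {
        # noise floor: spread of the residual in the flattest half of the
        # image; forces below it are indistinguishable from noise
        g2 <- gx^2 + gy^2 + gz^2
        flat <- g2 <= stats::median(g2)
        gate <- settings$noise_gate * stats::mad(diff[flat])
      }
      keep <- abs(diff) > gate
      fx <- fx + diff * gx * keep
      fy <- fy + diff * gy * keep
      fz <- fz + diff * gz * keep
      denom <- denom + (gx^2 + gy^2 + gz^2) * keep + diff^2 / step2
    }
    denom[denom < 1e-12] <- 1e-12
    du <- array(0, c(d, 3L))
    du[, , , 1] <- fx / denom
    du[, , , 2] <- fy / denom
    du[, , , 3] <- fz / denom
    du <- smooth_field(du, settings$sigma_fluid_vox)
    u <- smooth_field(u + du, settings$sigma_elastic_vox)
  }
  u
}

resize_field <- function(u, new_dim) {
  out <- array(0, c(new_dim, 3L))
  for (comp in 1:3) out[, , , comp] <- resize_array(u[, , , comp], new_dim)
  out
}

## Pyramid factors per axis, never collapsing an axis below 6 voxels.
level_factors <- function(d, f) {
  pmax(1L, pmin(as.integer(f), d %/% 6L))
}

demons_multires <- function(fixed, moving, spacing, u0, settings) {
  d <- dim(fixed[[1]])
  u <- u0
  for (li in seq_along(settings$levels)) {
    f <- level_factors(d, settings$levels[li])
    pre <- settings$sigma_image_vox
    fl <- lapply(fixed, function(a) gauss_smooth3(downsample_mean(a, f), pre))
    ml <- lapply(moving, function(a) gauss_smooth3(downsample_mean(a, f), pre))
    dl <- dim(fl[[1]])
    ul <- resize_field(u, dl)
    ul <- demons_level(fl, ml, spacing * f, ul, settings$iterations[li],
                       settings)
    u <- resize_field(ul, d)
  }
  u
}

#' Deformable registration of two volumes
#'
#' Composition of an affine stage and a multiresolution demons-type
#' free-form stage. The default metric is mean-squared difference on
#' normalised intensities (same-modality MR-MR); a mutual-information metric
#' is available for the affine stage for cross-modality pairs. The result is
#' deterministic given the inputs and settings.
#'
#' @param fixed,moving `volume_grid` objects on a common lattice.
#' @param mode "affine+ffd" (default), "affine" or "ffd".
#' @param metric "msd" (default) or "mi" (affine stage).
#' @param settings [register_settings()].
#' @return Displacement-field array (mm, dim `c(dim, 3)`) with attribute
#'   `converged`; `warp_volume(moving, field)` approximates `fixed`.
#' @export
register_volumes <- function(fixed, moving,
                             mode = c("affine+ffd", "affine", "ffd"),
                             metric = c("msd", "mi"),
                             settings = register_settings()) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  stop_if_lattice_mismatch(fixed, moving, "fixed and moving")
  d <- dim(fixed$values)
  fa <- normalise_intensity(fixed$values)
  ma <- normalise_intensity(moving$values)
  converged <- TRUE
  u <- zero_field(d)
  if (mode %in% c("affine+ffd", "affine")) {
    aff <- register_affine(fa, ma, fixed$spacing, metric, settings)
    u <- affine_field(aff$pars, d, fixed$spacing)
    converged <- aff$converged
    if (!converged)
      warning("affine stage did not converge; returning best-so-far")
  }
  if (mode %in% c("affine+ffd", "ffd")) {
    u <- demons_multires(list(fa), list(ma), fixed$spacing, u, settings)
  }
  attr(u, "converged") <- converged
  u
}

#' Label-driven refinement registration
#'
#' Demons registration on Gaussian-smoothed per-structure indicator maps of
#' two segmentations instead of raw intensities: the force pulls structure
#' boundaries into agreement, so a pair already matched yields a
#' near-identity refinement. Used for the constrained warping stage of the
#' synthetic-CT generator.
#'
#' @param fixed_seg,moving_seg `label_map` objects on a common lattice.
#' @param u0 initial displacement field (mm); default zero.
#' @param sigma_mm smoothing of the indicator maps, mm.
#' @param settings [register_settings()].
#' @param labels label ids to drive the registration (default: all legend
#'   labels present in either segmentation except background air).
#' @return Displacement-field array (mm).
#' @export
register_labels <- function(fixed_seg, moving_seg, u0 = NULL, sigma_mm = 6,
                            settings = register_settings(),
                            labels = NULL) {
  stop_if_lattice_mismatch(fixed_seg, moving_seg, "segmentations")
  d <- dim(fixed_seg$labels)
  sp <- fixed_seg$spacing
  if (is.null(u0)) u0 <- zero_field(d)
  if (is.null(labels)) {
    present <- union(unique(as.vector(fixed_seg$labels)),
                     unique(as.vector(moving_seg$labels)))
    labels <- setdiff(present, tissue_legend()[["air"]])
  }
  sig_vox <- sigma_mm / sp
  chan <- function(seg) {
    lapply(labels, function(l)
      gauss_smooth3(array(as.numeric(seg$labels == l), d), sig_vox))
  }
  demons_multires(chan(fixed_seg), chan(moving_seg), sp, u0, settings)
}
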