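#' Parallel-beam projection geometry
#'
#' 2D parallel-beam geometry applied slice by slice: uniformly spaced angles
#' over [0, pi) and radial bins at the in-plane voxel pitch. The projector is
#' a pixel-driven sparse matrix with linear splatting onto the two nearest
#' radial bins, weighted by the pixel pitch so that `A %*% x` approximates
#' line integrals in value * mm. The exact transpose of the same matrix is
#' the backprojector, so the projector/backprojector pair is adjoint to
#' machine precision.
#'
#' @param dim_xy integer(2), in-plane image size.
#' @param spacing_xy in-plane voxel size, mm (isotropic in-plane assumed;
#'   the mean is used if the two differ slightly).
#' @param n_angles number of projection angles (default 112, so the clinical
#'   28-subset protocol divides it).
#' @return A `pet_geometry` object with the sparse system matrix `A`
#'   (`n_angles * n_rad` rows, `nx * ny` columns).
#' @export
pet_geometry <- function(dim_xy, spacing_xy, n_angles = 112) {
  nx <- as.integer(dim_xy[1]); ny <- as.integer(dim_xy[2])
  ds <- mean(spacing_xy[1:2])
  n_rad <- 2L * as.integer(ceiling(sqrt((nx / 2)^2 + (ny / 2)^2))) + 1L
  angles <- (seq_len(n_angles) - 1) * pi / n_angles
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  ij <- cbind(rep.int(seq_len(nx), ny), rep(seq_len(ny), each = nx))
  xs <- (ij[, 1] - cx) * spacing_xy[1]
  ys <- (ij[, 2] - cy) * spacing_xy[2]
  npix <- nx * ny
  mid <- (n_rad + 1) / 2
  parts <- vector("list", n_angles)
  for (t in seq_len(n_angles)) {
    s <- xs * cos(angles[t]) + ys * sin(angles[t])
    b <- s / ds + mid
    b0 <- floor(b)
    w1 <- b - b0
    ok0 <- b0 >= 1 & b0 <= n_rad
    ok1 <- (b0 + 1) >= 1 & (b0 + 1) <= n_rad
    base <- (t - 1L) * n_rad
    parts[[t]] <- list(i = c(base + b0[ok0], base + b0[ok1] + 1L),
                       j = c(which(ok0), which(ok1)),
                       x = c((1 - w1[ok0]) * ds, w1[ok1] * ds))
  }
  A <- Matrix::sparseMatrix(i = unlist(lapply(parts, `[[`, "i")),
                            j = unlist(lapply(parts, `[[`, "j")),
                            x = unlist(lapply(parts, `[[`, "x")),
                            dims = c(n_angles * n_rad, npix))
  structure(list(nx = nx, ny = ny, spacing = ds, n_angles = n_angles,
                 n_rad = n_rad, angles = angles, A = A),
            class = "pet_geometry")
}

#' @export
print.pet_geometry <- function(x, ...) {
  cat(sprintf("<pet_geometry> %d x %d image, %d angles x %d radial bins\n",
              x$nx, x$ny, x$n_angles, x$n_rad))
  invisible(x)
}

#' Reconstruction configuration
#'
#' Defaults mirror a clinical pelvic protocol: 2 iterations and 28 subsets
#' (the package default of 112 angles is divisible by 28). If `n_subsets` is
#' `NULL` it resolves at reconstruction time to the largest divisor of the
#' angle count not exceeding 28.
#'
#' @param n_iterations OSEM iterations (full passes over all subsets).
#' @param n_subsets subset count; must divide the number of angles.
#' @param noise_scale expected total counts per slice for the Poisson model
#'   (`NULL` = no rescaling of the noise-free sinogram).
#' @param seed RNG seed for the Poisson draw.
#' @return A `recon_config` list.
#' @export
recon_config <- function(n_iterations = 2, n_subsets = NULL,
                         noise_scale = NULL, seed = 1) {
  list(n_iterations = n_iterations, n_subsets = n_subsets,
       noise_scale = noise_scale, seed = seed)
}

largest_divisor_below <- function(n, k) {
  for (d in seq(min(k, n), 1)) if (n %% d == 0) return(as.integer(d))
  1L
}

#' Attenuated forward projection
#'
#' Per slice: parallel-beam line integrals of the activity, each line of
#' response multiplied by its survival probability `exp(-integral of mu dl)`
#' computed on the same rays. If `noise_scale` is given, a single global
#' factor scales the sinogram so the mean total per slice equals it; the
#' factor is stored so reconstruction recovers absolute activity units.
#'
#' @param activity `volume_grid`, Bq/ml.
#' @param mu_true `volume_grid`, cm^-1, same lattice.
#' @param geometry [pet_geometry()] matching the in-plane lattice.
#' @param noise_scale expected total counts per slice, or `NULL`.
#' @return A `sinogram`: counts array (`n_rad x n_angles x n_slices`),
#'   attenuation factors, scale factor and geometry.
#' @export
forward_project <- function(activity, mu_true, geometry, noise_scale = NULL) {
  stop_if_lattice_mismatch(activity, mu_true, "activity and mu")
  d <- dim(activity$values)
  if (d[1] != geometry$nx || d[2] != geometry$ny ||
      abs(mean(activity$spacing[1:2]) - geometry$spacing) > 1e-6)
    stop("geometry does not match the volume lattice")
  A <- geometry$A
  nz <- d[3]
  counts <- array(0, c(geometry$n_rad, geometry$n_angles, nz))
  att <- array(1, c(geometry$n_rad, geometry$n_angles, nz))
  for (z in seq_len(nz)) {
    p <- as.vector(A %*% as.vector(activity$values[, , z]))
    a <- exp(-0.1 * as.vector(A %*% as.vector(mu_true$values[, , z])))
    counts[, , z] <- p * a
    att[, , z] <- a
  }
  scale <- 1
  if (!is.null(noise_scale)) {
    tot <- sum(counts)
    if (tot > 0) scale <- noise_scale * nz / tot
    counts <- counts * scale
  }
  structure(list(counts = counts, att = att, scale = scale,
                 geometry = geometry, spacing_z = activity$spacing[3],
                 spacing = activity$spacing, origin = activity$origin),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<sinogram> %d radial x %d angles x %d slices, total %.3g counts\n",
              d[1], d[2], d[3], sum(x$counts)))
  invisible(x)
}

#' Poisson counting noise
#'
#' Independent Poisson draw per sinogram bin with the noise-free bin value
#' as expectation; deterministic given the seed. Bins with zero expectation
#' stay zero.
#'
#' @param sino a `sinogram`.
#' @param seed RNG seed.
#' @return A `sinogram` with integer counts.
#' @export
add_poisson_noise <- function(sino, seed = 1) {
  sino$counts <- with_seed(seed, {
    array(stats::rpois(length(sino$counts), lambda = as.vector(sino$counts)),
          dim(sino$counts))
  })
  sino
}

#' OSEM reconstruction with a candidate attenuation map
#'
#' Standard ordered-subset expectation-maximization, slice by slice, with
#' the attenuation factors derived from `mu_for_ac` folded into the system
#' model (the data keep whatever attenuation the forward simulation
#' applied, so a wrong candidate map produces quantification errors in the
#' reconstruction, exactly as in a scanner). Angles are assigned to subsets
#' by stride. Non-negative output; deterministic.
#'
#' @param sino a `sinogram`.
#' @param mu_for_ac `volume_grid` mu-map used for attenuation correction.
#' @param config [recon_config()].
#' @return `volume_grid` of reconstructed activity in the input units.
#' @export
osem_reconstruct <- function(sino, mu_for_ac, config = recon_config()) {
  g <- sino$geometry
  d <- c(g$nx, g$ny, dim(sino$counts)[3])
  if (!identical(dim(mu_for_ac$values), d))
    stop("attenuation map does not match the sinogram geometry")
  if (all(sino$counts == 0)) {
    warning("all-zero sinogram: returning zero image")
    return(volume_grid(array(0, d), sino$spacing, sino$origin,
                       unit = "Bq/ml"))
  }
  n_sub <- config$n_subsets
  if (is.null(n_sub)) n_sub <- largest_divisor_below(g$n_angles, 28)
  if (g$n_angles %% n_sub != 0)
    stop("n_subsets (", n_sub, ") must divide the number of angles (",
         g$n_angles, ")")
  # subset row indices (angles by stride) and submatrices
  subset_rows <- lapply(seq_len(n_sub), function(k) {
    ts <- seq(k, g$n_angles, by = n_sub)
    as.vector(outer(seq_len(g$n_rad), (ts - 1L) * g$n_rad, `+`))
  })
  A_sub <- lapply(subset_rows, function(r) g$A[r, , drop = FALSE])
  At_sub <- lapply(A_sub, Matrix::t)
  # golden-ratio ordering spreads successive subsets in angle, which
  # substantially accelerates early OSEM convergence
  subset_order <- order(((seq_len(n_sub) - 1) * ((sqrt(5) - 1) / 2)) %% 1)
  npix <- g$nx * g$ny
  # circular reconstruction support
  ij <- cbind(rep.int(seq_len(g$nx), g$ny), rep(seq_len(g$ny), each = g$nx))
  r2 <- (ij[, 1] - (g$nx + 1) / 2)^2 + (ij[, 2] - (g$ny + 1) / 2)^2
  support <- r2 <= (min(g$nx, g$ny) / 2)^2
  out <- array(0, d)
  eps <- 1e-12
  for (z in seq_len(d[3])) {
    y <- as.vector(sino$counts[, , z])
    if (all(y == 0)) next
    att <- exp(-0.1 * as.vector(g$A %*% as.vector(mu_for_ac$values[, , z]))) *
      sino$scale
    x <- as.numeric(support)
    for (it in seq_len(config$n_iterations)) {
      for (k in subset_order) {
        r <- subset_rows[[k]]
        ak <- att[r]
        p <- ak * as.vector(A_sub[[k]] %*% x)
        ratio <- ifelse(p > eps, y[r] / p, 0)
        num <- as.vector(At_sub[[k]] %*% (ak * ratio))
        den <- as.vector(At_sub[[k]] %*% ak)
        upd <- ifelse(den > eps, num / den, 0)
        x <- x * upd
      }
    }
    out[, , z] <- x
  }
  volume_grid(out, sino$spacing, sino$origin, unit = "Bq/ml")
}

#' Convert activity concentration to SUV
#'
#' SUV = concentration / (injected dose / body weight). The calibration
#' factor maps simulator units to activity concentration; percentage SUV
#' differences between two reconstructions are invariant to it.
#'
#' @param recon `volume_grid`, activity concentration.
#' @param injected_dose MBq.
#' @param body_weight kg.
#' @param calibration unit calibration factor (default 1).
#' @return `volume_grid` in SUV units.
#' @export
to_suv <- function(recon, injected_dose, body_weight, calibration = 1) {
  if (injected_dose <= 0 || body_weight <= 0)
    stop("dose and weight must be positive")
  denom <- injected_dose * 1e6 / (body_weight * 1000)  # Bq/g
  volume_grid(recon$values * calibration / denom, recon$spacing,
              recon$origin, unit = "SUV")
}
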