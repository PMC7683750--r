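#' Default phantom parameters
#'
#' Tissue intensity models and deformation settings for the procedural pelvis
#' phantom. CT numbers are drawn per label from Gaussian distributions with
#' standard abdominal-CT means; MR intensities follow a T2-like contrast
#' (fluid and fat bright, cortical bone dark) with a smooth multiplicative
#' bias field and additive noise. Activity is specified in SUV units per
#' tissue and converted to Bq/ml per subject from injected dose and body
#' weight.
#'
#' @param bone_scale global multiplier on drawn bone HU values, emulating
#'   cohorts with lower bone density (default 1).
#' @return A list of parameter values.
#' @export
phantom_params <- function(bone_scale = 1) {
  list(
    # CT model: per-label (mean, SD) in HU; air and bowel gas are constant.
    hu = list(air = c(-1000, 0), bowel_gas = c(-1000, 0),
              fat = c(-90, 20), soft_tissue = c(40, 15),
              bladder = c(10, 10), prostate = c(45, 10),
              bone_trabecular = c(300, 80), bone_cortical = c(1100, 150)),
    hu_clip = c(-1000, 2000),
    bone_range = c(200, 1500),
    bone_scale = bone_scale,
    # MR model: per-label mean intensity (arbitrary units).
    mr = c(air = 0.02, bowel_gas = 0.02, fat = 0.90, soft_tissue = 0.50,
           bladder = 0.95, prostate = 0.60, bone_trabecular = 0.35,
           bone_cortical = 0.08),
    mr_bias_amplitude = 0.10,    # multiplicative smooth bias field
    mr_noise_sd = 0.03 * 0.50,   # 3 % of the soft-tissue mean
    # Activity model, SUV units per tissue ([11C]acetate-like; design
    # constants, the tracer's extra-prostatic distribution is not prescribed
    # by any reference).
    suv = c(air = 0, bowel_gas = 0, fat = 0.4, soft_tissue = 1.0,
            bladder = 1.8, prostate = 2.5, bone_trabecular = 0.8,
            bone_cortical = 0.3),
    hotspot_radius_mm = 9,
    # Deformation model.
    deform_amplitude_mm = 6,
    deform_correlation_mm = 30,
    # Dose / weight sampling (MBq, kg).
    dose_mean = 431, dose_sd = 53, dose_range = c(300, 600),
    weight_mean = 79.3, weight_sd = 7, weight_range = c(71, 95)
  )
}

## Run code with a temporary RNG state seeded at `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Derive n child seeds (< 2^31) from one parent seed.
derive_seeds <- function(seed, n, salt = 0L) {
  with_seed(seed + salt, sample.int(.Machine$integer.max - 1L, n))
}

#' Procedurally drawn canonical pelvis phantom
#'
#' Draws a stack of pelvis cross-sections on a regular grid: an elliptical
#' body outline with a subcutaneous fat rim, two hip-bone columns and a
#' sacrum (cortical shell around a trabecular core), a bladder and a
#' prostate, and optional bowel-gas pockets. The physical field of view is
#' fixed (400 x 400 x 120 mm by default, via the default spacing), so the
#' same anatomy is rendered at any grid size.
#'
#' @param grid_shape integer(3); at least 32 in-plane voxels and 8 slices.
#' @param spacing voxel size in mm; default scales a 400 x 400 x 120 mm FOV
#'   to `grid_shape`.
#' @param seed RNG seed for the intensity draws.
#' @param params see [phantom_params()].
#' @param gas_pockets optional list of bowel-gas spheres, each
#'   `list(centre = mm-vector relative to volume centre, radius = mm)`.
#' @return A `template_entry`: list with `mr`, `ct` (`volume_grid`) and
#'   `seg` (`label_map`) on one lattice.
#' @export
make_canonical_pelvis <- function(grid_shape = c(128, 128, 32),
                                  spacing = NULL, seed = 1,
                                  params = phantom_params(),
                                  gas_pockets = NULL) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape[1:2] < 32L) ||
      grid_shape[3] < 8L)
    stop("grid must be at least 32 x 32 in-plane and 8 slices")
  if (is.null(spacing)) spacing <- c(400, 400, 120) / grid_shape
  L <- grid_shape * spacing  # physical extent, mm

  ix <- voxel_index_grid(grid_shape)
  # centred physical coordinates, mm (y positive = posterior)
  X <- (ix[, 1] - (grid_shape[1] + 1) / 2) * spacing[1]
  Y <- (ix[, 2] - (grid_shape[2] + 1) / 2) * spacing[2]
  Z <- (ix[, 3] - (grid_shape[3] + 1) / 2) * spacing[3]

  lg <- tissue_legend()
  lab <- rep(lg[["air"]], nrow(ix))

  inside_ellipsoid <- function(c0, r) {
    ((X - c0[1]) / r[1])^2 + ((Y - c0[2]) / r[2])^2 +
      ((Z - c0[3]) / r[3])^2 <= 1
  }
  big <- 10 * max(L)  # "infinite" z semi-axis for columnar structures

  # body with a mild axial taper
  taper <- 1 - 0.08 * (2 * Z / L[3])^2
  body_frac <- sqrt((X / (0.42 * L[1]))^2 + (Y / (0.34 * L[2]))^2) / taper
  body <- body_frac <= 1
  lab[body] <- lg[["soft_tissue"]]
  lab[body & body_frac > 0.88] <- lg[["fat"]]

  add_bone <- function(lab, c0, r) {
    frac <- sqrt(((X - c0[1]) / r[1])^2 + ((Y - c0[2]) / r[2])^2 +
                   ((Z - c0[3]) / r[3])^2)
    lab[frac <= 1] <- lg[["bone_cortical"]]
    lab[frac <= 0.65] <- lg[["bone_trabecular"]]
    lab
  }
  lab <- add_bone(lab, c(-0.27 * L[1], 0.02 * L[2], 0), c(0.07 * L[1], 0.09 * L[2], big))
  lab <- add_bone(lab, c(+0.27 * L[1], 0.02 * L[2], 0), c(0.07 * L[1], 0.09 * L[2], big))
  lab <- add_bone(lab, c(0, 0.23 * L[2], 0), c(0.10 * L[1], 0.065 * L[2], big))

  lab[inside_ellipsoid(c(0, -0.10 * L[2], 0.15 * L[3]),
                       c(0.12 * L[1], 0.10 * L[2], 0.25 * L[3]))] <- lg[["bladder"]]
  lab[inside_ellipsoid(c(0, -0.02 * L[2], -0.12 * L[3]),
                       c(0.065 * L[1], 0.055 * L[2], 0.16 * L[3]))] <- lg[["prostate"]]

  if (!is.null(gas_pockets)) {
    for (p in gas_pockets) {
      inside <- (X - p$centre[1])^2 + (Y - p$centre[2])^2 +
        (Z - p$centre[3])^2 <= p$radius^2
      lab[inside & lab == lg[["soft_tissue"]]] <- lg[["bowel_gas"]]
    }
  }

  required <- setdiff(names(lg), "bowel_gas")
  for (nm in required) {
    if (!any(lab == lg[[nm]]))
      stop("grid too small to contain structure '", nm, "'")
  }

  lab_arr <- array(lab, grid_shape)
  seg <- label_map(lab_arr, spacing, c(0, 0, 0))

  with_seed(seed, {
    ct <- numeric(length(lab))
    mr <- numeric(length(lab))
    for (nm in names(lg)) {
      sel <- lab == lg[[nm]]
      n <- sum(sel)
      if (n == 0) next
      hu <- params$hu[[nm]]
      v <- if (hu[2] > 0) stats::rnorm(n, hu[1], hu[2]) else rep(hu[1], n)
      if (nm %in% c("bone_trabecular", "bone_cortical"))
        v <- v * params$bone_scale
      ct[sel] <- v
      mr[sel] <- params$mr[[nm]]
    }
    ct <- pmin(pmax(ct, params$hu_clip[1]), params$hu_clip[2])
    bias <- gauss_smooth3(array(stats::rnorm(length(lab)), grid_shape),
                          pmax(grid_shape / 8, 2))
    bias <- bias / max(stats::sd(bias), 1e-12)
    mr <- mr * (1 + params$mr_bias_amplitude * as.vector(bias)) +
      stats::rnorm(length(lab), 0, params$mr_noise_sd)
  })

  list(mr = volume_grid(array(mr, grid_shape), spacing, unit = "a.u."),
       ct = volume_grid(array(ct, grid_shape), spacing, unit = "HU"),
       seg = seg) |>
    structure(class = "template_entry")
}

#' @export
print.template_entry <- function(x, ...) {
  cat("<template_entry>\n  mr : "); print(x$mr)
  cat("  ct : "); print(x$ct)
  invisible(x)
}

#' Smooth random deformation of a phantom entry
#'
#' Generates a band-limited random displacement field (white noise smoothed
#' with a Gaussian of the stated correlation length, rescaled to the target
#' mean displacement magnitude) and applies it identically to the MR, CT and
#' segmentation (nearest-neighbour for labels). Fields whose mapping
#' `x + u(x)` folds (non-positive Jacobian determinant anywhere) are rejected
#' and redrawn, up to `max_retry` times.
#'
#' @param entry a `template_entry` (or any list with `mr`, `ct`, `seg`).
#' @param amplitude_mm target mean displacement magnitude; 0 returns the
#'   input unchanged with a zero field.
#' @param seed RNG seed; the result is a pure function of inputs and seed.
#' @param correlation_mm Gaussian correlation length of the field.
#' @param max_retry retries on folding before giving up.
#' @return `list(entry = deformed entry, field = displacement array)`.
#' @export
apply_random_deformation <- function(entry, amplitude_mm = 6, seed = 1,
                                     correlation_mm = 30, max_retry = 10) {
  if (amplitude_mm < 0) stop("'amplitude_mm' must be non-negative")
  d <- dim(entry$seg$labels)
  if (amplitude_mm == 0)
    return(list(entry = entry, field = zero_field(d)))
  spacing <- entry$seg$spacing
  sigma_vox <- correlation_mm / spacing
  seeds <- derive_seeds(seed, max_retry, salt = 271L)
  for (attempt in seq_len(max_retry)) {
    field <- with_seed(seeds[attempt], {
      f <- array(stats::rnorm(prod(d) * 3), c(d, 3L))
      f <- smooth_field(f, sigma_vox)
      mag <- sqrt(f[, , , 1]^2 + f[, , , 2]^2 + f[, , , 3]^2)
      # amplitude = peak displacement magnitude of the drawn field
      f * (amplitude_mm / max(max(mag), 1e-12))
    })
    if (all(jacobian_determinant(field, spacing) > 0)) {
      out <- list(mr = warp_volume(entry$mr, field),
                  ct = warp_volume(entry$ct, field),
                  seg = warp_volume(entry$seg, field))
      class(out) <- class(entry)
      return(list(entry = out, field = field))
    }
  }
  stop("could not draw a fold-free deformation in ", max_retry, " attempts")
}

#' Generate the template database
#'
#' Independent anatomies obtained by re-drawing the canonical phantom's
#' per-label intensities and applying an independent random deformation per
#' template. The default database size mirrors a typical multi-atlas setup
#' of 15 paired MR/CT scans.
#'
#' @param n_templates number of atlas members (default 15).
#' @param seed master seed; every template derives from it deterministically.
#' @param grid_shape,spacing,params as in [make_canonical_pelvis()].
#' @return List of `template_entry` objects on one common lattice.
#' @export
make_template_database <- function(n_templates = 15, seed = 1,
                                   grid_shape = c(128, 128, 32),
                                   spacing = NULL,
                                   params = phantom_params()) {
  if (n_templates < 1) stop("'n_templates' must be at least 1")
  s_int <- derive_seeds(seed, n_templates, salt = 11L)
  s_def <- derive_seeds(seed, n_templates, salt = 23L)
  lapply(seq_len(n_templates), function(i) {
    canon <- make_canonical_pelvis(grid_shape, spacing, seed = s_int[i],
                                   params = params)
    ent <- apply_random_deformation(canon, params$deform_amplitude_mm,
                                    s_def[i],
                                    params$deform_correlation_mm)$entry
    # interpolation can drift a hair outside the HU range
    ent$ct$values <- pmin(pmax(ent$ct$values, params$hu_clip[1]),
                          params$hu_clip[2])
    ent
  })
}

## Draw 1..3 bowel-gas spheres in the anterior supra-prostatic soft tissue.
draw_gas_pockets <- function(seed, L) {
  with_seed(seed, {
    k <- sample(1:3, 1)
    lapply(seq_len(k), function(i) {
      list(centre = c(stats::runif(1, -0.15, 0.15) * L[1],
                      stats::runif(1, -0.25, -0.12) * L[2],
                      stats::runif(1, -0.05, 0.30) * L[3]),
           radius = stats::runif(1, 8, 16))
    })
  })
}

#' Generate a held-out subject cohort
#'
#' Subjects are drawn like templates (canonical anatomy, fresh intensity
#' draws, independent deformation) from a seed stream disjoint from the
#' template database. Each subject carries a ground-truth CT, an activity map
#' with elevated prostate uptake and a spherical hotspot inside the prostate,
#' VOI masks, and scan metadata. Bowel-gas pockets are drawn independently
#' for the CT anatomy (`ct_true`/`seg_true`) and the MR-session anatomy
#' (`mr`, activity), emulating bowel air that moves between examinations.
#'
#' @param n_subjects cohort size (default 12).
#' @param seed master seed.
#' @param hotspot_contrast hotspot uptake as a multiple of prostate uptake
#'   (must be >= 1; default 3).
#' @param grid_shape,spacing,params as in [make_canonical_pelvis()].
#' @return List of `subject` objects.
#' @export
make_subject_cohort <- function(n_subjects = 12, seed = 1,
                                hotspot_contrast = 3,
                                grid_shape = c(128, 128, 32),
                                spacing = NULL,
                                params = phantom_params()) {
  if (n_subjects < 1) stop("'n_subjects' must be at least 1")
  if (hotspot_contrast < 1) stop("'hotspot_contrast' must be >= 1")
  s_int <- derive_seeds(seed, n_subjects, salt = 104729L)
  s_def <- derive_seeds(seed, n_subjects, salt = 104743L)
  s_gas <- derive_seeds(seed, n_subjects, salt = 104759L)
  s_met <- derive_seeds(seed, n_subjects, salt = 104773L)
  lapply(seq_len(n_subjects), function(i) {
    make_one_subject(grid_shape, spacing, params, hotspot_contrast,
                     s_int[i], s_def[i], s_gas[i], s_met[i])
  })
}

make_one_subject <- function(grid_shape, spacing, params, hotspot_contrast,
                             seed_int, seed_def, seed_gas, seed_meta) {
  canon <- make_canonical_pelvis(grid_shape, spacing, seed = seed_int,
                                 params = params)
  def <- apply_random_deformation(canon, params$deform_amplitude_mm,
                                  seed_def, params$deform_correlation_mm)
  ent <- def$entry
  d <- dim(ent$seg$labels)
  sp <- ent$seg$spacing
  L <- d * sp
  lg <- ent$seg$legend

  # independent gas pockets for the two "sessions"
  gas <- derive_seeds(seed_gas, 2, salt = 5L)
  pockets_ct <- draw_gas_pockets(gas[1], L)
  pockets_mr <- draw_gas_pockets(gas[2], L)

  carve <- function(seg_arr, pockets) {
    ix <- voxel_index_grid(d)
    X <- (ix[, 1] - (d[1] + 1) / 2) * sp[1]
    Y <- (ix[, 2] - (d[2] + 1) / 2) * sp[2]
    Z <- (ix[, 3] - (d[3] + 1) / 2) * sp[3]
    v <- as.vector(seg_arr)
    for (p in pockets) {
      inside <- (X - p$centre[1])^2 + (Y - p$centre[2])^2 +
        (Z - p$centre[3])^2 <= p$radius^2
      v[inside & v == lg[["soft_tissue"]]] <- lg[["bowel_gas"]]
    }
    array(v, d)
  }

  seg_ct_arr <- carve(ent$seg$labels, pockets_ct)
  seg_mr_arr <- carve(ent$seg$labels, pockets_mr)

  ct_arr <- pmin(pmax(ent$ct$values, params$hu_clip[1]), params$hu_clip[2])
  ct_arr[seg_ct_arr == lg[["bowel_gas"]]] <- -1000
  mr_arr <- ent$mr$values
  mr_arr[seg_mr_arr == lg[["bowel_gas"]]] <- params$mr[["bowel_gas"]]

  seg_true <- label_map(seg_ct_arr, sp, ent$seg$origin, lg)

  meta <- with_seed(seed_meta, {
    list(dose = min(max(stats::rnorm(1, params$dose_mean, params$dose_sd),
                        params$dose_range[1]), params$dose_range[2]),
         weight = min(max(stats::rnorm(1, params$weight_mean, params$weight_sd),
                          params$weight_range[1]), params$weight_range[2]))
  })

  # activity on the MR-session anatomy, SUV units then Bq/ml
  suv <- unname(params$suv[names(lg)[match(as.vector(seg_mr_arr), lg)]])
  prost <- as.vector(seg_mr_arr) == lg[["prostate"]]
  hot <- hotspot_mask(seg_mr_arr, sp, params$hotspot_radius_mm, lg)
  suv[as.vector(hot)] <- hotspot_contrast * params$suv[["prostate"]]
  conc_per_suv <- meta$dose * 1e6 / (meta$weight * 1000)  # Bq/ml at SUV 1
  act <- array(suv * conc_per_suv, d)

  structure(list(
    mr = volume_grid(mr_arr, sp, ent$mr$origin, unit = "a.u."),
    ct_true = volume_grid(ct_arr, sp, ent$ct$origin, unit = "HU"),
    seg_true = seg_true,
    activity_true = volume_grid(act, sp, ent$ct$origin, unit = "Bq/ml"),
    voi_prostate = array(prost, d),
    voi_hotspot = hot,
    injected_dose = meta$dose,
    body_weight = meta$weight,
    deformation_truth = def$field
  ), class = "subject")
}

## Largest sphere (up to radius_mm) around the prostate centroid that fits
## entirely inside the prostate label.
hotspot_mask <- function(seg_arr, spacing, radius_mm, legend) {
  d <- dim(seg_arr)
  prost <- seg_arr == legend[["prostate"]]
  if (!any(prost)) stop("phantom has no prostate voxels")
  ix <- which(prost, arr.ind = TRUE)
  centre <- colMeans(ix)
  # seed at the prostate voxel nearest the centroid, so a small enough
  # sphere is always contained
  seed_d2 <- colSums((t(ix) - centre)^2 * spacing^2)
  seed <- ix[which.min(seed_d2), ]
  grid <- voxel_index_grid(d)
  dist2 <- ((grid[, 1] - seed[1]) * spacing[1])^2 +
    ((grid[, 2] - seed[2]) * spacing[2])^2 +
    ((grid[, 3] - seed[3]) * spacing[3])^2
  r <- radius_mm
  repeat {
    mask <- dist2 <= r^2
    if (any(mask) && all(prost[mask])) break
    if (r < min(spacing) / 4)
      stop("hotspot sphere cannot be placed inside the prostate")
    r <- 0.8 * r
  }
  array(mask, d)
}

#' @export
print.subject <- function(x, ...) {
  cat(sprintf("<subject> dose %.0f MBq, weight %.1f kg, prostate %d vox, hotspot %d vox\n",
              x$injected_dose, x$body_weight, sum(x$voi_prostate),
              sum(x$voi_hotspot)))
  invisible(x)
}
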