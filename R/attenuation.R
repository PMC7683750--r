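#' Bilinear HU-to-mu conversion parameters (511 keV)
#'
#' Parameters of the standard piecewise-linear conversion from CT numbers to
#' 511-keV linear attenuation coefficients: below the breakpoint, a
#' water-air mixture scaling; above it, a bone slope. Defaults are typical
#' published 511-keV values; the same parameters must be used for the real
#' CT and any synthetic CT so the comparison isolates the HU error.
#'
#' @param mu_water attenuation of water at 511 keV, cm^-1.
#' @param bone_slope slope above the breakpoint, cm^-1 per HU.
#' @param breakpoint HU value separating the two segments.
#' @return A `bilinear_params` list.
#' @export
bilinear_params <- function(mu_water = 0.096, bone_slope = 4.0e-5,
                            breakpoint = 0) {
  if (mu_water <= 0 || bone_slope < 0)
    stop("parameters must give non-decreasing segments")
  structure(list(mu_water = mu_water, bone_slope = bone_slope,
                 breakpoint = breakpoint),
            class = "bilinear_params")
}

#' Convert a CT volume to a 511-keV attenuation map
#'
#' mu = mu_water * (HU + 1000) / 1000 for HU <= breakpoint and
#' mu = mu_water + bone_slope * HU above it, clipped below at zero. The map
#' is continuous at the default breakpoint (0 HU) and monotone
#' non-decreasing.
#'
#' @param ct `volume_grid` in HU.
#' @param params [bilinear_params()].
#' @return `volume_grid` in cm^-1 (a mu-map).
#' @export
hu_to_mu <- function(ct, params = bilinear_params()) {
  hu <- ct$values
  if (any(!is.finite(hu))) stop("CT volume contains non-finite HU values")
  mu <- ifelse(hu <= params$breakpoint,
               params$mu_water * (hu + 1000) / 1000,
               params$mu_water + params$bone_slope * hu)
  mu <- pmax(mu, 0)
  volume_grid(array(mu, dim(hu)), ct$spacing, ct$origin, unit = "cm^-1")
}

#' Emulated Dixon-segmentation attenuation map
#'
#' Emulates a scanner's Dixon fat/water attenuation correction in the pelvic
#' field of view: every voxel receives a populational class attenuation
#' value — air (and bowel gas) 0, fat `mu_fat`, soft tissues `mu_soft` — and
#' all bone labels are assigned the fat value, reproducing the
#' characteristic bone-to-fat misclassification that underestimates bone
#' attenuation. The ground-truth segmentation stands in for the fat/water
#' decomposition, so bone misclassification is the only error source.
#'
#' @param ct_true `volume_grid` in HU (lattice reference).
#' @param seg_true `label_map` on the same lattice.
#' @param mu_fat,mu_soft class attenuation values, cm^-1.
#' @return `volume_grid` mu-map in cm^-1.
#' @export
dixon_ac_map <- function(ct_true, seg_true, mu_fat = 0.0864,
                         mu_soft = 0.0975) {
  stop_if_lattice_mismatch(ct_true, seg_true, "ct_true and seg_true")
  lg <- tissue_legend()
  class_mu <- c(air = 0, bowel_gas = 0, fat = mu_fat,
                soft_tissue = mu_soft, bladder = mu_soft, prostate = mu_soft,
                bone_cortical = mu_fat, bone_trabecular = mu_fat)
  lab <- as.vector(seg_true$labels)
  pos <- match(lab, lg[names(class_mu)])
  if (any(is.na(pos)))
    stop("unknown label id(s): ",
         paste(unique(lab[is.na(pos)]), collapse = ", "))
  mu <- unname(class_mu[pos])
  volume_grid(array(mu, dim(seg_true$labels)), seg_true$spacing,
              seg_true$origin, unit = "cm^-1")
}

#' Threshold a reference mu-map into bone and soft tissue
#'
#' Bone is defined as body voxels whose reference (CT-derived) attenuation
#' is strictly greater than the threshold; all remaining body voxels are
#' soft tissue. The two masks are disjoint and partition the body. The
#' segmentation is intended to be run per subject on that subject's own
#' CT-derived mu-map.
#'
#' @param mu_ref `volume_grid` mu-map, cm^-1.
#' @param body_mask logical array on the same lattice.
#' @param threshold cm^-1; default 0.102.
#' @return `list(bone = logical array, soft = logical array)`.
#' @export
segment_tissue <- function(mu_ref, body_mask, threshold = 0.102) {
  if (threshold <= 0) stop("'threshold' must be positive")
  if (!identical(dim(body_mask), dim(mu_ref$values)))
    stop("body mask must match the mu-map lattice")
  if (!any(body_mask)) stop("body mask is empty")
  bone <- body_mask & (mu_ref$values > threshold)
  soft <- body_mask & !bone
  list(bone = bone, soft = soft)
}
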