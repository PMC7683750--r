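#' Synthetic-CT generator configuration
#'
#' @param patch_radius half-width (voxels) of the cubic patch used for the
#'   local similarity kernel.
#' @param kernel_sigma2 kernel bandwidth (squared intensity units); `NULL`
#'   scales it to the mean patch MSD across candidates, so the weighting
#'   adapts to the image noise level.
#' @param label_sigma_mm smoothing of the structure indicator maps driving
#'   the constrained warp.
#' @param hu_clip HU range of the fused output.
#' @param register registration settings for the intensity stage
#'   ([register_settings()]).
#' @param refine registration settings for the label-driven refinement.
#' @return A config list for [generate_sct()].
#' @export
sct_config <- function(patch_radius = 2, kernel_sigma2 = NULL,
                       label_sigma_mm = 6, hu_clip = c(-1000, 2000),
                       register = register_settings(iterations = c(50, 25),
                                                    affine_maxit = 200),
                       refine = register_settings(iterations = c(25, 12))) {
  list(patch_radius = patch_radius, kernel_sigma2 = kernel_sigma2,
       label_sigma_mm = label_sigma_mm, hu_clip = hu_clip,
       register = register, refine = refine)
}

## Uniform (box) smoothing matrix of half-width r, rows renormalised.
box_matrix <- function(n, r) {
  if (r <= 0 || n == 1L) return(diag(n))
  i <- seq_len(n)
  S <- outer(i, i, function(a, b) as.numeric(abs(a - b) <= r))
  S / rowSums(S)
}

box_smooth3 <- function(arr, r) {
  d <- dim(arr)
  for (ax in 1:3)
    if (d[ax] > 1L) arr <- apply_axis(arr, ax, box_matrix(d[ax], r))
  arr
}

#' Patch-similarity fusion weights
#'
#' For each candidate, computes the local mean-squared MR intensity
#' difference D between the subject MR and the candidate's warped template
#' MR over a cubic patch centred at each voxel, and converts it to a
#' strictly positive weight `exp(-D / sigma2)`. A candidate identical to the
#' subject receives weight 1 everywhere; larger local mismatch gives
#' strictly smaller weight. With `kernel_sigma2 = NULL` the bandwidth is the
#' mean patch MSD over all candidates and voxels, so weights adapt to the
#' phantom's noise level.
#'
#' @param subject_mr `volume_grid`.
#' @param warped_template_mrs list of `volume_grid`s on the subject lattice.
#' @param patch_radius patch half-width in voxels.
#' @param kernel_sigma2 bandwidth; `NULL` for the adaptive default.
#' @return List of per-candidate weight arrays (values in (0, 1]).
#' @export
similarity_weights <- function(subject_mr, warped_template_mrs,
                               patch_radius = 2, kernel_sigma2 = NULL) {
  if (patch_radius < 0) stop("'patch_radius' must be non-negative")
  D <- lapply(warped_template_mrs, function(w) {
    stop_if_lattice_mismatch(subject_mr, w, "subject and warped template")
    box_smooth3((subject_mr$values - w$values)^2, patch_radius)
  })
  if (is.null(kernel_sigma2)) {
    kernel_sigma2 <- mean(vapply(D, mean, numeric(1)))
    if (kernel_sigma2 <= 0) kernel_sigma2 <- 1
  }
  lapply(D, function(dd) exp(-dd / kernel_sigma2))
}

#' Weighted-vote multi-atlas segmentation
#'
#' Each template's segmentation is warped to the subject by its
#' registration field; the final label at a voxel is the weighted majority
#' over templates, with weights from the patch similarity of each warped
#' template MR to the subject MR. Ties go to the lowest label id.
#'
#' @param subject_mr `volume_grid`.
#' @param templates list of `template_entry`.
#' @param fields list of displacement fields (one per template, mm).
#' @param weights optional list of per-template weight arrays; the default
#'   computes [similarity_weights()] on the warped template MRs.
#' @param patch_radius passed to [similarity_weights()].
#' @return `label_map` on the subject lattice.
#' @export
vote_segmentation <- function(subject_mr, templates, fields, weights = NULL,
                              patch_radius = 2) {
  if (length(templates) == 0) stop("at least one template is required")
  if (length(fields) != length(templates))
    stop("need exactly one field per template")
  warped_segs <- mapply(function(tp, u) warp_volume(tp$seg, u),
                        templates, fields, SIMPLIFY = FALSE)
  if (is.null(weights)) {
    warped_mrs <- mapply(function(tp, u) warp_volume(tp$mr, u),
                         templates, fields, SIMPLIFY = FALSE)
    weights <- similarity_weights(subject_mr, warped_mrs, patch_radius)
  }
  d <- dim(subject_mr$values)
  legend <- templates[[1]]$seg$legend
  ids <- sort(unname(legend))
  score <- matrix(0, prod(d), length(ids))
  for (i in seq_along(templates)) {
    lab <- as.vector(warped_segs[[i]]$labels)
    w <- as.vector(weights[[i]])
    for (j in seq_along(ids))
      score[, j] <- score[, j] + w * (lab == ids[j])
  }
  best <- max.col(score, ties.method = "first")  # first = lowest label id
  label_map(array(ids[best], d), subject_mr$spacing, subject_mr$origin,
            legend)
}

#' Constrained warping of templates to a target segmentation
#'
#' Refines each template's stage-1 registration with a registration driven
#' by agreement of the segmented structures (demons forces on smoothed
#' per-structure indicator maps) rather than raw intensity, then applies
#' the refined fields to the template CTs, producing one HU candidate per
#' template. A template whose warped segmentation already equals the target
#' receives a near-identity refinement.
#'
#' @param templates list of `template_entry`.
#' @param fields_stage1 list of stage-1 displacement fields.
#' @param target_seg `label_map` from [vote_segmentation()].
#' @param config [sct_config()].
#' @return List with `sct_candidates` (warped template CTs), `warped_mrs`
#'   (template MRs under the refined fields) and `fields` (refined fields).
#' @export
constrained_warp <- function(templates, fields_stage1, target_seg,
                             config = sct_config()) {
  if (length(templates) == 0) stop("at least one template is required")
  # group labels into driving structures: what matters for the CT candidates
  # is the bone/fat/gas/soft partition (soft organs share near-water HU)
  lg <- target_seg$legend
  groups <- list(bone = c(lg[["bone_cortical"]], lg[["bone_trabecular"]]),
                 fat = lg[["fat"]], gas = lg[["bowel_gas"]],
                 soft = c(lg[["soft_tissue"]], lg[["bladder"]],
                          lg[["prostate"]]))
  d <- dim(target_seg$labels)
  sp <- target_seg$spacing
  sig_vox <- config$label_sigma_mm / sp
  chan <- function(lab_arr) {
    lapply(groups, function(ids)
      gauss_smooth3(array(as.numeric(lab_arr %in% ids), d), sig_vox))
  }
  fixed_ch <- chan(as.vector(target_seg$labels))
  out <- lapply(seq_along(templates), function(i) {
    moving_ch <- chan(as.vector(templates[[i]]$seg$labels))
    u <- demons_multires(fixed_ch, moving_ch, sp, fields_stage1[[i]],
                         config$refine)
    list(ct = warp_volume(templates[[i]]$ct, u),
         mr = warp_volume(templates[[i]]$mr, u),
         field = u)
  })
  list(sct_candidates = lapply(out, `[[`, "ct"),
       warped_mrs = lapply(out, `[[`, "mr"),
       fields = lapply(out, `[[`, "field"))
}

#' Voxelwise weighted median fusion
#'
#' At each voxel the fused value is the weighted median of the candidate HU
#' values: the smallest candidate value v such that the cumulative weight of
#' candidates with value <= v reaches half the total weight. With equal
#' weights this is the ordinary (lower) median.
#'
#' @param candidates list of `volume_grid` HU candidates on one lattice.
#' @param weights list of per-candidate non-negative weight arrays; at every
#'   voxel the total weight must be positive.
#' @return `volume_grid` of fused HU values.
#' @export
fuse_weighted_median <- function(candidates, weights) {
  k <- length(candidates)
  if (k == 0) stop("at least one candidate is required")
  if (length(weights) != k) stop("need one weight array per candidate")
  d <- dim(candidates[[1]]$values)
  V <- matrix(vapply(candidates, function(c) as.vector(c$values),
                     numeric(prod(d))), nrow = prod(d))
  W <- matrix(vapply(weights, as.vector, numeric(prod(d))),
              nrow = prod(d))
  if (k == 1L) {
    if (any(W <= 0)) stop("total weight must be positive at every voxel")
    return(candidates[[1]])
  }
  if (any(rowSums(W) <= 0))
    stop("total weight must be positive at every voxel")
  # vectorised compare-exchange sorting network over the k columns,
  # carrying weights with values
  for (pass in seq_len(k - 1)) {
    for (j in seq_len(k - 1)) {
      swap <- V[, j] > V[, j + 1]
      if (any(swap)) {
        tv <- V[swap, j]; V[swap, j] <- V[swap, j + 1]; V[swap, j + 1] <- tv
        tw <- W[swap, j]; W[swap, j] <- W[swap, j + 1]; W[swap, j + 1] <- tw
      }
    }
  }
  half <- rowSums(W) / 2
  cum <- W[, 1]
  idx <- rep.int(1L, nrow(V))
  done <- cum >= half
  for (j in 2:k) {
    cum <- cum + W[, j]
    newly <- !done & cum >= half
    idx[newly] <- j
    done <- done | newly
  }
  fused <- V[cbind(seq_len(nrow(V)), idx)]
  volume_grid(array(fused, d), candidates[[1]]$spacing,
              candidates[[1]]$origin, unit = "HU")
}

#' Generate a synthetic CT from a subject MR
#'
#' Full multi-atlas pipeline: register every template MR to the subject MR
#' (affine + free-form), produce a weighted-vote segmentation of the
#' subject, refine each template's field with the label-driven constrained
#' warp, weight each warped template CT by local MR patch similarity, and
#' fuse with the voxelwise weighted median. Output HU values are clipped to
#' the configured range.
#'
#' @param subject_mr `volume_grid`.
#' @param templates list of `template_entry`.
#' @param config [sct_config()].
#' @return `volume_grid` in HU on the subject lattice.
#' @export
generate_sct <- function(subject_mr, templates, config = sct_config()) {
  if (length(templates) == 0) stop("at least one template is required")
  fields1 <- lapply(templates, function(tp)
    register_volumes(subject_mr, tp$mr, settings = config$register))
  target_seg <- vote_segmentation(subject_mr, templates, fields1,
                                  patch_radius = config$patch_radius)
  cw <- constrained_warp(templates, fields1, target_seg, config)
  w <- similarity_weights(subject_mr, cw$warped_mrs, config$patch_radius,
                          config$kernel_sigma2)
  sct <- fuse_weighted_median(cw$sct_candidates, w)
  sct$values <- pmin(pmax(sct$values, config$hu_clip[1]), config$hu_clip[2])
  sct
}
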