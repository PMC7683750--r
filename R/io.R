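#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file into a [volume_grid()] (or [label_map()] with
#' `as = "label"`), honouring voxel spacing and origin from the stored
#' transform.
#'
#' @param path file path (.nii or .nii.gz).
#' @param as "volume" (default) or "label".
#' @param legend legend for label maps.
#' @return `volume_grid` or `label_map`.
#' @export
read_volume <- function(path, as = c("volume", "label"),
                        legend = tissue_legend()) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("cannot read NIfTI file '", path, "': ",
                         conditionMessage(e)))
  aff <- RNifti::xform(img)
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("invalid header in '", path, "': non-positive pixdim/xform scaling")
  origin <- aff[1:3, 4]
  vals <- array(as.vector(img), dim(img))
  if (length(dim(vals)) == 2L) dim(vals) <- c(dim(vals), 1L)
  if (as == "label")
    label_map(array(as.integer(round(vals)), dim(vals)), spacing, origin,
              legend)
  else volume_grid(vals, spacing, origin)
}

#' Write a volume to NIfTI
#'
#' Writes double-precision NIfTI-1 with a diagonal affine built from the
#' spacing and origin, so a write/read round trip reproduces values and
#' geometry exactly.
#'
#' @param volume `volume_grid` or `label_map`.
#' @param path output path (.nii or .nii.gz).
#' @export
write_volume <- function(volume, path) {
  vals <- if (inherits(volume, "label_map")) volume$labels else volume$values
  aff <- diag(4)
  diag(aff)[1:3] <- volume$spacing
  aff[1:3, 4] <- volume$origin
  img <- RNifti::asNifti(vals)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path,
                     datatype = if (inherits(volume, "label_map")) "int32"
                                else "double")
  invisible(path)
}

#' Write a phantom cohort to a directory
#'
#' One subdirectory per template (`template_XX`) and subject
#' (`subject_XX`), each holding NIfTI volumes plus a JSON metadata sidecar
#' (dose, weight).
#'
#' @param templates list of `template_entry` (may be `NULL`).
#' @param subjects list of `subject` (may be `NULL`).
#' @param dir output directory.
#' @export
write_cohort <- function(templates = NULL, subjects = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(templates)) {
    td <- file.path(dir, sprintf("template_%02d", i))
    dir.create(td, showWarnings = FALSE)
    write_volume(templates[[i]]$mr, file.path(td, "mr.nii.gz"))
    write_volume(templates[[i]]$ct, file.path(td, "ct.nii.gz"))
    write_volume(templates[[i]]$seg, file.path(td, "seg.nii.gz"))
  }
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    sd <- file.path(dir, sprintf("subject_%02d", i))
    dir.create(sd, showWarnings = FALSE)
    write_volume(s$mr, file.path(sd, "mr.nii.gz"))
    write_volume(s$ct_true, file.path(sd, "ct.nii.gz"))
    write_volume(s$seg_true, file.path(sd, "seg.nii.gz"))
    write_volume(s$activity_true, file.path(sd, "act.nii.gz"))
    write_volume(volume_grid(array(as.numeric(s$voi_prostate),
                                   dim(s$voi_prostate)),
                             s$mr$spacing, s$mr$origin),
                 file.path(sd, "voi_prostate.nii.gz"))
    write_volume(volume_grid(array(as.numeric(s$voi_hotspot),
                                   dim(s$voi_hotspot)),
                             s$mr$spacing, s$mr$origin),
                 file.path(sd, "voi_hotspot.nii.gz"))
    jsonlite::write_json(list(injected_dose_MBq = s$injected_dose,
                              body_weight_kg = s$body_weight),
                         file.path(sd, "meta.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Load a template directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return List of `template_entry`.
#' @export
read_templates <- function(dir) {
  tds <- sort(list.dirs(dir, recursive = FALSE))
  tds <- tds[grepl("template_", basename(tds))]
  if (!length(tds)) stop("no template_* directories under ", dir)
  lapply(tds, function(td) {
    structure(list(mr = read_volume(file.path(td, "mr.nii.gz")),
                   ct = read_volume(file.path(td, "ct.nii.gz")),
                   seg = read_volume(file.path(td, "seg.nii.gz"),
                                     as = "label")),
              class = "template_entry")
  })
}

#' Default pipeline configuration
#'
#' All tunables of the end-to-end study in one serialisable list; a YAML
#' round trip reproduces it exactly. Defaults echo the emulated clinical
#' protocol: 15 templates, 12 subjects, 2 OSEM iterations with 28 subsets,
#' and the 0.102 cm^-1 bone threshold.
#'
#' @param seed master seed.
#' @param n_templates,n_subjects cohort sizes.
#' @param grid_shape phantom grid.
#' @param n_angles projection angles (divisible by `n_subsets`).
#' @param n_iterations,n_subsets OSEM protocol.
#' @param noise_scale expected counts per slice (NULL/NA = noise-free).
#' @param n_missing_slices inferior CT slices missing and re-padded.
#' @param bone_threshold bone segmentation threshold, cm^-1.
#' @param floor_frac reference floor for percentage maps.
#' @param hotspot_contrast hotspot-to-prostate uptake ratio.
#' @param common_space compute cohort common-space mean error maps.
#' @return A config list.
#' @export
pipeline_config <- function(seed = 1, n_templates = 15, n_subjects = 12,
                            grid_shape = c(128, 128, 32), n_angles = 112,
                            n_iterations = 2, n_subsets = 28,
                            noise_scale = NULL, n_missing_slices = 3,
                            bone_threshold = 0.102, floor_frac = 0.05,
                            hotspot_contrast = 3, common_space = TRUE) {
  list(seed = as.integer(seed), n_templates = as.integer(n_templates),
       n_subjects = as.integer(n_subjects),
       grid_shape = as.integer(grid_shape),
       n_angles = as.integer(n_angles),
       n_iterations = as.integer(n_iterations),
       n_subsets = as.integer(n_subsets),
       noise_scale = if (is.null(noise_scale) || is.na(noise_scale))
         NA_real_ else as.numeric(noise_scale),
       n_missing_slices = as.integer(n_missing_slices),
       bone_threshold = as.numeric(bone_threshold),
       floor_frac = as.numeric(floor_frac),
       hotspot_contrast = as.numeric(hotspot_contrast),
       common_space = isTRUE(common_space))
}

#' Save / load a pipeline configuration as YAML
#'
#' @param config list from [pipeline_config()].
#' @param path YAML file path.
#' @return `load_config` returns the config list.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, c(
    raw[setdiff(names(raw), "noise_scale")],
    list(noise_scale = if (is.null(raw$noise_scale) ||
                           is.na(raw$noise_scale)) NULL else raw$noise_scale)
  ))
}
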