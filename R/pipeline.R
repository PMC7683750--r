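## Moment skewness (population).
skewness <- function(x) {
  x <- x[!is.na(x)]
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  if (s < 1e-12) return(0)
  mean((x - m)^3) / s^3
}

## Crop the n most inferior slices, then repeat the new inferior slice to
## restore the extent (field-of-view emulation). Returns volume + validity.
emulate_missing_slices <- function(ct, n) {
  if (n == 0)
    return(list(volume = ct, valid_slices = rep(TRUE, dim(ct$values)[3])))
  d <- dim(ct$values)
  cropped <- volume_grid(ct$values[, , (n + 1):d[3], drop = FALSE],
                         ct$spacing,
                         ct$origin + c(0, 0, n * ct$spacing[3]), ct$unit)
  extend_fov_slices(cropped, n)
}

## Contour implied by a Dixon-style mu-map (mu > 0, holes filled).
contour_from_mu <- function(mu) {
  pseudo <- volume_grid(ifelse(mu$values > 0, 0, -1000), mu$spacing,
                        mu$origin, "HU")
  body_contour(pseudo)
}

process_subject <- function(s, templates, geom, config, noise_seed,
                            sct = NULL) {
  if (is.null(sct)) sct <- generate_sct(s$mr, templates)

  fov <- emulate_missing_slices(s$ct_true, config$n_missing_slices)
  body_ct <- body_contour(fov$volume)
  ct_p <- replace_air_pockets(fov$volume, body_ct)
  sct_p <- replace_air_pockets(sct, body_contour(sct))

  mu_dixon <- dixon_ac_map(s$ct_true, s$seg_true)
  ref_contour <- contour_from_mu(mu_dixon)
  ct_h <- harmonize_contour(ct_p, ref_contour)
  sct_h <- harmonize_contour(sct_p, ref_contour)

  mu_ct <- hu_to_mu(ct_h)
  mu_sda <- hu_to_mu(sct_h)

  sino <- forward_project(s$activity_true, mu_ct, geom,
                          noise_scale = if (is.na(config$noise_scale)) NULL
                                        else config$noise_scale)
  if (!is.na(config$noise_scale)) sino <- add_poisson_noise(sino, noise_seed)

  rc <- recon_config(config$n_iterations, config$n_subsets)
  recs <- list(ct = osem_reconstruct(sino, mu_ct, rc),
               dixon = osem_reconstruct(sino, mu_dixon, rc),
               sda = osem_reconstruct(sino, mu_sda, rc))
  suvs <- lapply(recs, to_suv, injected_dose = s$injected_dose,
                 body_weight = s$body_weight)

  tissues <- segment_tissue(mu_ct, ref_contour, config$bone_threshold)
  pet_mask <- make_eval_mask(suvs$ct, ref_contour, fov$valid_slices,
                             config$floor_frac)
  ac_mask <- make_eval_mask(mu_ct, ref_contour, fov$valid_slices,
                            config$floor_frac)

  diff <- list(
    pet = list(dixon = percent_diff_map(suvs$dixon, suvs$ct, pet_mask),
               sda = percent_diff_map(suvs$sda, suvs$ct, pet_mask)),
    ac = list(dixon = percent_diff_map(mu_dixon, mu_ct, ac_mask),
              sda = percent_diff_map(mu_sda, mu_ct, ac_mask)))

  stats <- do.call(rbind, lapply(names(diff), function(mod) {
    do.call(rbind, lapply(names(diff[[mod]]), function(meth) {
      st <- region_error_stats(diff[[mod]][[meth]], tissues$bone,
                               tissues$soft, ref_contour)
      cbind(modality = mod, method = meth, st)
    }))
  }))

  # PET slices without real CT data are excluded from all analyses,
  # including the VOIs
  d <- dim(s$mr$values)
  valid_arr <- array(rep(fov$valid_slices, each = d[1] * d[2]), d)
  voi <- voi_suv_error(suvs, list(prostate = s$voi_prostate & valid_arr,
                                  hotspot = s$voi_hotspot & valid_arr))

  list(stats = stats, voi = voi, diff = diff, body = ref_contour,
       tissues = tissues, mr = s$mr, sct = sct)
}

#' Run the full evaluation pipeline
#'
#' Orchestrates the end-to-end study on a synthetic cohort: phantom
#' generation (template database + held-out subjects), synthetic-CT
#' generation per subject, attenuation-map construction for the three
#' methods (CT reference, Dixon emulation, synthetic CT), pre-processing
#' (missing-slice padding, air-pocket replacement, contour harmonisation),
#' attenuated PET simulation and OSEM reconstruction per method, and the
#' quantitative error analysis with VOI SUV errors and paired Wilcoxon
#' tests. Heavy stages (templates, subjects, synthetic CTs) are cached
#' under `out_dir/cache` keyed by the configuration, and a deleted cache
#' stage is recomputed identically; the whole run is a pure function of the
#' configuration.
#'
#' @param config [pipeline_config()].
#' @param out_dir output directory (created if needed); per-subject and
#'   cohort CSV tables, a JSON summary, the resolved YAML configuration and
#'   (optionally) common-space error maps are written there.
#' @param keep_maps write common-space mean error maps as NIfTI.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with per-subject tables, cohort summaries,
#'   VOI results and test results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         keep_maps = FALSE, quiet = FALSE) {
  t_start <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  cfg_file <- file.path(cache_dir, "config.rds")
  if (file.exists(cfg_file) && !identical(readRDS(cfg_file), config)) {
    unlink(list.files(cache_dir, full.names = TRUE))
  }
  saveRDS(config, cfg_file)
  cached <- function(name, fun) {
    f <- file.path(cache_dir, paste0(name, ".rds"))
    if (file.exists(f)) return(readRDS(f))
    val <- fun()
    saveRDS(val, f)
    val
  }
  say <- function(...) if (!quiet) message(sprintf(...))

  say("[phantom] %d templates, %d subjects", config$n_templates,
      config$n_subjects)
  templates <- cached("templates", function()
    make_template_database(config$n_templates, config$seed,
                           grid_shape = config$grid_shape))
  subjects <- cached("subjects", function()
    make_subject_cohort(config$n_subjects, config$seed,
                        hotspot_contrast = config$hotspot_contrast,
                        grid_shape = config$grid_shape))

  geom <- pet_geometry(config$grid_shape[1:2],
                       subjects[[1]]$mr$spacing[1:2], config$n_angles)
  noise_seeds <- derive_seeds(config$seed, config$n_subjects, salt = 33301L)

  results <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    t0 <- Sys.time()
    sct <- cached(sprintf("sct_%02d", i), function()
      generate_sct(subjects[[i]]$mr, templates))
    results[[i]] <- process_subject(subjects[[i]], templates, geom, config,
                                    noise_seeds[i], sct = sct)
    say("[subject %02d] done in %.1f s", i,
        as.numeric(Sys.time() - t0, units = "secs"))
  }

  per_subject <- do.call(rbind, lapply(seq_along(results), function(i)
    cbind(subject = i, results[[i]]$stats)))
  voi_tab <- do.call(rbind, lapply(seq_along(results), function(i)
    cbind(subject = i, results[[i]]$voi)))

  cohort <- do.call(rbind, lapply(c("pet", "ac"), function(mod)
    do.call(rbind, lapply(c("dixon", "sda"), function(meth) {
      sl <- lapply(results, function(r)
        r$stats[r$stats$modality == mod & r$stats$method == meth,
                c("region", "n_voxels", "mean", "sd", "mae", "rmse")])
      cbind(modality = mod, method = meth, cohort_error_stats(sl))
    }))))

  # paired Wilcoxon: Dixon vs SDA percentage SUV error, per VOI
  tests <- lapply(c(prostate = "prostate", hotspot = "hotspot"),
                  function(vn) {
    dx <- voi_tab$pct_delta_suv[voi_tab$voi == vn & voi_tab$method == "dixon"]
    sd_ <- voi_tab$pct_delta_suv[voi_tab$voi == vn & voi_tab$method == "sda"]
    wilcoxon_signed_rank(dx, sd_)
  })

  # pooled voxel errors per method/region for the histogram summaries
  pooled <- lapply(c(dixon = "dixon", sda = "sda"), function(meth) {
    lapply(list(whole = "body", bone = "bone", soft = "soft"),
           function(reg) {
      unlist(lapply(results, function(r) {
        mask <- switch(reg, body = r$body, bone = r$tissues$bone,
                       soft = r$tissues$soft)
        v <- r$diff$pet[[meth]]$values[mask]
        v[!is.na(v)]
      }))
    })
  })
  hist_summary <- lapply(pooled, function(by_reg)
    lapply(by_reg, function(v)
      list(mean = mean(v), sd = stats::sd(v), skewness = skewness(v),
           n = length(v))))

  common <- NULL
  if (config$common_space && config$n_subjects >= 2) {
    say("[common space] registering %d subjects", config$n_subjects)
    mrs <- lapply(results, `[[`, "mr")
    bodies <- lapply(results, `[[`, "body")
    common <- lapply(c(dixon = "dixon", sda = "sda"), function(meth)
      common_space_mean_map(lapply(results, function(r) r$diff$pet[[meth]]),
                            mrs, body_masks = bodies))
    if (keep_maps) {
      for (meth in names(common))
        write_volume(volume_grid(
          ifelse(is.na(common[[meth]]$map$values), 0,
                 common[[meth]]$map$values),
          common[[meth]]$map$spacing, common[[meth]]$map$origin),
          file.path(out_dir, sprintf("common_space_pet_%s.nii.gz", meth)))
    }
  }

  utils::write.csv(per_subject, file.path(out_dir, "per_subject_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort, file.path(out_dir, "cohort_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(voi_tab, file.path(out_dir, "voi_results.csv"),
                   row.names = FALSE)
  save_config(config, file.path(out_dir, "config.yaml"))

  voi_means <- stats::aggregate(pct_delta_suv ~ voi + method, voi_tab, mean)
  summary <- list(
    config = config,
    cohort = cohort,
    voi_mean_pct_delta_suv = voi_means,
    wilcoxon = lapply(tests, function(t)
      list(statistic = t$statistic, p_value = t$p_value,
           n_effective = t$n_effective, method = t$method)),
    histograms = hist_summary,
    common_space_reference = if (is.null(common)) NA_integer_
                             else common$dixon$reference
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE, na = "null")
  say("[done] total %.1f min",
      as.numeric(Sys.time() - t_start, units = "mins"))

  invisible(list(per_subject = per_subject, cohort = cohort, voi = voi_tab,
                 tests = tests, histograms = hist_summary, common = common,
                 summary_file = file.path(out_dir, "summary.json")))
}
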