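#' Evaluation mask for percentage-difference maps
#'
#' Restricts voxelwise percentage comparisons to body voxels on valid
#' slices whose reference value is above a floor (a fraction of the body
#' mean), guarding the denominator against near-zero reference values that
#' would otherwise dominate the error histograms.
#'
#' @param reference `volume_grid` (the reference image).
#' @param body logical body mask.
#' @param valid_slices logical per-slice vector, or `NULL` for all.
#' @param floor_frac reference floor as a fraction of the body-mean
#'   reference value (default 0.05).
#' @return Logical array.
#' @export
make_eval_mask <- function(reference, body, valid_slices = NULL,
                           floor_frac = 0.05) {
  d <- dim(reference$values)
  mask <- body
  if (!is.null(valid_slices)) {
    keep <- array(rep(valid_slices, each = d[1] * d[2]), d)
    mask <- mask & keep
  }
  floor_val <- floor_frac * mean(reference$values[body])
  mask & (reference$values > floor_val)
}

#' Voxelwise percentage-difference map
#'
#' 100 * (test - reference) / reference inside the mask; `NA` outside.
#'
#' @param test,reference `volume_grid`s on one lattice.
#' @param mask logical array (see [make_eval_mask()]).
#' @return `volume_grid` of percentages with `NA` outside the mask.
#' @export
percent_diff_map <- function(test, reference, mask) {
  stop_if_lattice_mismatch(test, reference, "test and reference")
  if (!any(mask)) stop("evaluation mask is empty")
  out <- array(NA_real_, dim(test$values))
  out[mask] <- 100 * (test$values[mask] - reference$values[mask]) /
    reference$values[mask]
  volume_grid(out, test$spacing, test$origin, unit = "%")
}

#' Regional error statistics of a percentage-difference map
#'
#' Mean, standard deviation, mean absolute error and root-mean-square error
#' of the masked percentage differences, for the whole body and separately
#' for bone and soft tissue. The SD is the population SD (divisor n), so
#' RMSE^2 = mean^2 + SD^2 holds exactly per region.
#'
#' @param diff_map `volume_grid` from [percent_diff_map()] (`NA` outside
#'   its mask).
#' @param bone_mask,soft_mask,body_mask logical arrays.
#' @return data.frame with one row per region (`whole`, `bone`, `soft`).
#' @export
region_error_stats <- function(diff_map, bone_mask, soft_mask, body_mask) {
  one <- function(region, mask) {
    v <- diff_map$values[mask]
    v <- v[!is.na(v)]
    n <- length(v)
    if (n == 0)
      return(data.frame(region = region, n_voxels = 0L, mean = NA_real_,
                        sd = NA_real_, mae = NA_real_, rmse = NA_real_))
    m <- mean(v)
    sd_pop <- sqrt(mean((v - m)^2))
    data.frame(region = region, n_voxels = n, mean = m, sd = sd_pop,
               mae = mean(abs(v)), rmse = sqrt(mean(v^2)))
  }
  rbind(one("whole", body_mask), one("bone", bone_mask),
        one("soft", soft_mask))
}

#' Cohort summary of per-subject error statistics
#'
#' @param stats_list list of per-subject data.frames from
#'   [region_error_stats()].
#' @param mode "mean" (unweighted mean of per-subject statistics, default)
#'   or "pooled" (voxel-pooled: statistics weighted by per-subject voxel
#'   counts; approximates pooling all voxels for mean/MAE/RMSE).
#' @return data.frame with one row per region.
#' @export
cohort_error_stats <- function(stats_list, mode = c("mean", "pooled")) {
  mode <- match.arg(mode)
  all <- do.call(rbind, stats_list)
  out <- do.call(rbind, lapply(split(all, all$region), function(g) {
    w <- if (mode == "pooled") g$n_voxels else rep(1, nrow(g))
    w <- w / sum(w)
    m <- sum(w * g$mean)
    msq <- sum(w * g$rmse^2)
    data.frame(region = g$region[1], n_subjects = nrow(g),
               n_voxels = sum(g$n_voxels), mean = m,
               sd = if (mode == "pooled") sqrt(max(msq - m^2, 0))
                    else sum(w * g$sd),
               mae = sum(w * g$mae),
               rmse = if (mode == "pooled") sqrt(msq) else sum(w * g$rmse))
  }))
  rownames(out) <- NULL
  out[match(c("whole", "bone", "soft"), out$region), ]
}

#' Cohort mean error map in a common space
#'
#' Registers every subject's MR to a reference subject's MR and applies the
#' resulting deformations to the subjects' error maps, then averages
#' voxelwise over subjects wherever at least half the cohort contributes.
#' The default reference is the subject whose body volume is closest to the
#' cohort median (an "average-sized" anatomy).
#'
#' @param error_maps list of `volume_grid` percentage maps (`NA` outside
#'   their masks).
#' @param subject_mrs list of `volume_grid` MR volumes.
#' @param reference_subject index of the reference subject, or `NULL` for
#'   the median-body-volume choice.
#' @param body_masks list of logical body masks (used for the default
#'   reference choice; optional otherwise).
#' @param settings registration settings.
#' @return `list(map = volume_grid, n_contrib = array, reference = index)`.
#' @export
common_space_mean_map <- function(error_maps, subject_mrs,
                                  reference_subject = NULL,
                                  body_masks = NULL,
                                  settings = register_settings()) {
  n <- length(error_maps)
  stopifnot(n == length(subject_mrs))
  if (is.null(reference_subject)) {
    if (is.null(body_masks))
      stop("body_masks needed to choose the median-volume reference")
    vols <- vapply(body_masks, sum, numeric(1))
    reference_subject <- which.min(abs(vols - stats::median(vols)))
  }
  ref_mr <- subject_mrs[[reference_subject]]
  d <- dim(ref_mr$values)
  acc <- array(0, d)
  cnt <- array(0, d)
  for (i in seq_len(n)) {
    if (i == reference_subject) {
      u <- zero_field(d)
    } else {
      u <- register_volumes(ref_mr, subject_mrs[[i]], settings = settings)
    }
    vals <- error_maps[[i]]$values
    valid <- !is.na(vals)
    vals[!valid] <- 0
    wa <- warp_volume(volume_grid(vals, error_maps[[i]]$spacing), u)
    wv <- warp_volume(volume_grid(array(as.numeric(valid), d),
                                  error_maps[[i]]$spacing), u)
    contrib <- wv$values > 0.5
    acc[contrib] <- acc[contrib] + wa$values[contrib] / wv$values[contrib]
    cnt <- cnt + contrib
  }
  out <- array(NA_real_, d)
  keep <- cnt >= n / 2
  out[keep] <- acc[keep] / cnt[keep]
  list(map = volume_grid(out, ref_mr$spacing, ref_mr$origin, unit = "%"),
       n_contrib = cnt, reference = reference_subject)
}

#' VOI SUV errors relative to a reference method
#'
#' Mean SUV inside each VOI for each reconstruction method and the
#' percentage SUV deviation from the reference method.
#'
#' @param suv_by_method named list of `volume_grid` SUV images; must include
#'   `reference`.
#' @param vois named list of logical VOI masks.
#' @param reference name of the reference method (default "ct").
#' @return data.frame with columns voi, method, suv_mean, pct_delta_suv.
#' @export
voi_suv_error <- function(suv_by_method, vois, reference = "ct") {
  if (!reference %in% names(suv_by_method))
    stop("reference method '", reference, "' missing")
  out <- do.call(rbind, lapply(names(vois), function(vn) {
    mask <- vois[[vn]]
    if (!any(mask)) stop("VOI '", vn, "' is empty")
    ref_mean <- mean(suv_by_method[[reference]]$values[mask])
    do.call(rbind, lapply(names(suv_by_method), function(mn) {
      m <- mean(suv_by_method[[mn]]$values[mask])
      data.frame(voi = vn, method = mn, suv_mean = m,
                 pct_delta_suv = 100 * (m - ref_mean) / ref_mean)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on the paired differences. Zero differences are dropped
#' (the original convention); ties receive mid-ranks. For 15 or fewer
#' non-zero differences the p-value is exact, obtained by enumerating all
#' 2^n sign assignments of the observed rank magnitudes (so it remains
#' exact under ties); above that a normal approximation with tie and
#' continuity corrections is used. If every difference is zero the result
#' is defined as p = 1 with a warning.
#'
#' @param paired_a,paired_b equal-length numeric vectors.
#' @return list with `statistic` (V, sum of positive ranks), `p_value`,
#'   `n_effective` and `method`.
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b))
    stop("paired samples must have equal length")
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p-value defined as 1")
    return(list(statistic = NA_real_, p_value = 1, n_effective = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 15) {
    # exact: subset-sum distribution of the observed rank magnitudes
    sums <- 0
    for (ri in r) sums <- c(sums, sums + ri)
    tol <- 1e-9
    p_ge <- mean(sums >= V - tol)
    p_le <- mean(sums <= V + tol)
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  list(statistic = V, p_value = p, n_effective = n, method = method)
}

#' Histogram of percentage errors
#'
#' Fixed-width bins centred on zero over the masked voxels.
#'
#' @param diff_map `volume_grid` percentage map (`NA` outside its mask).
#' @param mask optional logical array restricting further.
#' @param bin_width percentage points per bin (default 1).
#' @return data.frame with bin midpoints and counts.
#' @export
error_histogram <- function(diff_map, mask = NULL, bin_width = 1) {
  v <- diff_map$values
  if (!is.null(mask)) v <- v[mask]
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("no values to histogram")
  k <- max(1, ceiling((max(abs(v)) + bin_width / 2) / bin_width))
  h <- graphics::hist(v, breaks = seq(-(k + 0.5) * bin_width,
                                      (k + 0.5) * bin_width,
                                      by = bin_width), plot = FALSE)
  data.frame(mid = h$mids, count = h$counts)
}
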