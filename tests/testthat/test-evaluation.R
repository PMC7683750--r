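test_that("percentage maps scale correctly and respect the floor", {
  d <- c(4, 4, 2)
  ref <- volume_grid(array(10, d))
  mask <- array(TRUE, d)
  expect_true(all(percent_diff_map(ref, ref, mask)$values == 0))

  t9 <- volume_grid(array(9, d))
  expect_true(all(abs(percent_diff_map(t9, ref, mask)$values + 10) < 1e-12))

  # voxels under the reference floor drop out of the mask
  ref2 <- ref
  ref2$values[1, 1, 1] <- 0.01
  body <- array(TRUE, d)
  m <- make_eval_mask(ref2, body, floor_frac = 0.05)
  expect_false(m[1, 1, 1])
  expect_equal(sum(m), prod(d) - 1)
  pm <- percent_diff_map(t9, ref2, m)
  expect_true(is.na(pm$values[1, 1, 1]))

  # padded slices are excluded via the validity vector
  m2 <- make_eval_mask(ref, body, valid_slices = c(FALSE, TRUE))
  expect_true(all(!m2[, , 1]) && all(m2[, , 2]))

  expect_error(percent_diff_map(t9, ref, array(FALSE, d)), "empty")
})

test_that("regional statistics reproduce the hand-computed example", {
  d <- c(3, 1, 1)
  diffs <- volume_grid(array(c(-2, 0, 2), d))
  all_mask <- array(TRUE, d)
  st <- region_error_stats(diffs, all_mask, all_mask, all_mask)
  expect_equal(st$mean, rep(0, 3))
  expect_equal(st$sd, rep(1.6329932, 3), tolerance = 1e-6)
  expect_equal(st$mae, rep(4 / 3, 3), tolerance = 1e-12)
  expect_equal(st$rmse, rep(1.6329932, 3), tolerance = 1e-6)
  # population-SD identity rmse^2 = mean^2 + sd^2
  expect_equal(st$rmse^2, st$mean^2 + st$sd^2, tolerance = 1e-12)

  zero <- volume_grid(array(0, d))
  st0 <- region_error_stats(zero, all_mask, all_mask, all_mask)
  expect_true(all(unlist(st0[, c("mean", "sd", "mae", "rmse")]) == 0))
})

test_that("rmse identity holds on random maps and cohort summaries combine", {
  set.seed(8)
  d <- c(6, 6, 3)
  stats_list <- lapply(1:4, function(i) {
    dm <- volume_grid(array(stats::rnorm(prod(d), mean = -2, sd = 4), d))
    m <- array(TRUE, d)
    st <- region_error_stats(dm, m, m, m)
    expect_equal(st$rmse^2, st$mean^2 + st$sd^2, tolerance = 1e-10)
    st
  })
  co <- cohort_error_stats(stats_list)
  expect_identical(co$region, c("whole", "bone", "soft"))
  expect_equal(co$mean[1], mean(vapply(stats_list, function(s) s$mean[1],
                                       numeric(1))))
  pooled <- cohort_error_stats(stats_list, mode = "pooled")
  expect_equal(pooled$rmse[1]^2, pooled$mean[1]^2 + pooled$sd[1]^2,
               tolerance = 1e-10)
})

test_that("VOI SUV errors follow scaling and spatially varying bias", {
  d <- c(8, 8, 2)
  ref <- volume_grid(array(2, d))
  scaled <- volume_grid(array(2 * 0.944, d))
  voi_a <- array(FALSE, d); voi_a[1:4, , ] <- TRUE
  voi_b <- array(FALSE, d); voi_b[1:2, 1:2, 1] <- TRUE
  res <- voi_suv_error(list(ct = ref, m = scaled),
                       list(prostate = voi_a, hotspot = voi_b))
  expect_equal(res$pct_delta_suv[res$method == "ct"], c(0, 0))
  expect_equal(res$pct_delta_suv[res$method == "m"], c(-5.6, -5.6),
               tolerance = 1e-9)

  # spatially varying bias: hotspot and prostate errors differ
  biased <- ref
  biased$values[voi_b] <- 2 * 0.8
  res2 <- voi_suv_error(list(ct = ref, m = biased),
                        list(prostate = voi_a, hotspot = voi_b))
  dm <- res2[res2$method == "m", ]
  expect_lt(dm$pct_delta_suv[dm$voi == "hotspot"],
            dm$pct_delta_suv[dm$voi == "prostate"])
  expect_error(voi_suv_error(list(ct = ref), list(v = array(FALSE, d))),
               "empty")
})

test_that("wilcoxon signed-rank handles degenerate, one-sided and tied data", {
  expect_warning(res <- wilcoxon_signed_rank(rep(1, 6), rep(1, 6)), "zero")
  expect_equal(res$p_value, 1)

  # n = 12, all differences the same sign: exact p = 2 / 2^12
  a <- 1:12 + 0.5
  res2 <- wilcoxon_signed_rank(a, rep(0, 12))
  expect_equal(res2$p_value, 2 / 4096, tolerance = 1e-12)
  expect_equal(res2$statistic, 78)

  # ties are handled exactly via mid-rank enumeration
  set.seed(31)
  aa <- c(1, 1, -1, 2, 3, 3)
  res3 <- wilcoxon_signed_rank(aa, rep(0, 6))
  expect_equal(res3$p_value, oracle_signed_rank_p(aa, rep(0, 6)),
               tolerance = 1e-12)
})

test_that("exact p-values match the enumeration oracle and wilcox.test", {
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    a <- round(stats::rnorm(n, 0.3, 1), 3)
    b <- round(stats::rnorm(n), 3)
    d <- a - b
    a <- a[d != 0]; b <- b[d != 0]
    if (length(a) < 5) next
    got <- wilcoxon_signed_rank(a, b)
    expect_equal(got$p_value, oracle_signed_rank_p(a, b), tolerance = 1e-12)
    if (!any(duplicated(abs(a - b)))) {
      ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("large-sample approximation stays close to wilcox.test", {
  set.seed(5)
  a <- stats::rnorm(30, 0.4)
  b <- stats::rnorm(30)
  got <- wilcoxon_signed_rank(a, b)
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 0.02)
  expect_identical(got$method, "normal-approximation")
})

test_that("error histograms conserve counts and reflect symmetry", {
  d <- c(10, 10, 1)
  vals <- array(NA_real_, d)
  mask <- array(FALSE, d); mask[1:50] <- TRUE
  vals[1:25] <- 3.2; vals[26:50] <- -3.2
  dm <- volume_grid(vals)
  h <- error_histogram(dm, bin_width = 1)
  expect_equal(sum(h$count), 50)
  expect_true(0 %in% h$mid)
  expect_equal(h$count[h$mid == 3], h$count[h$mid == -3])

  h0 <- error_histogram(volume_grid(array(0, c(2, 2, 1))))
  expect_equal(sum(h0$count > 0), 1)
  expect_equal(h0$mid[h0$count > 0], 0)
})

test_that("common-space averaging preserves identity cohorts and cancels opposites", {
  e <- fx_canonical()
  body <- body_contour(e$ct)
  d <- dim(e$mr$values)
  err <- array(NA_real_, d)
  err[body] <- 5
  maps <- list(volume_grid(err, e$mr$spacing),
               volume_grid(err, e$mr$spacing),
               volume_grid(err, e$mr$spacing))
  mrs <- list(e$mr, e$mr, e$mr)
  cs <- common_space_mean_map(maps, mrs, body_masks = list(body, body, body))
  inmask <- !is.na(cs$map$values) & body
  expect_gt(sum(inmask), 0.5 * sum(body))
  expect_lt(mean(abs(cs$map$values[inmask] - 5)), 0.5)

  # +e and -e on the same geometry average to ~0
  err2 <- err; err2[body] <- -5
  cs2 <- common_space_mean_map(list(maps[[1]], volume_grid(err2, e$mr$spacing)),
                               mrs[1:2], reference_subject = 1)
  in2 <- !is.na(cs2$map$values)
  expect_lt(mean(abs(cs2$map$values[in2])), 0.5)
})
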