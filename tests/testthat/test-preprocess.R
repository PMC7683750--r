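test_that("body contour matches the generating ellipse and contains soft tissue", {
  e <- fx_canonical()
  mask <- body_contour(e$ct)
  d <- dim(e$ct$values)
  sp <- e$ct$spacing
  kz <- (d[3] + 1) %/% 2
  Z <- (kz - (d[3] + 1) / 2) * sp[3]
  L <- d * sp
  taper <- 1 - 0.08 * (2 * Z / L[3])^2
  analytic <- pi * (0.42 * L[1]) * (0.34 * L[2]) * taper^2
  measured <- sum(mask[, , kz]) * sp[1] * sp[2]
  expect_lt(abs(measured - analytic) / analytic, 0.02)
  lg <- tissue_legend()
  expect_true(all(mask[e$seg$labels == lg[["soft_tissue"]]]))
  expect_error(body_contour(volume_grid(array(-1000, c(4, 4, 4)))), "empty")
})

test_that("air pockets become water inside the body only", {
  e <- make_canonical_pelvis(tiny_grid, seed = 3,
                             gas_pockets = list(list(centre = c(0, -95, 10),
                                                     radius = 14)))
  body <- body_contour(e$ct)
  lg <- tissue_legend()
  gas <- e$seg$labels == lg[["bowel_gas"]]
  out <- replace_air_pockets(e$ct, body)
  expect_true(all(out$values[gas] == 0))
  expect_true(all(out$values[!body] == e$ct$values[!body]))
  # volume without internal air is untouched
  e2 <- fx_canonical()
  body2 <- body_contour(e2$ct)
  expect_identical(replace_air_pockets(e2$ct, body2)$values, e2$ct$values)
})

test_that("contour harmonisation adds water, removes protrusions, idempotent", {
  e <- fx_canonical()
  body <- body_contour(e$ct)
  own <- harmonize_contour(e$ct, body)
  expect_identical(own$values, e$ct$values)

  # dilated reference: rim voxels inside reference but outside body -> water
  grown <- gauss_smooth3(array(as.numeric(body), dim(body)), 1.5) > 0.05
  h <- harmonize_contour(e$ct, grown)
  rim <- grown & !body
  expect_gt(sum(rim), 0)
  expect_true(all(h$values[rim] == 0))

  # shrunken reference: protruding voxels -> air
  shrunk <- gauss_smooth3(array(as.numeric(body), dim(body)), 1.5) > 0.95
  h2 <- harmonize_contour(e$ct, shrunk)
  protr <- body & !shrunk
  expect_gt(sum(protr), 0)
  expect_true(all(h2$values[protr] == -1000))

  # idempotence
  expect_identical(harmonize_contour(h2, shrunk)$values, h2$values)
})

test_that("slice padding repeats the inferior slice and flags validity", {
  e <- fx_canonical()
  same <- extend_fov_slices(e$ct, 0)
  expect_identical(same$volume$values, e$ct$values)
  expect_true(all(same$valid_slices))

  p <- extend_fov_slices(e$ct, 3)
  d <- dim(e$ct$values)
  expect_identical(dim(p$volume$values)[3], d[3] + 3L)
  for (k in 1:3)
    expect_identical(p$volume$values[, , k], e$ct$values[, , 1])
  expect_identical(p$valid_slices, c(rep(FALSE, 3), rep(TRUE, d[3])))
  expect_error(extend_fov_slices(e$ct, d[3]), "slices")
})

test_that("physical resampling honours identity, constants and round trips", {
  e <- fx_canonical()
  same <- resample_to(e$ct, e$ct)
  expect_identical(same$values, e$ct$values)

  const <- volume_grid(array(7, c(8, 8, 8)), spacing = c(2, 2, 2))
  target <- list(dim = c(5, 5, 5), spacing = c(3, 3, 3), origin = c(0, 0, 0))
  out <- resample_to(const, target)
  expect_true(all(abs(out$values - 7) < 1e-12))

  # smooth phantom: noise-free per-label HU means, smoothed; then
  # downsample 2x and back gives a small HU error inside the body
  lg <- tissue_legend()
  p <- phantom_params()
  means <- vapply(names(lg), function(nm) p$hu[[nm]][1], numeric(1))
  flat <- means[match(as.vector(e$seg$labels), lg)]
  smooth_ct <- volume_grid(gauss_smooth3(array(flat, dim(e$seg$labels)), 5),
                           e$ct$spacing, e$ct$origin, "HU")
  half <- list(dim = dim(smooth_ct$values) %/% 2L,
               spacing = smooth_ct$spacing * 2,
               origin = smooth_ct$origin + smooth_ct$spacing / 2)
  down <- resample_to(smooth_ct, half)
  back <- resample_to(down, smooth_ct)
  body <- body_contour(e$ct)
  expect_lt(mean(abs(back$values[body] - smooth_ct$values[body])), 5)

  far <- list(dim = c(4, 4, 4), spacing = c(1, 1, 1),
              origin = c(1e5, 1e5, 1e5))
  expect_error(resample_to(e$ct, far), "overlap")
})

test_that("labels resample with nearest-neighbour interpolation", {
  e <- fx_canonical()
  half <- list(dim = dim(e$seg$labels) %/% 2L, spacing = e$seg$spacing * 2,
               origin = e$seg$origin)
  down <- resample_to(e$seg, half)
  expect_s3_class(down, "label_map")
  expect_true(all(down$labels %in% tissue_legend()))
})
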