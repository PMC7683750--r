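test_that("similarity weights follow the Gaussian patch kernel", {
  s <- fx_tiny_subject()
  # identical candidate: D = 0 -> weight exactly 1 everywhere
  w <- similarity_weights(s$mr, list(s$mr), kernel_sigma2 = 0.01)
  expect_true(all(w[[1]] == 1))

  # constant offsets: known D, so known weight ratio (e for D = sigma^2)
  d <- dim(s$mr$values)
  off1 <- s$mr; off1$values <- off1$values + 0.1
  w2 <- similarity_weights(s$mr, list(s$mr, off1), kernel_sigma2 = 0.01)
  expect_true(all(abs(w2[[2]] / w2[[1]] - exp(-1)) < 1e-10))

  # monotone: larger local mismatch gives strictly smaller weight
  off2 <- s$mr; off2$values <- off2$values + 0.2
  w3 <- similarity_weights(s$mr, list(off1, off2), kernel_sigma2 = 0.01)
  expect_true(all(w3[[2]] < w3[[1]]))
  expect_true(all(w3[[2]] > 0))
})

test_that("weighted voting resolves unanimity, single voters and hand cases", {
  s <- fx_tiny_subject()
  tpl <- fx_templates()
  d <- dim(s$mr$values)
  zero <- array(0, c(d, 3))

  one <- vote_segmentation(s$mr, tpl[1], list(zero))
  expect_identical(one$labels, tpl[[1]]$seg$labels)

  # unanimity: identical templates agree regardless of weights
  same <- vote_segmentation(s$mr, list(tpl[[1]], tpl[[1]]), list(zero, zero),
                            weights = list(array(0.9, d), array(0.1, d)))
  expect_identical(same$labels, tpl[[1]]$seg$labels)

  # hand-worked weighted vote: labels (1,2,2), weights (0.5,0.3,0.3) -> 2
  mk <- function(lab) {
    t1 <- tpl[[1]]
    t1$seg <- label_map(array(lab, d), t1$seg$spacing, t1$seg$origin)
    t1
  }
  v <- vote_segmentation(s$mr, list(mk(1L), mk(2L), mk(2L)),
                         list(zero, zero, zero),
                         weights = list(array(0.5, d), array(0.3, d),
                                        array(0.3, d)))
  expect_true(all(v$labels == 2L))

  # tie: equal weight on labels 1 and 2 -> lowest label id
  v2 <- vote_segmentation(s$mr, list(mk(2L), mk(1L)), list(zero, zero),
                          weights = list(array(0.5, d), array(0.5, d)))
  expect_true(all(v2$labels == 1L))

  expect_error(vote_segmentation(s$mr, list(), list()), "at least one")
})

test_that("uniform-weight voting equals simple majority", {
  s <- fx_tiny_subject()
  tpl <- fx_templates()
  d <- dim(s$mr$values)
  zero <- array(0, c(d, 3))
  w1 <- lapply(1:3, function(i) array(1, d))
  v <- vote_segmentation(s$mr, tpl, list(zero, zero, zero), weights = w1)
  labs <- vapply(tpl, function(t) as.vector(t$seg$labels),
                 integer(prod(d)))
  majority <- apply(labs, 1, function(x) {
    tab <- table(x)
    cand <- as.integer(names(tab)[tab == max(tab)])
    min(cand)
  })
  expect_identical(as.vector(v$labels), majority)
})

test_that("weighted-median fusion matches hand cases and stays bounded", {
  d <- c(2, 2, 1)
  mkv <- function(x) volume_grid(array(x, d))
  mkw <- function(x) array(x, d)

  # uniform weights over (-100, 40, 300): ordinary median
  f <- fuse_weighted_median(list(mkv(-100), mkv(40), mkv(300)),
                            list(mkw(1), mkw(1), mkw(1)))
  expect_true(all(f$values == 40))

  # single candidate returns itself
  f1 <- fuse_weighted_median(list(mkv(77)), list(mkw(0.2)))
  expect_true(all(f1$values == 77))

  # values (0, 100) with weights (1, 3): cumulative reaches half at 100
  f2 <- fuse_weighted_median(list(mkv(0), mkv(100)), list(mkw(1), mkw(3)))
  expect_true(all(f2$values == 100))

  # equal halves: smallest value reaching half the weight wins
  f3 <- fuse_weighted_median(list(mkv(0), mkv(100)), list(mkw(1), mkw(1)))
  expect_true(all(f3$values == 0))

  expect_error(fuse_weighted_median(list(mkv(0), mkv(1)),
                                    list(mkw(0), mkw(0))), "positive")
})

test_that("fusion agrees with the definition oracle on random instances", {
  set.seed(42)
  for (rep in 1:200) {
    k <- sample(2:5, 1)
    vals <- sample(c(-1000, -90, 0, 40, 300, 1100, 40), k, replace = TRUE)
    w <- round(stats::runif(k, 0.01, 1), 3)
    cand <- lapply(vals, function(v) volume_grid(array(v, c(1, 1, 1))))
    wts <- lapply(w, function(x) array(x, c(1, 1, 1)))
    got <- fuse_weighted_median(cand, wts)$values[1, 1, 1]
    expect_identical(got, oracle_weighted_median(vals, w))
    expect_true(got >= min(vals) && got <= max(vals))
  }
})

test_that("constrained warp yields one candidate per template, near-identity when matched", {
  s <- fx_tiny_subject()
  tpl <- fx_templates()[1:2]
  d <- dim(s$mr$values)
  zero <- array(0, c(d, 3))

  # target equal to a template's (unwarped) segmentation: refinement of that
  # template stays close to its initialisation
  cw <- constrained_warp(tpl[1], list(zero), tpl[[1]]$seg)
  expect_length(cw$sct_candidates, 1)
  mag_vox <- sqrt(cw$fields[[1]][, , , 1]^2 + cw$fields[[1]][, , , 2]^2 +
                    cw$fields[[1]][, , , 3]^2) / mean(s$mr$spacing)
  expect_lt(mean(mag_vox), 0.5)

  # candidate count equals template count on a real target
  fields <- lapply(tpl, function(tp) register_volumes(s$mr, tp$mr,
    settings = register_settings(iterations = c(25, 10))))
  seg <- vote_segmentation(s$mr, tpl, fields)
  cw2 <- constrained_warp(tpl, fields, seg)
  expect_length(cw2$sct_candidates, 2)

  # majority of candidates carry bone-like HU at deep cortical voxels
  lg <- tissue_legend()
  cort <- array(as.numeric(seg$labels == lg[["bone_cortical"]]), d)
  deep <- gauss_smooth3(cort, 1) > 0.8
  if (sum(deep) < 10) deep <- seg$labels == lg[["bone_cortical"]]
  frac_bone <- rowMeans(vapply(cw2$sct_candidates,
                               function(c) c$values[deep] > 150,
                               logical(sum(deep))))
  expect_gt(mean(frac_bone), 0.5)
})

test_that("the full synthetic-CT generator is accurate and deterministic", {
  tpl <- fx_templates()
  cfg <- sct_config(register = register_settings(iterations = c(30, 12)),
                    refine = register_settings(iterations = c(15, 6)))
  # self-atlas sanity: subject is one of the templates
  sct <- generate_sct(tpl[[1]]$mr, tpl, cfg)
  body <- body_contour(tpl[[1]]$ct)
  expect_lt(mean(abs(sct$values[body] - tpl[[1]]$ct$values[body])), 30)
  expect_true(all(sct$values >= -1000 & sct$values <= 2000))

  sct2 <- generate_sct(tpl[[1]]$mr, tpl, cfg)
  expect_identical(sct$values, sct2$values)
})
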