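## anti-aliased disc (supersampled fractional coverage at the rim)
aa_disc <- function(n, sp, radius_mm, value = 1, ss = 4) {
  fine <- n * ss
  ij <- cbind(rep.int(seq_len(fine), fine), rep(seq_len(fine), each = fine))
  r <- sqrt((ij[, 1] - (fine + 1) / 2)^2 +
              (ij[, 2] - (fine + 1) / 2)^2) * sp / ss
  m <- matrix(as.numeric(r < radius_mm), fine, fine)
  coarse <- matrix(0, n, n)
  for (a in seq_len(ss)) for (b in seq_len(ss))
    coarse <- coarse + m[seq(a, fine, by = ss), seq(b, fine, by = ss)]
  array(value * coarse / ss^2, c(n, n, 1))
}

test_that("forward projection obeys zero activity, symmetry and the chord law", {
  n <- 64; sp <- 6
  g <- pet_geometry(c(n, n), c(sp, sp), 112)
  zerovol <- volume_grid(array(0, c(n, n, 1)), c(sp, sp, sp))
  s0 <- forward_project(zerovol, zerovol, g)
  expect_true(all(s0$counts == 0))

  # central point source without attenuation: constant maximum across angles
  # (odd grid so the source sits exactly on the rotation centre)
  n1 <- 63
  g1 <- pet_geometry(c(n1, n1), c(sp, sp), 112)
  pt <- array(0, c(n1, n1, 1))
  pt[(n1 + 1) / 2, (n1 + 1) / 2, 1] <- 1
  zero1 <- volume_grid(array(0, c(n1, n1, 1)), c(sp, sp, sp))
  sp_pt <- forward_project(volume_grid(pt, c(sp, sp, sp)), zero1, g1)
  maxima <- apply(sp_pt$counts[, , 1], 2, max)
  expect_lt(diff(range(maxima)) / mean(maxima), 1e-9)

  # uniform disc with uniform mu: central LOR attenuated by exp(-mu * chord)
  act <- volume_grid(aa_disc(n, sp, 100), c(sp, sp, sp))
  mu <- volume_grid(aa_disc(n, sp, 100, value = 0.096), c(sp, sp, sp))
  s_att <- forward_project(act, mu, g)
  s_free <- forward_project(act, zerovol, g)
  mid <- (g$n_rad + 1) / 2
  ratio <- s_att$counts[mid, 1, 1] / s_free$counts[mid, 1, 1]
  expect_lt(abs(ratio - exp(-0.096 * 20)) / exp(-0.096 * 20), 0.01)
  # unattenuated central line integral close to the 200 mm chord
  expect_lt(abs(s_free$counts[mid, 1, 1] - 200) / 200, 0.01)
})

test_that("projector and backprojector are exactly adjoint", {
  g <- pet_geometry(c(64, 64), c(4, 4), 56)
  set.seed(3)
  x <- stats::rnorm(64 * 64)
  y <- stats::rnorm(nrow(g$A))
  lhs <- sum(as.vector(g$A %*% x) * y)
  rhs <- sum(x * as.vector(Matrix::t(g$A) %*% y))
  expect_lt(abs(lhs - rhs) / abs(rhs), 1e-10)
})

test_that("poisson noise is seeded and preserves expectations", {
  n <- 32; sp <- 8
  g <- pet_geometry(c(n, n), c(sp, sp), 28)
  act <- volume_grid(aa_disc(n, sp, 80, value = 50), c(sp, sp, sp))
  mu0 <- volume_grid(array(0, c(n, n, 1)), c(sp, sp, sp))
  sino <- forward_project(act, mu0, g, noise_scale = 2e5)
  expect_equal(sum(sino$counts), 2e5, tolerance = 1e-9)

  n1 <- add_poisson_noise(sino, seed = 9)
  n2 <- add_poisson_noise(sino, seed = 9)
  expect_identical(n1$counts, n2$counts)
  expect_true(all(n1$counts[sino$counts == 0] == 0))
  expect_true(all(n1$counts >= 0))

  # Monte-Carlo mean over 200 seeds within 1% for well-populated bins
  acc <- array(0, dim(sino$counts))
  for (s in 1:200) acc <- acc + add_poisson_noise(sino, seed = s)$counts
  acc <- acc / 200
  big <- sino$counts > 500
  rel <- abs(acc[big] - sino$counts[big]) / sino$counts[big]
  expect_lt(max(rel), 0.01)
  some <- sino$counts > 100
  expect_lt(mean(abs(acc[some] - sino$counts[some]) / sino$counts[some]),
            0.01)
})

test_that("OSEM reconstructs, underestimates without AC, and handles zero data", {
  s <- fx_subject()
  body <- body_contour(s$ct_true)
  mu <- hu_to_mu(s$ct_true)
  g <- pet_geometry(dim(s$mr$values)[1:2], s$mr$spacing[1:2], 112)
  sino <- forward_project(s$activity_true, mu, g)

  rec <- osem_reconstruct(sino, mu, recon_config(n_iterations = 4,
                                                 n_subsets = 28))
  truth <- s$activity_true$values
  expect_true(all(rec$values >= 0))
  expect_lt(mean(abs(rec$values[body] - truth[body])) / mean(truth[body]),
            0.10)

  # no attenuation correction on attenuated data: body mean below truth
  mu0 <- volume_grid(array(0, dim(mu$values)), mu$spacing)
  rec0 <- osem_reconstruct(sino, mu0, recon_config(n_iterations = 2,
                                                   n_subsets = 28))
  expect_lt(mean(rec0$values[body]), mean(truth[body]))

  # all-zero sinogram: zero image with a warning
  sino0 <- sino; sino0$counts[] <- 0
  expect_warning(z <- osem_reconstruct(sino0, mu), "zero")
  expect_true(all(z$values == 0))

  expect_error(osem_reconstruct(sino, mu, recon_config(n_subsets = 13)),
               "divide")
})

test_that("OSEM with one subset equals an independently coded MLEM", {
  n <- 32; sp <- 8
  g <- pet_geometry(c(n, n), c(sp, sp), 24)
  act <- volume_grid(aa_disc(n, sp, 70, value = 10), c(sp, sp, sp))
  mu <- volume_grid(aa_disc(n, sp, 70, value = 0.08), c(sp, sp, sp))
  sino <- forward_project(act, mu, g)
  rec <- osem_reconstruct(sino, mu, recon_config(n_iterations = 5,
                                                 n_subsets = 1))

  # oracle MLEM written directly from the update equation
  A <- g$A
  y <- as.vector(sino$counts[, , 1])
  att <- exp(-0.1 * as.vector(A %*% as.vector(mu$values[, , 1])))
  ij <- cbind(rep.int(seq_len(n), n), rep(seq_len(n), each = n))
  supp <- as.numeric((ij[, 1] - (n + 1) / 2)^2 +
                       (ij[, 2] - (n + 1) / 2)^2 <= (n / 2)^2)
  x <- supp
  sens <- as.vector(Matrix::t(A) %*% att)
  for (it in 1:5) {
    p <- att * as.vector(A %*% x)
    ratio <- ifelse(p > 1e-12, y / p, 0)
    x <- x * ifelse(sens > 1e-12,
                    as.vector(Matrix::t(A) %*% (att * ratio)) / sens, 0)
  }
  expect_equal(as.vector(rec$values[, , 1]), x, tolerance = 1e-10)
})

test_that("count totals are conserved in the MLEM limit", {
  n <- 32; sp <- 8
  g <- pet_geometry(c(n, n), c(sp, sp), 24)
  act <- volume_grid(aa_disc(n, sp, 70, value = 10), c(sp, sp, sp))
  mu <- volume_grid(aa_disc(n, sp, 70, value = 0.08), c(sp, sp, sp))
  sino <- forward_project(act, mu, g)
  rec <- osem_reconstruct(sino, mu, recon_config(n_iterations = 50,
                                                 n_subsets = 1))
  refit <- forward_project(rec, mu, g)
  expect_lt(abs(sum(refit$counts) - sum(sino$counts)) / sum(sino$counts),
            0.005)
})

test_that("SUV conversion is linear and calibration cancels in percent errors", {
  s <- fx_subject()
  conc <- s$injected_dose * 1e6 / (s$body_weight * 1000)
  flat <- volume_grid(array(conc, c(4, 4, 2)))
  suv <- to_suv(flat, s$injected_dose, s$body_weight)
  expect_true(all(abs(suv$values - 1) < 1e-12))
  suv2 <- to_suv(flat, 2 * s$injected_dose, s$body_weight)
  expect_true(all(abs(suv2$values - 0.5) < 1e-12))

  a <- volume_grid(array(stats::runif(32, 1, 2), c(4, 4, 2)))
  b <- volume_grid(array(stats::runif(32, 1, 2), c(4, 4, 2)))
  mask <- array(TRUE, c(4, 4, 2))
  p1 <- percent_diff_map(to_suv(a, 400, 80, calibration = 1),
                         to_suv(b, 400, 80, calibration = 1), mask)
  p2 <- percent_diff_map(to_suv(a, 400, 80, calibration = 7.3),
                         to_suv(b, 400, 80, calibration = 7.3), mask)
  expect_equal(p1$values, p2$values, tolerance = 1e-10)
})
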