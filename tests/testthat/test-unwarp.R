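test_that("apply_field is the identity for a zero field and is linear", {
  st <- test_study(seed = 1)
  expect_equal(apply_field(st$img, zero_field(c(64, 64)), +1, st$params),
               st$img)
  # complex input: real and imaginary parts are unwarped independently
  out <- apply_field(st$img, st$field, +1, st$params)
  expect_equal(Re(out), apply_field(Re(st$img), st$field, +1, st$params))
  expect_equal(Im(out), apply_field(Im(st$img), st$field, +1, st$params))
})

test_that("least-squares restoration reduces to averaging at zero field", {
  st <- test_study(seed = 2)
  a <- Mod(st$img)
  b <- a * 0.5 + 0.1
  out <- lsr_restore(a, b, zero_field(c(64, 64)), st$params)
  expect_equal(out, (a + b) / 2, tolerance = 1e-9)
  # identical inputs return the input
  same <- lsr_restore(a, a, zero_field(c(64, 64)), st$params)
  expect_equal(same, a, tolerance = 1e-9)
})

test_that("restoration matches a hand-built normal-equations solve (N = 8)", {
  params <- acq_params(c(1, 8), total_readout_time = 0.032)
  d <- rep(1, 8)                       # one-voxel integer shift
  f <- field_map(array(d / params$total_readout_time, c(1, 8)))
  set.seed(9)
  o_true <- runif(8)
  # forward model: up samples y - d, down samples y + d (jacobian = 1)
  Aup <- matrix(0, 8, 8); Adn <- matrix(0, 8, 8)
  for (y in 1:8) {
    if (y - 1 >= 1) Aup[y, y - 1] <- 1
    if (y + 1 <= 8) Adn[y, y + 1] <- 1
  }
  iu <- as.vector(Aup %*% o_true); id <- as.vector(Adn %*% o_true)
  got <- lsr_restore(array(iu, c(1, 8)), array(id, c(1, 8)), f, params,
                     jacobian = FALSE)
  # dense normal equations with the same support-based ridge
  G <- t(Aup) %*% Aup + t(Adn) %*% Adn
  dg <- diag(G); dmax <- max(dg)
  eps <- 1e-10 * dmax + ifelse(dg < 1e-3 * dmax, 1e-3 * dmax, 0)
  oracle <- solve(G + diag(eps), t(Aup) %*% iu + t(Adn) %*% id)
  expect_lt(max(abs(as.vector(got) - as.vector(oracle))), 1e-8)
})

test_that("restoration beats single-image unwarping on noiseless pairs", {
  st <- test_study(seed = 1)
  obj <- Mod(st$img) > 0
  up <- distort_image(st$img, st$field, +1, st$params)
  dn <- distort_image(st$img, st$field, -1, st$params)
  rec <- lsr_restore(up, dn, st$field, st$params)
  expect_lt(sqrt(sum(Mod(rec[obj] - st$img[obj])^2) /
                   sum(Mod(st$img[obj])^2)), 0.01)
  au <- apply_field(up, st$field, +1, st$params)
  ad <- apply_field(dn, st$field, -1, st$params)
  mse <- function(x) mean(Mod(x[obj] - st$img[obj])^2)
  expect_lt(mse(rec), mse(au))
  expect_lt(mse(rec), mse(ad))
  expect_lt(mse(rec), mse((au + ad) / 2))
})

test_that("null-field correction reproduces the k-space-limited image", {
  img <- make_phantom(c(64, 64), seed = 2)
  z <- zero_field(c(64, 64))
  # pf = 1: both combinations return the exact phantom reconstruction
  p1 <- acq_params(c(64, 64), partial_fourier = 1)
  k1 <- simulate_cenepi_kspace(img, z, p1)
  for (lsr in c(TRUE, FALSE)) {
    out <- correct_cenepi(k1, z, use_lsr = lsr)
    expect_lt(rel_err(out$magnitude, Mod(img)), 1e-6)
  }
  # pf = 0.75: the partial-Fourier-limited reconstruction
  p2 <- acq_params(c(64, 64), partial_fourier = 0.75)
  k2 <- simulate_cenepi_kspace(img, z, p2)
  pfref <- ifftc(k2$data)
  for (lsr in c(TRUE, FALSE)) {
    out <- correct_cenepi(k2, z, use_lsr = lsr)
    expect_lt(rel_err(out$complex, pfref), 1e-4)
  }
})

test_that("correction improves masks and LSR sharpens beyond averaging", {
  st <- test_study(seed = 2)
  k <- simulate_cenepi_kspace(st$img, st$field, st$params)
  distorted <- Mod(ifftc(k$data))
  cl <- correct_cenepi(k, st$field, use_lsr = TRUE)
  ca <- correct_cenepi(k, st$field, use_lsr = FALSE)
  expect_gt(dice(otsu_mask(cl$magnitude), st$mask),
            dice(otsu_mask(distorted), st$mask))
  ref <- Mod(st$img)
  rmse_in <- function(x) sqrt(mean((x[st$mask] - ref[st$mask])^2))
  expect_lt(rmse_in(cl$magnitude), rmse_in(ca$magnitude))
  # energy bookkeeping: corrected total magnitude close to the phantom's
  expect_lt(abs(sum(cl$magnitude) / sum(ref) - 1), 0.1)
  # deterministic
  expect_identical(cl$complex, correct_cenepi(k, st$field, TRUE)$complex)
})
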