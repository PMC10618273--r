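test_that("phantom generation is seeded, compact, and zero-backgrounded", {
  a <- make_phantom(c(48, 48), seed = 1)
  b <- make_phantom(c(48, 48), seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, make_phantom(c(48, 48), seed = 2)))
  # background corners stay exactly zero (object confined to the centre)
  for (s in 1:4) {
    p <- make_phantom(c(48, 48), seed = s)
    expect_identical(Mod(p)[1:6, 1:6], matrix(0, 6, 6))
    expect_identical(Mod(p)[43:48, 43:48], matrix(0, 6, 6))
    expect_gt(mean(Mod(p) == 0), 0.3)
  }
  expect_error(make_phantom(c(48, 48, 4)), "degenerate")
  expect_error(make_phantom(c(16, 48)), ">= 32")
})

test_that("synthetic field maps respect amplitude and smoothness bounds", {
  z <- make_field_map(c(48, 48), 0, seed = 1)
  expect_true(all(z$values == 0))
  for (s in 1:4) {
    f <- make_field_map(c(48, 48), 50, smoothness = 8, seed = s)
    expect_lte(max(abs(f$values)), 50 + 1e-9)
    g <- cenepi:::pe_gradient(f$values, 2L)
    expect_lte(max(abs(g)), 50 / 8)
  }
  f1 <- make_field_map(c(48, 48), 50, seed = 1)
  f2 <- make_field_map(c(48, 48), 50, seed = 2)
  expect_false(identical(f1$values, f2$values))
})

test_that("distortion model: identity, integer shift, and dense oracle", {
  st <- test_study(seed = 1)
  expect_equal(distort_image(st$img, zero_field(c(64, 64)), +1, st$params),
               st$img + 0i)
  # uniform displacement of exactly +2 voxels along +PE
  u <- field_map(array(2 / st$params$total_readout_time, c(64, 64)))
  sh <- distort_image(Mod(st$img), u, +1, st$params, modulate_jacobian = FALSE)
  expect_equal(sh[, 3:64], Mod(st$img)[, 1:62])
  expect_true(all(sh[, 1:2] == 0))
  # voxel-by-voxel brute-force resampling oracle (independent double loop)
  d <- st$field$values * st$params$total_readout_time
  img <- Mod(st$img)
  oracle <- img * 0
  for (i in 1:64) for (j in 1:64) {
    p <- j - d[i, j]                      # sample position along PE
    j0 <- floor(p); w <- p - j0
    v0 <- if (j0 >= 1 && j0 <= 64) img[i, j0] else 0
    v1 <- if (j0 + 1 >= 1 && j0 + 1 <= 64) img[i, j0 + 1] else 0
    oracle[i, j] <- (1 - w) * v0 + w * v1
  }
  got <- distort_image(img, st$field, +1, st$params, modulate_jacobian = FALSE)
  expect_lt(max(abs(got - oracle)), 1e-10)
})

test_that("jacobian modulation conserves per-PE-line sums for smooth fields", {
  st <- test_study(seed = 2, amplitude_hz = 90)
  img <- Mod(st$img)
  for (pol in c(1, -1)) {
    dst <- distort_image(img, st$field, pol, st$params)
    expect_lt(max(abs(rowSums(dst) - rowSums(img))) / max(rowSums(img)),
              0.005)
  }
})

test_that("opposite distortions invert each other on band-limited images", {
  params <- test_params()
  img <- gaussian_smooth(Mod(make_phantom(c(64, 64), seed = 1)), 1.5)
  tr <- make_field_map(c(64, 64), 60, 16, seed = 101)
  obj <- img > 0.05 * max(img)
  # unwarp round trip
  rt <- apply_field(distort_image(img, tr, +1, params), tr, +1, params)
  expect_lt(sqrt(sum((rt[obj] - img[obj])^2) / sum(img[obj]^2)), 0.02)
  # opposite-polarity distortion with the field resampled to distorted space
  f_res <- field_map(pe_resample(tr$values,
                                 -tr$values * params$total_readout_time,
                                 2L, "linear"))
  rt2 <- distort_image(distort_image(img, tr, +1, params), f_res, -1, params)
  expect_lt(sqrt(sum((rt2[obj] - img[obj])^2) / sum(img[obj]^2)), 0.02)
})

test_that("centric k-space assembly follows the blip-polarity split", {
  st <- test_study(seed = 1)
  # zero field: composite equals the masked transform of the phantom
  k0 <- simulate_cenepi_kspace(st$img, zero_field(c(64, 64)), st$params)
  ref <- cenepi:::zero_unacquired(fftc(st$img), cenepi:::pf_acquired_mask(st$params), 2L)
  expect_lt(rel_err(k0$data, ref), 1e-12)
  # pf = 0.75, N = 64: rows 17..64 acquired (0-based 16..63)
  expect_identical(which(k0$acquired_mask), 17:64)
  expect_equal(sum(k0$acquired_mask), 48L)
  # nonzero field: the zero-filled up half resembles the blip-up image more
  # than the blip-down image
  k <- simulate_cenepi_kspace(st$img, st$field, st$params)
  halves <- split_for_correction(k)
  up_img <- 2 * ifftc(halves$k_up$data)
  d_up <- distort_image(st$img, st$field, +1, st$params)
  d_dn <- distort_image(st$img, st$field, -1, st$params)
  expect_lt(rel_err(Mod(up_img), Mod(d_up)), rel_err(Mod(up_img), Mod(d_dn)))
  # reproducible with noise
  kn1 <- simulate_cenepi_kspace(st$img, st$field, st$params, 0.01, seed = 7)
  kn2 <- simulate_cenepi_kspace(st$img, st$field, st$params, 0.01, seed = 7)
  expect_identical(kn1$data, kn2$data)
  expect_error(simulate_cenepi_kspace(st$img, st$field,
                                      acq_params(c(64, 64),
                                                 trajectory = "linear_up")),
               "centric")
})

test_that("double-echo GRE pair has the closed-form phase difference", {
  st <- test_study(seed = 3, amplitude_hz = 30)
  pr <- simulate_gre_pair(st$img, st$field)
  expect_equal(Mod(pr$echo1), Mod(pr$echo2))
  dphi <- Arg(pr$echo2 * Conj(pr$echo1))
  expect_equal(dphi[st$mask],
               (2 * pi * st$field$values * 2.46e-3)[st$mask],
               tolerance = 1e-10)
  # zero field: no phase difference
  p0 <- simulate_gre_pair(st$img, zero_field(c(64, 64)))
  expect_lt(max(abs(Arg(p0$echo2 * Conj(p0$echo1)))[st$mask]), 1e-12)
  expect_error(simulate_gre_pair(st$img, st$field, 7e-3, 5e-3), "exceed")
})

test_that("perfusion series has the designed label/control structure", {
  img <- make_phantom(c(48, 48), seed = 4)
  gm <- Mod(img) > 0.8
  s0 <- simulate_perfusion_series(img, gm, perfusion_fraction = 0.02,
                                  noise_sd = 0, n_pairs = 5, seed = 1)
  dm <- apply(s0$control - s0$label, 1:3, mean)
  m <- array(Mod(img), dim(dm))
  expect_equal(dm[s0$gm_mask], 0.02 * m[s0$gm_mask], tolerance = 1e-12)
  expect_false(any(s0$gm_mask & s0$bg_mask))
  # default acquisition counts follow the protocol (34 pairs, 15 M0)
  s1 <- simulate_perfusion_series(img, gm, seed = 1)
  expect_equal(dim(s1$control)[4], 34L)
  expect_equal(dim(s1$m0)[4], 15L)
  expect_identical(s1$control,
                   simulate_perfusion_series(img, gm, seed = 1)$control)
  expect_error(simulate_perfusion_series(img, gm & FALSE), "empty")
})
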