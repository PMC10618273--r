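test_that("CBF quantification matches an independent evaluation of the model", {
  p <- cbf_params()
  # the standard constants
  expect_identical(c(p$t1_blood, p$alpha, p$lam, p$pld, p$tau),
                   c(1.65, 0.68, 0.9, 1.5, 1.8))
  dm <- array(0.01, c(4, 4)); m0 <- array(1, c(4, 4))
  got <- cbf_map(dm, m0, p)
  # term-by-term arithmetic oracle
  num <- 6000 * 0.9 * exp(1.5 / 1.65)
  den <- 2 * 0.68 * 1.65 * (1 - exp(-1.8 / 1.65))
  expect_lt(max(abs(got - 0.01 * num / den)) / (0.01 * num / den), 1e-12)
  # zero difference -> zero flow; linear in dM; degree -1 in M0
  expect_true(all(cbf_map(dm * 0, m0, p) == 0))
  expect_equal(cbf_map(3 * dm, m0, p), 3 * got, tolerance = 1e-12)
  expect_equal(cbf_map(dm, 2 * m0, p), got / 2, tolerance = 1e-12)
  # nonpositive M0 flagged invalid
  m0[1, 1] <- 0
  expect_true(is.na(cbf_map(dm, m0, p)[1, 1]))
})

test_that("Dice follows its closed form and symmetry", {
  a <- matrix(FALSE, 4, 4); b <- a
  a[1, 1:3] <- TRUE
  expect_equal(dice(a, a), 1)
  b[4, 1:2] <- TRUE
  expect_equal(dice(a, b), 0)
  a <- matrix(FALSE, 4, 4); b <- a
  a[1:6] <- TRUE; b[4:7] <- TRUE   # |A|=6, |B|=4, overlap {4,5,6} = 3
  expect_equal(dice(a, b), 0.6)
  expect_equal(dice(a, b), dice(b, a))
})

test_that("Hausdorff matches the brute-force oracle on random masks", {
  h_oracle <- function(a, b) {
    pa <- which(cenepi:::mask_boundary(a), arr.ind = TRUE)
    pb <- which(cenepi:::mask_boundary(b), arr.ind = TRUE)
    dab <- 0
    for (i in seq_len(nrow(pa))) {
      best <- Inf
      for (j in seq_len(nrow(pb)))
        best <- min(best, sqrt(sum((pa[i, ] - pb[j, ])^2)))
      dab <- max(dab, best)
    }
    dba <- 0
    for (j in seq_len(nrow(pb))) {
      best <- Inf
      for (i in seq_len(nrow(pa)))
        best <- min(best, sqrt(sum((pa[i, ] - pb[j, ])^2)))
      dba <- max(dba, best)
    }
    max(dab, dba)
  }
  a <- matrix(FALSE, 9, 9); a[3, 3] <- TRUE
  b <- matrix(FALSE, 9, 9); b[3, 6] <- TRUE
  expect_equal(hausdorff(a, a), 0)
  expect_equal(hausdorff(a, b), 3)
  expect_equal(hausdorff(a, b), hausdorff(b, a))
  for (s in 1:4) {
    set.seed(s)
    m1 <- matrix(runif(100) > 0.6, 10, 10)
    m2 <- matrix(runif(100) > 0.6, 10, 10)
    if (!any(m1) || !any(m2)) next
    expect_equal(hausdorff(m1, m2), h_oracle(m1, m2), tolerance = 1e-12)
  }
  # translation leaves the distance between a mask and itself at zero
  m <- matrix(FALSE, 12, 12); m[4:6, 4:6] <- TRUE
  mt <- matrix(FALSE, 12, 12); mt[7:9, 6:8] <- TRUE
  expect_equal(dice(m, m), dice(mt, mt))
  expect_equal(hausdorff(mt, mt), 0)
})

test_that("perfusion SNR scales linearly and matches its expectation", {
  img <- make_phantom(c(48, 48), seed = 4)
  gm <- Mod(img) > 0.8
  s <- simulate_perfusion_series(img, gm, perfusion_fraction = 0.02,
                                 noise_sd = 0.01, n_pairs = 34, seed = 2)
  perf <- cenepi:::perfusion_weighted(s)
  snr <- perfusion_snr(perf, s$gm_mask, s$bg_mask)
  # doubling the gray-matter perfusion signal doubles the SNR
  perf2 <- perf; perf2[s$gm_mask] <- 2 * perf[s$gm_mask]
  expect_equal(perfusion_snr(perf2, s$gm_mask, s$bg_mask), 2 * snr)
  # expectation: mean GM signal 0.02 * mean |img|_gm over background sd
  # sd(control - label averaged over n pairs) = noise_sd * sqrt(2 / n)
  expected <- 0.02 * mean(array(Mod(img), dim(perf))[s$gm_mask]) /
    (0.01 * sqrt(2 / 34))
  expect_lt(abs(snr / expected - 1), 0.1)
  expect_error(perfusion_snr(perf * 0, s$gm_mask, s$bg_mask), "zero-variance")
})

test_that("temporal SNR follows the scalar definition and noise scaling", {
  img <- make_phantom(c(48, 48), seed = 5)
  gm <- Mod(img) > 0.8
  s1 <- simulate_perfusion_series(img, gm, 0.02, 0.01, n_pairs = 60, seed = 3)
  # single-voxel gray matter: tSNR equals that voxel's mean/sd
  one <- s1$gm_mask & FALSE
  one[which(s1$gm_mask)[1]] <- TRUE
  dm <- s1$control - s1$label
  v <- dm[rep(one, dim(dm)[4])]
  expect_equal(perfusion_tsnr(s1, one), mean(v) / sd(v), tolerance = 1e-10)
  # doubling the noise roughly halves tSNR
  s2 <- simulate_perfusion_series(img, gm, 0.02, 0.02, n_pairs = 60, seed = 3)
  ratio <- perfusion_tsnr(s1, s1$gm_mask) / perfusion_tsnr(s2, s2$gm_mask)
  expect_lt(abs(ratio - 2), 0.3)
  # constant series: zero temporal variance is an error
  s0 <- simulate_perfusion_series(img, gm, 0.02, 0, n_pairs = 5, seed = 1)
  expect_error(perfusion_tsnr(s0, s0$gm_mask), "temporal")
})

test_that("field-map correlation is Pearson's r with its invariances", {
  f1 <- make_field_map(c(48, 48), 50, seed = 1)
  f2 <- make_field_map(c(48, 48), 50, seed = 2)
  roi <- Mod(make_phantom(c(48, 48), seed = 1)) > 0
  expect_equal(fieldmap_correlation(f1, f1, roi), 1)
  expect_equal(fieldmap_correlation(f1, field_map(-f1$values), roi), -1)
  # direct covariance-formula oracle
  x <- f1$values[roi]; y <- f2$values[roi]
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(fieldmap_correlation(f1, f2, roi), r_oracle, tolerance = 1e-12)
  # affine rescaling leaves r unchanged
  expect_equal(fieldmap_correlation(field_map(3 * f1$values + 7), f2, roi),
               fieldmap_correlation(f1, f2, roi), tolerance = 1e-12)
  expect_error(fieldmap_correlation(f1, field_map(f2$values * 0), roi),
               "variance")
})

test_that("centre-slice selection picks the middle slab", {
  expect_identical(center_slices(9), 3:7)
  expect_identical(center_slices(40), 18:22)
  expect_identical(center_slices(3), 1:3)
})
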