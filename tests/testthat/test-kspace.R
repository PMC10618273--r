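make_tiny_k <- function(n_pe = 8L, pf = 0.75, seed = 1) {
  params <- acq_params(c(8L, n_pe), partial_fourier = pf)
  set.seed(seed)
  data <- array(complex(real = rnorm(8 * n_pe), imaginary = rnorm(8 * n_pe)),
                c(8L, n_pe))
  kspace(data, params = params)
}

nonzero_rows <- function(k) which(apply(Mod(k$data) > 0, 2, any))

test_that("estimation split shares exactly the centre row", {
  k <- make_tiny_k()
  sp <- split_for_estimation(k)
  # N=8, pf=0.75: centre 0-based 4 -> 1-based 5; up {5..8}, down {3,4,5}
  expect_identical(nonzero_rows(sp$k_up), 5:8)
  expect_identical(nonzero_rows(sp$k_down), 3:5)
  expect_identical(sp$k_up$data[, 5], sp$k_down$data[, 5])
  expect_identical(intersect(which(sp$k_up$acquired_mask),
                             which(sp$k_down$acquired_mask)), 5L)
  # conservation: centre counted twice
  expect_equal(sum(sp$k_up$acquired_mask) + sum(sp$k_down$acquired_mask),
               sum(k$acquired_mask) + 1L)
})

test_that("correction split partitions the acquired samples", {
  k <- make_tiny_k()
  sp <- split_for_correction(k)
  expect_identical(nonzero_rows(sp$k_up), 5:8)
  expect_identical(nonzero_rows(sp$k_down), 3:4)
  expect_equal(sp$k_up$data + sp$k_down$data, k$data)
  # pf = 1 limit: the full lower half goes to blip-down
  k1 <- make_tiny_k(pf = 1)
  sp1 <- split_for_correction(k1)
  expect_identical(nonzero_rows(sp1$k_down), 1:4)
  expect_identical(nonzero_rows(sp1$k_up), 5:8)
})

test_that("splits demand a centric trajectory with an acquired centre", {
  params <- acq_params(c(8, 8), trajectory = "linear_up")
  k <- kspace(array(1 + 0i, c(8, 8)), params = params)
  expect_error(split_for_estimation(k), "centric")
})

test_that("POCS is exact for fully sampled input and data-consistent always", {
  img <- make_phantom(c(48, 48), seed = 5)
  params <- acq_params(c(48, 48), partial_fourier = 1)
  kfull <- kspace(fftc(img), rep(TRUE, 48), params)
  expect_lt(rel_err(pocs_reconstruct(kfull, n_iter = 3), ifftc(kfull$data)),
            1e-12)
  # partial input: transform of the output restores acquired rows exactly
  st <- test_study(seed = 5)
  k <- simulate_cenepi_kspace(st$img, st$field, st$params)
  sp <- split_for_estimation(k)
  for (half in sp) {
    rec <- pocs_reconstruct(half, n_iter = 8)
    kk <- fftc(rec)
    rows <- which(half$acquired_mask)
    expect_lt(max(Mod(kk[, rows] - half$data[, rows])) / max(Mod(half$data)),
              1e-10)
  }
})

test_that("POCS recovers a real image from half-plus-centre sampling", {
  img <- gaussian_smooth(Mod(make_phantom(c(64, 64), seed = 3)), 1.5)
  params <- test_params()
  k <- simulate_cenepi_kspace(img, zero_field(c(64, 64)), params)
  sp <- split_for_estimation(k)
  rec <- pocs_reconstruct(sp$k_up, n_iter = 300, tol = 1e-12,
                          phase_ref = array(0, c(64, 64)))
  expect_lt(rel_err(Mod(rec), img), 1e-3)
})

test_that("POCS beats zero filling on smooth-phase phantoms", {
  img <- make_phantom(c(64, 64), seed = 1)
  params <- test_params()
  k <- simulate_cenepi_kspace(img, zero_field(c(64, 64)), params)
  sp <- split_for_estimation(k)
  pocs_err <- rel_err(Mod(pocs_reconstruct(sp$k_up, n_iter = 100)), Mod(img))
  zf_err <- rel_err(Mod(2 * ifftc(sp$k_up$data)), Mod(img))
  expect_lt(pocs_err, 0.05)
  expect_lt(pocs_err, zf_err)
  # error is non-increasing in the iteration count
  errs <- sapply(c(5, 20, 100), function(n)
    rel_err(Mod(pocs_reconstruct(sp$k_up, n_iter = n)), Mod(img)))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("POCS refuses a centre-row-only k-space", {
  params <- acq_params(c(8, 8), partial_fourier = 0.51)
  mask <- rep(FALSE, 8); mask[5] <- TRUE
  k <- kspace(array(1 + 0i, c(8, 8)), mask, params)
  expect_error(pocs_reconstruct(k), "center row")
})

test_that("k-space containers round-trip through disk", {
  k <- make_tiny_k()
  stem <- file.path(withr::local_tempdir(), "k")
  kspace_write(k, stem)
  k2 <- kspace_read(stem)
  expect_equal(k2$data, k$data)
  expect_identical(k2$acquired_mask, k$acquired_mask)
  expect_equal(k2$params$partial_fourier, k$params$partial_fourier)
  expect_identical(k2$params$trajectory, k$params$trajectory)
})
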