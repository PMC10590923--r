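wassr_stack <- function(shifts, offsets = wassr_offset_schedule()$offsets,
                        amplitude = 0.85, fwhm = 0.6, noise = 0) {
  n <- length(shifts)
  dat <- array(0, dim = c(n, 1, length(offsets)))
  for (k in seq_along(offsets)) {
    dat[, 1, k] <- 1 - lorentzian(offsets[k] - shifts, amplitude, 0, fwhm) +
      rnorm(n, 0, noise)
  }
  wassr_image(dat, offsets)
}

test_that("WASSR minimum localizes the B0 shift", {
  w <- wassr_stack(c(0, 0.2, -0.35))
  b0 <- estimate_b0_map(w, matrix(TRUE, 3, 1))
  expect_true(all(b0$valid))
  expect_equal(b0$shift[1, 1], 0, tolerance = 1e-9)
  expect_equal(b0$shift[2, 1], 0.2, tolerance = 0.005)
  expect_equal(b0$shift[3, 1], -0.35, tolerance = 0.005)
})

test_that("edge minima and flat spectra are flagged invalid, not errors", {
  offs <- wassr_offset_schedule()$offsets
  dat <- array(0, dim = c(2, 1, length(offs)))
  dat[1, 1, ] <- offs          # monotone: minimum at the window edge
  dat[2, 1, ] <- 1             # flat
  b0 <- estimate_b0_map(wassr_image(dat, offs), matrix(TRUE, 2, 1))
  expect_false(any(b0$valid))
  expect_true(all(is.na(b0$shift)))
})

test_that("the simulated shift field is recovered across the brain", {
  cfg <- phantom_config(size = 64, n_per_group = 1, noise_sd = 0, seed = 5)
  sub <- simulate_subject(cfg, "WT", "W", seed = 13)
  b0 <- estimate_b0_map(sub$wassr, sub$zspec$mask)
  expect_true(all(b0$valid[sub$zspec$mask]))
  err <- abs(b0$shift - sub$b0_true)[sub$zspec$mask]
  expect_lt(max(err), 0.01)
})

test_that("zero shift leaves corrected spectra at interpolation round-off", {
  sub <- simulate_subject(noiseless_config(), "WT", "W", seed = 1)
  zero <- list(shift = matrix(0, 64, 64), valid = sub$zspec$mask)
  zc <- apply_b0_correction(sub$zspec, zero)
  expect_equal(zc$data, sub$zspec$data, tolerance = 1e-12)
  expect_true(zc$b0_corrected)
})

test_that("shift-then-correct round trip restores noiseless spectra", {
  cfg <- phantom_config(
    size = 64, n_per_group = 1, noise_sd = 0,
    b0_coef = c(c0 = 0.05, cx = 0.1, cy = -0.08, cxy = 0.02, cx2 = 0.1,
                cy2 = -0.06),
    seed = 5
  )
  shifted <- simulate_subject(cfg, "WT", "W", seed = 13)
  unshifted <- simulate_subject(noiseless_config(), "WT", "W", seed = 13)
  b0 <- estimate_b0_map(shifted$wassr, shifted$zspec$mask)
  zc <- apply_b0_correction(shifted$zspec, b0)
  idx <- which(shifted$zspec$mask)
  npix <- 64 * 64
  errs <- vapply(seq_along(zc$offsets), function(k) {
    max(abs(zc$data[idx + (k - 1) * npix] -
              unshifted$zspec$data[idx + (k - 1) * npix]))
  }, numeric(1))
  expect_lt(max(errs), 1e-3)

  # the corrected spectral minimum sits within one dense-grid step of water
  for (v in idx[c(1, 50, 400)]) {
    spec <- zc$data[v + (seq_along(zc$offsets) - 1) * npix]
    expect_lte(abs(zc$offsets[which.min(spec)]), 0.1)
  }
})

test_that("exactly low-rank Casorati matrices pass through SVD denoising", {
  offs <- seq(-5, 5, by = 0.5)
  base <- zspec_forward(offs, ref_pool_set())
  dat <- array(0, dim = c(6, 5, length(offs)))
  scal <- seq(0.8, 1.2, length.out = 30)
  for (k in seq_along(offs)) dat[, , k] <- matrix(scal * base[k], 6, 5)
  z <- zspec_image(dat, offs, matrix(1, 6, 5))
  out <- svd_denoise(z)
  expect_equal(out$rank, 1L)
  expect_equal(out$zspec$data, dat, tolerance = 1e-9)
  expect_true(out$zspec$denoised)
})

test_that("median criterion retains sigma > 2 x median", {
  # matrix constructed with prescribed singular values {10, .1, .1, .1, .1}
  set.seed(8)
  u <- qr.Q(qr(matrix(rnorm(25), 5)))
  v <- qr.Q(qr(matrix(rnorm(25), 5)))
  m <- u %*% diag(c(10, 0.1, 0.1, 0.1, 0.1)) %*% t(v)
  dat <- array(0, dim = c(5, 1, 5))
  dat[, 1, ] <- m
  out <- svd_denoise(zspec_image(dat, 1:5, matrix(1, 5, 1)))
  expect_equal(out$rank, 1L)  # median 0.1, threshold 0.2: only 10 survives
  best1 <- u[, 1, drop = FALSE] %*% t(v[, 1, drop = FALSE]) * 10
  expect_equal(out$zspec$data[, 1, ], best1, tolerance = 1e-9)
})

test_that("denoising reduces Frobenius error on low-rank signal plus noise", {
  offs <- default_offset_schedule()$offsets
  ps <- ref_pool_set()
  base <- rbind(
    zspec_forward(offs, ps),
    zspec_forward(offs + 0.2, ps),
    zspec_forward(offs, pool_set_from_decomposition(
      c(DS = 52, MT = 6, NOE = 40, amide = 1, amine = 1)))
  )
  set.seed(55)
  mixing <- matrix(runif(120 * 3), 120, 3)
  mixing <- mixing / rowSums(mixing)
  truth <- mixing %*% base  # rank-3 ground truth, 120 voxels
  for (rep in 1:20) {
    set.seed(100 + rep)
    noisy <- truth + matrix(rnorm(length(truth), 0, 0.01), nrow(truth))
    dat <- array(0, dim = c(12, 10, length(offs)))
    dat[] <- noisy  # voxels fill the first array dimension pairs
    z <- zspec_image(dat, offs, matrix(1, 12, 10))
    out <- svd_denoise(z)
    den <- matrix(out$zspec$data, 120, length(offs))
    expect_lt(norm(den - truth, "F"), norm(noisy - truth, "F"))
    expect_lte(out$rank, min(120, length(offs)))
  }
})
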