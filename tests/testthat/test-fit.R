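ds_only_config_pool <- function() {
  tibble::tibble(pool = "DS", amplitude = 0.5, center = 0, fwhm = 3)
}

ds_only_config <- function() {
  tibble::tibble(
    pool = "DS", center = 0, center_tol = 0.3, init_amplitude = 0.5,
    init_fwhm = 2, fwhm_min = 0.5, fwhm_max = 10, amp_min = 0, amp_max = 1
  )
}

test_that("a noiseless single-pool spectrum is recovered to 1e-4", {
  offs <- default_offset_schedule()$offsets
  truth <- c(a = 0.72, c = 0.12, w = 3.4)
  spec <- 1 - lorentzian(offs, truth["a"], truth["c"], truth["w"])
  fit <- fit_zspectrum(spec, offs, ds_only_config())
  expect_true(attr(fit, "converged"))
  expect_equal(fit$amplitude, unname(truth["a"]), tolerance = 1e-4)
  expect_equal(fit$center, unname(truth["c"]), tolerance = 1e-4)
  expect_equal(fit$fwhm, unname(truth["w"]), tolerance = 1e-4)
})

test_that("noiseless five-pool voxels are recovered within 1% of truth", {
  offs <- default_offset_schedule()$offsets
  ps <- ref_pool_set()
  set.seed(17)
  # ten voxels with mild parameter perturbations around the reference set
  for (v in 1:10) {
    pert <- ps
    pert$amplitude <- pert$amplitude * runif(5, 0.95, 1.05)
    pert$center <- pert$center + runif(5, -0.05, 0.05)
    spec <- zspec_forward(offs, pert)
    fit <- fit_zspectrum(spec, offs)
    expect_true(attr(fit, "converged"))
    rel <- abs(fit$amplitude - pert$amplitude) / pert$amplitude
    expect_lt(max(rel), 0.01)

    # independent oracle: L-BFGS-B refinement from a coarse grid of NOE
    # amplitude starts (different optimizer, different search path)
    bounds <- noemri:::.fit_bounds(default_pool_config())
    obj <- function(p) sum((spec - noemri:::.multipool_model(p, offs))^2)
    best <- NULL
    for (a_noe in seq(0.05, 0.3, by = 0.05)) {
      init <- bounds$init
      init[7] <- a_noe
      o <- optim(init, obj, method = "L-BFGS-B", lower = bounds$lower,
                 upper = bounds$upper, control = list(maxit = 500,
                                                      factr = 1e4))
      if (is.null(best) || o$value < best$value) best <- o
    }
    expect_lt(abs(fit$amplitude[3] - best$par[7]), 0.01 * pert$amplitude[3])
  }
})

test_that("voxelwise fit maps are identical for 1 and 2 workers", {
  sub <- simulate_subject(noiseless_config(), "WT", "W", seed = 3)
  roi <- sub$labels$labels == hippocampus_label
  f1 <- fit_multipool(sub$zspec, mask = roi, workers = 1)
  f2 <- fit_multipool(sub$zspec, mask = roi, workers = 2)
  expect_identical(f1$amplitude, f2$amplitude)
  expect_identical(f1$rms, f2$rms)
})

test_that("fitted residuals never exceed the initial-value residual", {
  z <- processed_subject()$zc
  roi <- small_cohort()$subjects$WT1$labels$labels == hippocampus_label
  fit <- fit_multipool(z, mask = roi & z$mask)
  bounds <- noemri:::.fit_bounds(default_pool_config())
  offs <- z$offsets
  idx <- which(roi & z$mask)
  npix <- prod(dim(z$data)[1:2])
  for (v in idx[seq(1, length(idx), by = 25)]) {
    spec <- z$data[v + (seq_along(offs) - 1) * npix] / z$reference[v]
    rms0 <- sqrt(mean((spec - noemri:::.multipool_model(bounds$init, offs))^2))
    rc <- arrayInd(v, dim(z$reference))
    expect_lte(fit$rms[rc], rms0 + 1e-12)
  }
  expect_true(all(fit$amplitude[!is.na(fit$amplitude)] >= 0))
  expect_true(all(fit$fwhm[!is.na(fit$fwhm)] > 0))
})

test_that("pool decomposition percentages sum to 100 wherever defined", {
  expect_equal(
    decompose_at_offset(ds_only_config_pool())$contribution, 100
  )
  two <- tibble::tibble(pool = c("a", "b"), amplitude = c(0.2, 0.2),
                        center = -3.5, fwhm = 3)
  expect_equal(decompose_at_offset(two)$contribution, c(50, 50))
  set.seed(23)
  for (i in 1:20) {
    ps <- pool_set(runif(5, 0.01, 0.15), c(0, -2.5, -3.5, 3.5, 2),
                   runif(5, 1, 20))
    expect_equal(sum(decompose_at_offset(ps, runif(1, -5, 5))$contribution),
                 100, tolerance = 1e-9)
  }
  zero <- tibble::tibble(pool = "x", amplitude = 0, center = 0, fwhm = 2)
  expect_warning(d <- decompose_at_offset(zero), "zero")
  expect_true(is.nan(d$contribution))
})


test_that("fit tables carry one row per voxel and pool", {
  sub <- simulate_subject(noiseless_config(), "WT", "W", seed = 3)
  roi <- sub$labels$labels == 7L  # cerebral peduncle: small ROI
  fit <- fit_multipool(sub$zspec, mask = roi)
  tab <- fit_table(fit)
  expect_equal(nrow(tab), sum(roi) * 5)
  expect_setequal(unique(tab$pool), c("DS", "MT", "NOE", "amide", "amine"))
  expect_true(all(tab$converged))
})
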