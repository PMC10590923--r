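# Shared fixtures, built lazily once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# reference five-pool set: packaged WT hippocampus lineshape
ref_pool_set <- function() {
  pool_set(
    amplitude = c(0.74, 0.06, 0.154, 0.102, 0.08),
    center = c(0, -2.5, -3.5, 3.5, 2.0),
    fwhm = c(4, 25, 3, 2, 2)
  )
}

# small noiseless, field-free configuration for closure tests
noiseless_config <- function(size = 64) {
  phantom_config(
    size = size, n_per_group = 1, noise_sd = 0,
    b0_coef = c(c0 = 0, cx = 0, cy = 0, cxy = 0, cx2 = 0, cy2 = 0),
    seed = 11
  )
}

# small noisy cohort used by several files (2 per group, 64 px)
small_cohort <- function() {
  fixture("small_cohort", function() {
    simulate_cohort(phantom_config(size = 64, n_per_group = 2, seed = 7))
  })
}

# one processed small subject: b0 map + corrected spectra
processed_subject <- function() {
  fixture("processed_subject", function() {
    sub <- small_cohort()$subjects[["WT1"]]
    b0 <- estimate_b0_map(sub$wassr, sub$zspec$mask)
    list(sub = sub, b0 = b0, zc = apply_b0_correction(sub$zspec, b0))
  })
}

hippocampus_label <- 3L

# two-group single-ROI cohort table used across test files
make_table <- function(wt, ad, roi = "hippocampus", metric = "noe_mtr") {
  dplyr::bind_rows(
    tibble::tibble(subject = paste0("WT", seq_along(wt)), group = "WT",
                   roi = roi, metric = metric, value = wt, n_pixels = 100L),
    tibble::tibble(subject = paste0("AD", seq_along(ad)), group = "AD",
                   roi = roi, metric = metric, value = ad, n_pixels = 100L)
  )
}

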