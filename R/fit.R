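#' Default five-pool fitting configuration
#'
#' Initial values and box bounds for the voxelwise five-pool Lorentzian fit.
#' Centres are constrained to small windows around the expected chemical
#' shifts (DS at water, MT broad and upfield-shifted, relayed NOE at
#' -3.5 ppm, amide at +3.5 ppm, amine at +2.0 ppm); amplitudes lie in
#' `[0, 1]`; widths are bounded away from zero, with the MT pool forced to be
#' broad. The amine centre is a configuration choice (some protocols place it
#' at +2.75 ppm): edit the returned tibble to change it.
#'
#' @return Tibble with one row per pool: `pool`, `center`, `center_tol`,
#'   `init_amplitude`, `init_fwhm`, `fwhm_min`, `fwhm_max`, `amp_min`,
#'   `amp_max`.
#' @export
default_pool_config <- function() {
  tibble(
    pool = POOL_NAMES,
    center = c(0, -2.5, -3.5, 3.5, 2.0),
    center_tol = c(0.3, 2.0, 0.5, 0.5, 0.5),
    init_amplitude = c(0.8, 0.1, 0.1, 0.05, 0.05),
    init_fwhm = c(2, 25, 3, 2, 2),
    fwhm_min = c(0.5, 10, 0.5, 0.5, 0.5),
    fwhm_max = c(10, 100, 10, 10, 10),
    amp_min = 0, amp_max = 1
  )
}

# internal: parameter vector layout is (a, c, w) per pool, pools in config order
.fit_bounds <- function(cfg) {
  list(
    init = as.vector(rbind(cfg$init_amplitude, cfg$center, cfg$init_fwhm)),
    lower = as.vector(rbind(cfg$amp_min, cfg$center - cfg$center_tol, cfg$fwhm_min)),
    upper = as.vector(rbind(cfg$amp_max, cfg$center + cfg$center_tol, cfg$fwhm_max))
  )
}

.multipool_model <- function(p, w) {
  z <- rep(1, length(w))
  np <- length(p) %/% 3
  for (i in seq_len(np) - 1) {
    z <- z - lorentzian(w, p[3 * i + 1], p[3 * i + 2], p[3 * i + 3])
  }
  z
}

.multipool_resid <- function(p, w, y) y - .multipool_model(p, w)

.multipool_jac <- function(p, w, y) {
  np <- length(p) %/% 3
  J <- matrix(0, length(w), length(p))
  for (i in seq_len(np) - 1) {
    a <- p[3 * i + 1]; c <- p[3 * i + 2]; s <- p[3 * i + 3]
    d <- w - c
    den <- s^2 + 4 * d^2
    J[, 3 * i + 1] <- s^2 / den
    J[, 3 * i + 2] <- 8 * a * s^2 * d / den^2
    J[, 3 * i + 3] <- 8 * a * s * d^2 / den^2
  }
  J
}

# internal: bounded Levenberg-Marquardt fit of one spectrum.
# Returns par, converged, iterations, rms.
.fit_one <- function(y, offs, bounds, maxiter, ftol) {
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = bounds$init, lower = bounds$lower, upper = bounds$upper,
      fn = .multipool_resid, jac = .multipool_jac,
      control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = ftol,
                                           ptol = ftol),
      w = offs, y = y
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(par = bounds$init, converged = FALSE, iter = 0L,
                rms = sqrt(mean(.multipool_resid(bounds$init, offs, y)^2))))
  }
  converged <- fit$info %in% 1:3
  par <- if (converged) fit$par else bounds$init
  list(par = par, converged = converged, iter = as.integer(fit$niter),
       rms = sqrt(mean(.multipool_resid(par, offs, y)^2)))
}

#' Fit one Z-spectrum with the five-pool model
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt with box bounds) of
#' `S/S0 = 1 - sum_n L_n(offset)` to a single normalized spectrum.
#'
#' @param spectrum Numeric vector of normalized signals.
#' @param offsets Offsets (ppm), same length.
#' @param pool_config See [default_pool_config()].
#' @param maxiter,ftol Optimizer controls.
#' @return Tibble with one row per pool (`pool`, `amplitude`, `center`,
#'   `fwhm`) plus attributes `converged`, `iterations`, `rms`.
#' @export
fit_zspectrum <- function(spectrum, offsets, pool_config = default_pool_config(),
                          maxiter = 200, ftol = 1e-8) {
  stopifnot(length(spectrum) == length(offsets))
  bounds <- .fit_bounds(pool_config)
  ok <- is.finite(spectrum)
  r <- .fit_one(spectrum[ok], offsets[ok], bounds, maxiter, ftol)
  out <- tibble(
    pool = pool_config$pool,
    amplitude = r$par[seq(1, length(r$par), by = 3)],
    center = r$par[seq(2, length(r$par), by = 3)],
    fwhm = r$par[seq(3, length(r$par), by = 3)]
  )
  attr(out, "converged") <- r$converged
  attr(out, "iterations") <- r$iter
  attr(out, "rms") <- r$rms
  out
}

#' Voxelwise five-pool Lorentzian fitting
#'
#' Fits the five-pool model independently to every masked voxel of a
#' (normalized) Z-spectrum image by bounded Levenberg-Marquardt least
#' squares, all voxels starting from the same initial values, so the result
#' does not depend on voxel order or on the number of workers. Spectra are
#' divided by the reference image first unless already normalized.
#' Voxels that fail to converge are flagged and carry the initial values.
#'
#' @param zspec A [zspec_image()] (typically denoised and B0-corrected).
#' @param pool_config See [default_pool_config()].
#' @param mask Logical matrix of voxels to fit (defaults to the image mask).
#' @param workers Number of parallel workers (forked; 1 = serial).
#' @param maxiter,ftol Optimizer controls.
#' @return A `fit_maps` object: arrays `amplitude`, `center`, `fwhm`
#'   (`nrow x ncol x 5`, pool order as in the config), matrices `rms`,
#'   `converged`, `iterations`, plus `pools` (pool names) and the config.
#' @export
fit_multipool <- function(zspec, pool_config = default_pool_config(),
                          mask = zspec$mask, workers = 1,
                          maxiter = 200, ftol = 1e-8) {
  bounds <- .fit_bounds(pool_config)
  bad_init <- bounds$init < bounds$lower | bounds$init > bounds$upper
  if (any(bad_init)) stop("initial values outside bounds")
  norm <- if (all(zspec$reference == 1)) zspec else normalize_zspec(zspec)
  mask <- mask & norm$mask
  cas <- casorati_matrix(zspec_image(norm$data, norm$offsets, norm$reference,
                                     mask, norm$b0_corrected, norm$denoised))
  offs <- norm$offsets
  rows <- seq_len(nrow(cas$matrix))
  fit_fun <- function(i) .fit_one(cas$matrix[i, ], offs, bounds, maxiter, ftol)
  fits <- if (workers > 1) {
    parallel::mclapply(rows, fit_fun, mc.cores = workers, mc.preschedule = TRUE)
  } else {
    lapply(rows, fit_fun)
  }
  n1 <- dim(zspec$data)[1]; n2 <- dim(zspec$data)[2]
  np <- nrow(pool_config)
  amp <- ctr <- wid <- array(NA_real_, dim = c(n1, n2, np),
                             dimnames = list(NULL, NULL, pool_config$pool))
  rms <- matrix(NA_real_, n1, n2)
  conv <- matrix(NA, n1, n2)
  iter <- matrix(NA_integer_, n1, n2)
  pars <- do.call(rbind, lapply(fits, `[[`, "par"))
  for (p in seq_len(np)) {
    amp[cbind(arrayInd(cas$idx, c(n1, n2)), p)] <- pars[, 3 * (p - 1) + 1]
    ctr[cbind(arrayInd(cas$idx, c(n1, n2)), p)] <- pars[, 3 * (p - 1) + 2]
    wid[cbind(arrayInd(cas$idx, c(n1, n2)), p)] <- pars[, 3 * (p - 1) + 3]
  }
  rms[cas$idx] <- vapply(fits, `[[`, numeric(1), "rms")
  conv[cas$idx] <- vapply(fits, `[[`, logical(1), "converged")
  iter[cas$idx] <- vapply(fits, `[[`, integer(1), "iter")
  structure(
    list(amplitude = amp, center = ctr, fwhm = wid, rms = rms,
         converged = conv, iterations = iter, pools = pool_config$pool,
         pool_config = pool_config, mask = mask),
    class = "fit_maps"
  )
}

#' @export
print.fit_maps <- function(x, ...) {
  cat(sprintf("<fit_maps> %dx%d, pools: %s; %d voxels fitted (%.1f%% converged)\n",
              nrow(x$rms), ncol(x$rms), paste(x$pools, collapse = ", "),
              sum(!is.na(x$rms)), 100 * mean(x$converged, na.rm = TRUE)))
  invisible(x)
}

#' Extract a pool amplitude map in percent
#'
#' @param fit A [fit_multipool()] result.
#' @param pool Pool name.
#' @return A [contrast_map()] of `100 * amplitude`.
#' @export
pool_amplitude_map <- function(fit, pool) {
  if (!pool %in% fit$pools) stop("unknown pool: ", pool)
  contrast_map(100 * fit$amplitude[, , pool], paste0(pool, "_amplitude"))
}

#' Tidy table of fitted pool parameters
#'
#' @param fit A [fit_multipool()] result.
#' @return Tibble with `row`, `col`, `pool`, `amplitude`, `center`, `fwhm`,
#'   `rms`, `converged`.
#' @export
fit_table <- function(fit) {
  idx <- which(!is.na(fit$rms))
  rc <- arrayInd(idx, dim(fit$rms))
  purrr::map_dfr(seq_along(fit$pools), function(p) {
    tibble(
      row = rc[, 1], col = rc[, 2], pool = fit$pools[p],
      amplitude = fit$amplitude[cbind(rc, p)],
      center = fit$center[cbind(rc, p)],
      fwhm = fit$fwhm[cbind(rc, p)],
      rms = fit$rms[idx], converged = fit$converged[idx]
    )
  })
}

#' Percentage pool contributions at an offset
#'
#' Decomposes the total fitted attenuation at `offset` into per-pool
#' percentage contributions: `100 * L_n(offset) / sum_m L_m(offset)`.
#' Contributions sum to 100 wherever the total attenuation is non-zero; a
#' zero total is undefined and returns `NaN` with a warning.
#'
#' @param pool_params Tibble with `pool`, `amplitude`, `center`, `fwhm`
#'   (a [pool_set()] or one voxel of [fit_table()]).
#' @param offset Evaluation offset (ppm), default -3.5.
#' @return Tibble with `pool`, `attenuation`, `contribution` (percent).
#' @export
decompose_at_offset <- function(pool_params, offset = -3.5) {
  att <- lorentzian(offset, pool_params$amplitude, pool_params$center,
                    pool_params$fwhm)
  total <- sum(att)
  if (total <= 0) {
    warning("total attenuation at ", offset, " ppm is zero; undefined")
    contribution <- rep(NaN, length(att))
  } else {
    contribution <- 100 * att / total
  }
  tibble(pool = pool_params$pool, attenuation = att, contribution = contribution)
}
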