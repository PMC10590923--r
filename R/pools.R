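POOL_NAMES <- c("DS", "MT", "NOE", "amide", "amine")

#' Lorentzian lineshape in amplitude/FWHM form
#'
#' Evaluates the saturation attenuation contributed by one pool at the given
#' offsets:
#' \deqn{L(\omega) = a \, \sigma^2 / (\sigma^2 + 4(\omega - \omega_0)^2)}
#' where `a` is the peak amplitude (fraction of the reference signal),
#' `omega_0` the pool centre (ppm) and `sigma` the full width at half maximum
#' (ppm), so that `L(omega_0) = a` and `L(omega_0 +/- sigma/2) = a/2`.
#'
#' @param offset Numeric vector of offsets (ppm).
#' @param amplitude Peak amplitude in `[0, 1]`.
#' @param center Pool centre (ppm).
#' @param fwhm Full width at half maximum (ppm), > 0.
#' @return Numeric vector of attenuations.
#' @export
lorentzian <- function(offset, amplitude, center, fwhm) {
  if (any(fwhm <= 0)) stop("`fwhm` must be > 0")
  d <- offset - center
  amplitude * fwhm^2 / (fwhm^2 + 4 * d^2)
}

#' Construct a five-pool parameter set
#'
#' A pool set holds the Lorentzian parameters of the five saturation pools
#' used to model the Z-spectrum: direct water saturation (DS), semi-solid
#' magnetization transfer (MT), relayed NOE, amide and amine. It is stored as
#' a tibble with one row per pool so it pipes into the usual verbs.
#'
#' @param amplitude,center,fwhm Numeric vectors of length 5 in the order
#'   DS, MT, NOE, amide, amine.
#' @return A tibble with columns `pool`, `amplitude`, `center`, `fwhm` and
#'   class `pool_set`.
#' @examples
#' ps <- pool_set(
#'   amplitude = c(0.74, 0.06, 0.154, 0.102, 0.08),
#'   center    = c(0, -2.5, -3.5, 3.5, 2.0),
#'   fwhm      = c(4, 25, 3, 2, 2)
#' )
#' zspec_forward(-3.5, ps)
#' @export
pool_set <- function(amplitude, center, fwhm) {
  stopifnot(length(amplitude) == 5, length(center) == 5, length(fwhm) == 5)
  if (any(amplitude < 0 | amplitude > 1)) stop("amplitudes must lie in [0, 1]")
  if (any(fwhm <= 0)) stop("`fwhm` must be > 0")
  out <- tibble(
    pool = POOL_NAMES,
    amplitude = as.numeric(amplitude),
    center = as.numeric(center),
    fwhm = as.numeric(fwhm)
  )
  class(out) <- c("pool_set", class(out))
  out
}

#' Forward Z-spectrum model
#'
#' Evaluates the normalized signal `S/S0 = 1 - sum_n L_n(offset)` for a pool
#' set, i.e. the Z-spectrum as a sum of Lorentzian attenuations subtracted
#' from the unsaturated level.
#'
#' @param offset_ppm Numeric vector of saturation offsets (ppm).
#' @param pools A [pool_set()] (or any data frame with `amplitude`, `center`,
#'   `fwhm` columns).
#' @return Numeric vector of normalized signals in `[0, 1]`.
#' @export
zspec_forward <- function(offset_ppm, pools) {
  att <- rep(0, length(offset_ppm))
  for (i in seq_len(nrow(pools))) {
    att <- att + lorentzian(offset_ppm, pools$amplitude[i], pools$center[i], pools$fwhm[i])
  }
  s <- 1 - att
  if (any(s < -1e-12)) {
    stop("pool amplitudes produce a negative signal; configuration rejected")
  }
  pmin(pmax(s, 0), 1)
}

#' NOE magnetization transfer ratio of a noiseless pool set
#'
#' `100 * (Z(-300) - Z(-3.5)) / Z(-300)` evaluated on the forward model; the
#' quantity the phantom calibration drives to a target.
#'
#' @param pools A [pool_set()].
#' @param noe_offset Offset of the NOE evaluation point (ppm), default -3.5.
#' @param ref_offset Reference offset (ppm), default -300.
#' @return NOE_MTR in percent.
#' @export
noe_mtr_forward <- function(pools, noe_offset = -3.5, ref_offset = -300) {
  zref <- zspec_forward(ref_offset, pools)
  znoe <- zspec_forward(noe_offset, pools)
  100 * (zref - znoe) / zref
}

#' Calibrate the direct-saturation amplitude to a target NOE_MTR
#'
#' Scales the DS pool amplitude, with all other pools held fixed, until the
#' noiseless forward model satisfies
#' `100 * (Z(-300) - Z(-3.5)) / Z(-300) == target_mtr_percent`. This anchors a
#' phantom region's ground truth to a prescribed NOE_MTR while its NOE, amide,
#' amine and MT amplitudes stay at their prescribed values.
#'
#' @param pools A [pool_set()].
#' @param target_mtr_percent Target NOE_MTR in percent, in (0, 100).
#' @param noe_offset,ref_offset Evaluation offsets (ppm).
#' @param tol Absolute tolerance on the achieved NOE_MTR (percent).
#' @return The calibrated [pool_set()].
#' @export
calibrate_noe_mtr <- function(pools, target_mtr_percent,
                              noe_offset = -3.5, ref_offset = -300,
                              tol = 1e-6) {
  if (target_mtr_percent < 0 || target_mtr_percent >= 100) {
    stop("`target_mtr_percent` must lie in [0, 100)")
  }
  ids <- which(pools$pool == "DS")
  f <- function(a) {
    p <- pools
    p$amplitude[ids] <- a
    noe_mtr_forward(p, noe_offset, ref_offset) - target_mtr_percent
  }
  lo <- f(0)
  if (lo > tol) {
    stop(sprintf(
      "target NOE_MTR %.3f%% unreachable: non-DS pools alone give %.3f%%",
      target_mtr_percent, lo + target_mtr_percent
    ))
  }
  hi <- f(1)
  if (hi < -tol) {
    stop(sprintf(
      "target NOE_MTR %.3f%% unreachable with DS amplitude <= 1 (max %.3f%%)",
      target_mtr_percent, hi + target_mtr_percent
    ))
  }
  root <- uniroot(f, c(0, 1), tol = 1e-14)
  out <- pools
  out$amplitude[ids] <- root$root
  achieved <- noe_mtr_forward(out, noe_offset, ref_offset)
  if (abs(achieved - target_mtr_percent) > tol) {
    stop("calibration did not converge to the requested tolerance")
  }
  out
}

#' Pool set reproducing a prescribed attenuation decomposition
#'
#' Builds a five-pool set whose *noiseless* percentage contributions to the
#' total attenuation at `offset` equal `contributions`, with the total
#' attenuation at that offset fixed at `total_attenuation`. Each amplitude is
#' obtained by root-bracketing the scalar equation
#' `L_n(offset) = contribution_n/100 * total_attenuation` in the amplitude.
#' Used as the whole-brain fixture for decomposition analyses (e.g. a
#' 52/6/40/1/1 split between DS, MT, NOE, amide and amine at -3.5 ppm).
#'
#' @param contributions Named numeric vector over `DS, MT, NOE, amide, amine`
#'   summing to 100 (percent).
#' @param offset Offset at which the decomposition is prescribed (ppm).
#' @param total_attenuation Total attenuation `1 - S/S0` at `offset`.
#' @param center,fwhm Length-5 shape parameters (defaults: the packaged
#'   whole-brain lineshape).
#' @return A [pool_set()].
#' @export
pool_set_from_decomposition <- function(contributions,
                                        offset = -3.5,
                                        total_attenuation = 0.40,
                                        center = c(0, -2.5, -3.5, 3.5, 2.0),
                                        fwhm = c(4, 25, 3, 2, 2)) {
  contributions <- contributions[POOL_NAMES]
  if (anyNA(contributions)) stop("`contributions` must name all five pools")
  if (abs(sum(contributions) - 100) > 1e-8) stop("contributions must sum to 100")
  amp <- vapply(seq_along(POOL_NAMES), function(i) {
    target <- contributions[[i]] / 100 * total_attenuation
    g <- function(a) lorentzian(offset, a, center[i], fwhm[i]) - target
    if (g(1) < 0) stop(sprintf("pool %s cannot reach its target attenuation", POOL_NAMES[i]))
    uniroot(g, c(0, 1), tol = 1e-14)$root
  }, numeric(1))
  pool_set(amplitude = amp, center = center, fwhm = fwhm)
}
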