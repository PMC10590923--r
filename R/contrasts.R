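#' Contrast map container
#'
#' @param values Numeric matrix in percent (`NA` outside the mask).
#' @param name Contrast name, e.g. `"noe_mtr"`.
#' @param b0_corrected,denoised,smoothing_sigma Provenance.
#' @return A `contrast_map` object.
#' @export
contrast_map <- function(values, name, b0_corrected = FALSE, denoised = FALSE,
                         smoothing_sigma = 0) {
  finite <- values[is.finite(values)]
  if (length(finite) && (max(finite) > 100 + 1e-9 || min(finite) < -100 - 1e-9)) {
    stop("contrast values must lie in [-100, 100] percent")
  }
  structure(
    list(values = values, name = name, b0_corrected = isTRUE(b0_corrected),
         denoised = isTRUE(denoised), smoothing_sigma = smoothing_sigma),
    class = "contrast_map"
  )
}

#' @export
print.contrast_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<contrast_map> %s: %dx%d, range [%.2f, %.2f]%%%s\n",
              x$name, nrow(x$values), ncol(x$values),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              if (x$b0_corrected) ", B0-corrected" else ""))
  invisible(x)
}

#' NOE magnetization transfer ratio map
#'
#' Computes, per voxel,
#' `NOE_MTR(%) = 100 * (S_ref - S(-3.5 ppm)) / S_ref`
#' where `S(-3.5)` is taken from the (optionally B0-corrected) saturated
#' stack and `S_ref` is the unsaturated reference image (the far
#' off-resonance acquisition). Voxels with non-positive reference, or outside
#' the mask, are `NA`.
#'
#' @param zspec A [zspec_image()]; its schedule must contain `noe_offset`.
#' @param noe_offset NOE evaluation offset (ppm), default -3.5.
#' @return A [contrast_map()] in percent.
#' @export
compute_noe_mtr <- function(zspec, noe_offset = -3.5) {
  k <- which(abs(zspec$offsets - noe_offset) < 1e-9)
  if (length(k) != 1) {
    stop("schedule does not contain the NOE offset ", noe_offset, " ppm")
  }
  s_noe <- zspec$data[, , k]
  ref <- zspec$reference
  vals <- 100 * (ref - s_noe) / ref
  vals[!(ref > 0)] <- NA_real_
  vals[!zspec$mask] <- NA_real_
  vals <- pmin(pmax(vals, -100), 100)
  contrast_map(vals, "noe_mtr", b0_corrected = zspec$b0_corrected,
               denoised = zspec$denoised)
}

#' MTR asymmetry curve over a region
#'
#' For each positive offset in `delta_range`,
#' `MTR_asym(dw) = (S(+dw) - S(-dw)) / S_ref`
#' averaged over the region, reported against the negative (upfield) offset
#' so that NOE-dominated asymmetry plots positive. Offsets lacking an exact
#' mirror are filled by linear interpolation with a warning.
#'
#' @param zspec A [zspec_image()].
#' @param roi_mask Logical matrix selecting the region (defaults to the
#'   image mask).
#' @param delta_range Range of |offset| to evaluate (ppm).
#' @return Tibble with `offset` (negative, ppm) and `asym`
#'   (fraction of the reference signal), class `mtr_asym`.
#' @export
compute_mtr_asym <- function(zspec, roi_mask = zspec$mask,
                             delta_range = c(0, 5)) {
  offs <- zspec$offsets
  pos <- offs[offs > 0 & offs >= delta_range[1] & offs <= delta_range[2]]
  idx <- which(roi_mask & zspec$mask & zspec$reference > 0)
  if (length(idx) == 0) stop("empty region")
  npix <- prod(dim(zspec$data)[1:2])
  mean_at <- function(k) mean(zspec$data[idx + (k - 1) * npix])
  spec <- vapply(seq_along(offs), mean_at, numeric(1))
  ref <- mean(zspec$reference[idx])
  interp_at <- function(w) {
    k <- which(abs(offs - w) < 1e-9)
    if (length(k) == 1) return(spec[k])
    warning("offset ", w, " ppm has no acquired mirror; interpolating")
    approx(offs, spec, xout = w, rule = 2)$y
  }
  asym <- vapply(pos, function(dw) (interp_at(dw) - interp_at(-dw)) / ref,
                 numeric(1))
  out <- tibble(offset = -pos, asym = asym)
  out <- out[order(out$offset), ]
  class(out) <- c("mtr_asym", class(out))
  out
}

#' Flatness of an asymmetry curve over a window
#'
#' Utility for checking the characteristic flat MTR_asym profile between
#' -3.5 and -2 ppm: returns the peak-to-peak spread of the curve inside the
#' window.
#'
#' @param asym A [compute_mtr_asym()] result.
#' @param window Offsets (ppm, negative) bounding the check.
#' @return Peak-to-peak spread (same units as `asym$asym`).
#' @export
asym_flatness <- function(asym, window = c(-3.5, -2)) {
  sel <- asym$offset >= min(window) & asym$offset <= max(window)
  if (!any(sel)) stop("no offsets inside the window")
  diff(range(asym$asym[sel]))
}

#' Gaussian smoothing of a contrast map
#'
#' 2D Gaussian filter with reflecting boundary handling; `NA` voxels are
#' excluded by renormalizing the kernel mass over observed neighbours.
#'
#' @param map A [contrast_map()] (or plain matrix).
#' @param sigma Kernel standard deviation in pixels; 0 returns the input.
#' @return Same type as the input, with `smoothing_sigma` recorded.
#' @export
gaussian_smooth <- function(map, sigma) {
  if (sigma < 0) stop("`sigma` must be >= 0")
  vals <- if (inherits(map, "contrast_map")) map$values else map
  if (sigma > 0) {
    half <- max(1L, ceiling(3 * sigma))
    g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
    g <- g / sum(g)
    pad_reflect <- function(m, h) {
      ri <- c(rev(seq_len(h)), seq_len(nrow(m)), nrow(m) - seq_len(h) + 1)
      ci <- c(rev(seq_len(h)), seq_len(ncol(m)), ncol(m) - seq_len(h) + 1)
      m[ri, ci, drop = FALSE]
    }
    obs <- is.finite(vals)
    v0 <- ifelse(obs, vals, 0)
    conv_sep <- function(m) {
      p <- pad_reflect(m, half)
      # separable convolution: rows then columns
      p <- apply(p, 2, function(col) stats::filter(col, g, sides = 2))
      p <- t(apply(p, 1, function(row) stats::filter(row, g, sides = 2)))
      p[(half + 1):(half + nrow(m)), (half + 1):(half + ncol(m))]
    }
    num <- conv_sep(v0)
    den <- conv_sep(obs * 1)
    sm <- num / den
    sm[!obs] <- NA_real_
    vals <- sm
  }
  if (inherits(map, "contrast_map")) {
    contrast_map(pmin(pmax(vals, -100), 100), map$name, map$b0_corrected,
                 map$denoised, smoothing_sigma = sigma)
  } else {
    vals
  }
}
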