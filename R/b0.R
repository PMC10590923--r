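#' Estimate the per-voxel B0 shift from WASSR data
#'
#' For every masked voxel, a natural cubic spline is passed through the WASSR
#' spectrum and its minimum is located on a dense grid (default 0.001 ppm
#' spacing) inside the acquired window. The minimizing frequency is the B0
#' shift estimate. Voxels whose minimum sits at the window edge (the true
#' minimum may lie outside the sampled range) or whose spectrum is flat are
#' flagged invalid rather than raising an error.
#'
#' @param wassr A [wassr_image()].
#' @param mask Logical matrix of voxels to estimate.
#' @param grid_step Search-grid spacing in ppm.
#' @return A `b0_map`: list with `shift` (matrix, ppm; `NA` where not
#'   estimated) and `valid` (logical matrix).
#' @export
estimate_b0_map <- function(wassr, mask, grid_step = 0.001) {
  offs <- wassr$offsets
  if (length(offs) < 5) stop("need at least 5 WASSR offsets")
  n1 <- dim(wassr$data)[1]; n2 <- dim(wassr$data)[2]
  stopifnot(all(dim(mask) == c(n1, n2)))
  grid <- seq(min(offs), max(offs), by = grid_step)
  shift <- matrix(NA_real_, n1, n2)
  valid <- matrix(FALSE, n1, n2)
  idx <- which(mask)
  npix <- n1 * n2
  koff <- (seq_along(offs) - 1) * npix
  for (v in idx) {
    y <- wassr$data[v + koff]
    if (max(y) - min(y) < 1e-9) next  # flat spectrum: no minimum
    f <- splinefun(offs, y, method = "natural")
    vals <- f(grid)
    j <- which.min(vals)
    if (j == 1L || j == length(grid)) next  # minimum at window edge
    shift[v] <- grid[j]
    valid[v] <- TRUE
  }
  structure(list(shift = shift, valid = valid), class = "b0_map")
}

#' @export
print.b0_map <- function(x, ...) {
  cat(sprintf("<b0_map> %d valid voxels, shift range [%.3f, %.3f] ppm\n",
              sum(x$valid), min(x$shift, na.rm = TRUE), max(x$shift, na.rm = TRUE)))
  invisible(x)
}

# internal: re-grid one spectrum sampled at `offs` onto query points `q`.
# Cubic spline on the densely sampled region (|offset| <= dense_limit),
# linear interpolation beyond it, queries clamped to the acquired range.
.regrid_spectrum <- function(y, offs, q, dense_limit = 6) {
  q <- pmin(pmax(q, min(offs)), max(offs))
  out <- numeric(length(q))
  dense_nodes <- abs(offs) <= dense_limit + 1e-9
  in_dense <- abs(q) <= dense_limit + 1e-9
  if (any(in_dense) && sum(dense_nodes) >= 4) {
    f <- splinefun(offs[dense_nodes], y[dense_nodes], method = "natural")
    out[in_dense] <- f(q[in_dense])
  } else if (any(in_dense)) {
    out[in_dense] <- approx(offs, y, xout = q[in_dense], rule = 2)$y
  }
  if (any(!in_dense)) {
    out[!in_dense] <- approx(offs, y, xout = q[!in_dense], rule = 2)$y
  }
  out
}

#' Correct a Z-spectrum image for B0 inhomogeneity
#'
#' Re-interpolates each voxel's measured spectrum onto the nominal offsets:
#' the corrected value at nominal offset `w` is the measured spectrum
#' evaluated at `w + shift(x, y)`, so that a voxel whose lineshape was
#' displaced by `shift` is restored to water-centred coordinates. Cubic
#' spline interpolation is used on the densely sampled region (default
#' |offset| <= 6 ppm), linear interpolation beyond it, and queries outside
#' the acquired range are clamped to the nearest acquired offset. Voxels the
#' B0 map marks invalid are passed through unchanged and dropped from the
#' returned validity map.
#'
#' @param zspec A [zspec_image()].
#' @param b0map An [estimate_b0_map()] result (or compatible list).
#' @param dense_limit Extent of the spline region in ppm.
#' @param max_shift Shifts larger than this are clamped with a warning.
#' @return A `zspec_image` with `b0_corrected = TRUE` and an extra element
#'   `corrected` (logical matrix of voxels actually corrected).
#' @export
apply_b0_correction <- function(zspec, b0map, dense_limit = 6, max_shift = 0.5) {
  offs <- zspec$offsets
  out <- zspec$data
  idx <- which(zspec$mask & b0map$valid)
  shifts <- b0map$shift[idx]
  if (any(abs(shifts) > max_shift)) {
    warning("B0 shifts larger than ", max_shift, " ppm clamped")
    shifts <- pmin(pmax(shifts, -max_shift), max_shift)
  }
  npix <- prod(dim(out)[1:2])
  koff <- (seq_along(offs) - 1) * npix
  for (j in seq_along(idx)) {
    v <- idx[j]
    y <- zspec$data[v + koff]
    out[v + koff] <- .regrid_spectrum(y, offs, offs + shifts[j], dense_limit)
  }
  res <- zspec_image(out, offs, zspec$reference, zspec$mask,
                     b0_corrected = TRUE, denoised = zspec$denoised)
  corrected <- matrix(FALSE, dim(out)[1], dim(out)[2])
  corrected[idx] <- TRUE
  res$corrected <- corrected
  res
}
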