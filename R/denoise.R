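#' SVD denoising of the Casorati matrix
#'
#' Stacks the masked voxels' Z-spectra into a Casorati matrix (voxels x
#' offsets), takes its singular value decomposition, retains the components
#' whose singular values exceed `multiplier * median(singular values)`
#' (median criterion; default multiplier 2), and reconstructs the spectra
#' from the retained components. Unmasked voxels are untouched.
#'
#' @param zspec A [zspec_image()].
#' @param mask Logical matrix (defaults to the image mask).
#' @param multiplier Threshold multiplier on the median singular value.
#' @return List with `zspec` (denoised image, `denoised = TRUE`) and `rank`
#'   (number of retained components).
#' @export
svd_denoise <- function(zspec, mask = zspec$mask, multiplier = 2) {
  if (sum(mask) < 2) stop("need at least 2 masked voxels")
  if (length(zspec$offsets) < 2) stop("need at least 2 offsets")
  cas <- casorati_matrix(zspec_image(zspec$data, zspec$offsets, zspec$reference,
                                     mask, zspec$b0_corrected, zspec$denoised))
  m <- cas$matrix
  dec <- svd(m)
  d <- dec$d
  # singular values at float-noise level are numerically zero; without this
  # floor an exactly low-rank matrix would report a spurious retained rank
  d[d < max(d) * max(dim(m)) * .Machine$double.eps] <- 0
  keep <- d > multiplier * stats::median(d) & d > 0
  rank <- sum(keep)
  if (rank == 0) {
    out <- zspec
    out$denoised <- TRUE
    return(list(zspec = out, rank = 0L))
  }
  ki <- which(keep)
  recon <- dec$u[, ki, drop = FALSE] %*%
    (dec$d[ki] * t(dec$v[, ki, drop = FALSE]))
  dat <- zspec$data
  npix <- prod(dim(dat)[1:2])
  for (j in seq_along(zspec$offsets)) {
    dat[cas$idx + (j - 1) * npix] <- recon[, j]
  }
  list(
    zspec = zspec_image(dat, zspec$offsets, zspec$reference, zspec$mask,
                        b0_corrected = zspec$b0_corrected, denoised = TRUE),
    rank = as.integer(rank)
  )
}
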