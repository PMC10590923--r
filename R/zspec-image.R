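#' Z-spectrum image stack
#'
#' Container for a single-slice saturation-transfer acquisition: one 2D image
#' per saturation offset plus an unsaturated reference image and an analysis
#' mask. Values are magnitude intensities; dividing by `reference` gives the
#' normalized Z-spectrum `S/S0`.
#'
#' @param data Numeric array `nrow x ncol x K` with `K == length(offsets)`.
#' @param offsets Numeric vector of saturation offsets (ppm), strictly
#'   increasing.
#' @param reference 2D numeric matrix, the unsaturated (far off-resonance)
#'   image.
#' @param mask Logical matrix of voxels to analyse; defaults to all voxels.
#' @param b0_corrected,denoised Provenance flags.
#' @return A `zspec_image` object.
#' @export
zspec_image <- function(data, offsets, reference, mask = NULL,
                        b0_corrected = FALSE, denoised = FALSE) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(offsets))
  if (any(diff(offsets) <= 0)) stop("`offsets` must be strictly increasing")
  stopifnot(all(dim(reference) == dim(data)[1:2]))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(reference), ncol(reference))
  stopifnot(all(dim(mask) == dim(reference)))
  structure(
    list(
      data = data, offsets = as.numeric(offsets), reference = reference,
      mask = mask, b0_corrected = isTRUE(b0_corrected),
      denoised = isTRUE(denoised)
    ),
    class = "zspec_image"
  )
}

#' @export
print.zspec_image <- function(x, ...) {
  cat(sprintf(
    "<zspec_image> %dx%d slice, %d offsets [%g, %g] ppm; b0_corrected=%s denoised=%s\n",
    dim(x$data)[1], dim(x$data)[2], length(x$offsets),
    min(x$offsets), max(x$offsets), x$b0_corrected, x$denoised
  ))
  invisible(x)
}

#' WASSR image stack
#'
#' Low-power saturation stack restricted to a narrow window about water,
#' used to locate the per-voxel direct-saturation minimum (B0 shift).
#'
#' @param data Numeric array `nrow x ncol x M`.
#' @param offsets Offsets (ppm), all within +/-1 ppm, at least 5 of them.
#' @return A `wassr_image` object.
#' @export
wassr_image <- function(data, offsets) {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(offsets))
  if (length(offsets) < 5) stop("WASSR needs at least 5 offsets")
  if (any(abs(offsets) > 1 + 1e-9)) stop("WASSR offsets must lie within +/-1 ppm")
  structure(list(data = data, offsets = as.numeric(offsets)), class = "wassr_image")
}

#' ROI label image
#'
#' Integer segmentation of the slice. Label 0 is background; each region of
#' interest has a positive integer label and a name.
#'
#' @param labels Integer matrix of labels (0 = background).
#' @param roi_table Tibble with columns `label` (integer) and `roi`
#'   (character); every listed label must occur in `labels`.
#' @return A `label_image` object.
#' @export
label_image <- function(labels, roi_table) {
  storage.mode(labels) <- "integer"
  if (any(labels < 0)) stop("labels must be non-negative")
  present <- unique(as.vector(labels))
  missing <- setdiff(roi_table$label, present)
  if (length(missing) > 0) {
    stop("labels absent from the image: ", paste(missing, collapse = ", "))
  }
  structure(list(labels = labels, roi_table = as_tibble(roi_table)),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("<label_image> %dx%d, %d ROIs\n",
              nrow(x$labels), ncol(x$labels), nrow(x$roi_table)))
  invisible(x)
}

#' Normalize a Z-spectrum image by its reference
#'
#' Divides every offset image by the unsaturated reference, voxelwise.
#' Voxels with non-positive reference are set to `NA` and removed from the
#' mask.
#'
#' @param zspec A [zspec_image()].
#' @return A `zspec_image` whose data are `S/S0` and whose reference is 1.
#' @export
normalize_zspec <- function(zspec) {
  ref <- zspec$reference
  bad <- !(ref > 0)
  ref[bad] <- NA_real_
  d <- zspec$data
  for (k in seq_along(zspec$offsets)) d[, , k] <- d[, , k] / ref
  zspec_image(d, zspec$offsets, reference = matrix(1, nrow(ref), ncol(ref)),
              mask = zspec$mask & !bad,
              b0_corrected = zspec$b0_corrected, denoised = zspec$denoised)
}

# internal: matrix of masked voxel spectra (voxels x K) and the index map
casorati_matrix <- function(zspec) {
  idx <- which(zspec$mask)
  k <- length(zspec$offsets)
  m <- matrix(NA_real_, length(idx), k)
  n <- prod(dim(zspec$data)[1:2])
  for (j in seq_len(k)) m[, j] <- zspec$data[idx + (j - 1) * n]
  list(matrix = m, idx = idx)
}
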