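#' Write a simulated subject to disk
#'
#' NIfTI stacks for the saturated, WASSR and reference images, an integer
#' NIfTI for the labels, two-column CSV offset tables (index, ppm) for both
#' schedules, and the ground-truth table as CSV.
#'
#' @param subject A [simulate_subject()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(subject$zspec$data, file.path(dir, "zspec.nii.gz"))
  RNifti::writeNifti(subject$wassr$data, file.path(dir, "wassr.nii.gz"))
  RNifti::writeNifti(subject$zspec$reference, file.path(dir, "reference.nii.gz"))
  RNifti::writeNifti(subject$anatomical, file.path(dir, "anatomical.nii.gz"))
  lab <- subject$labels$labels
  storage.mode(lab) <- "integer"
  RNifti::writeNifti(lab, file.path(dir, "labels.nii.gz"))
  readr::write_csv(
    tibble(index = seq_along(subject$zspec$offsets), ppm = subject$zspec$offsets),
    file.path(dir, "offsets.csv")
  )
  readr::write_csv(
    tibble(index = seq_along(subject$wassr$offsets), ppm = subject$wassr$offsets),
    file.path(dir, "wassr_offsets.csv")
  )
  readr::write_csv(subject$labels$roi_table, file.path(dir, "roi_table.csv"))
  readr::write_csv(subject$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' Read a subject written by [write_subject()]
#'
#' @param dir Directory containing the subject files.
#' @return A list with `zspec`, `wassr`, `anatomical`, `labels`, `truth`.
#' @export
read_subject <- function(dir) {
  offs <- readr::read_csv(file.path(dir, "offsets.csv"), show_col_types = FALSE)$ppm
  woffs <- readr::read_csv(file.path(dir, "wassr_offsets.csv"),
                           show_col_types = FALSE)$ppm
  zdat <- array(RNifti::readNifti(file.path(dir, "zspec.nii.gz")),
                dim = dim(RNifti::readNifti(file.path(dir, "zspec.nii.gz"))))
  ref <- as.matrix(RNifti::readNifti(file.path(dir, "reference.nii.gz"))[, ])
  lab <- RNifti::readNifti(file.path(dir, "labels.nii.gz"))
  lab <- matrix(as.integer(lab), dim(lab)[1], dim(lab)[2])
  roi_table <- readr::read_csv(file.path(dir, "roi_table.csv"),
                               show_col_types = FALSE)
  labels <- label_image(lab, roi_table)
  labels$brain <- lab >= 0 & .read_brain_mask(dir, lab)
  wdat <- RNifti::readNifti(file.path(dir, "wassr.nii.gz"))
  anat <- as.matrix(RNifti::readNifti(file.path(dir, "anatomical.nii.gz"))[, ])
  truth <- readr::read_csv(file.path(dir, "truth.csv"), show_col_types = FALSE)
  list(
    zspec = zspec_image(zdat, offs, ref, mask = labels$brain),
    wassr = wassr_image(array(wdat, dim = dim(wdat)), woffs),
    anatomical = anat, labels = labels, truth = truth
  )
}

# brain mask on disk is optional; fall back to reference support
.read_brain_mask <- function(dir, lab) {
  f <- file.path(dir, "brain_mask.nii.gz")
  if (file.exists(f)) {
    m <- RNifti::readNifti(f)
    matrix(as.numeric(m) > 0.5, dim(m)[1], dim(m)[2])
  } else {
    ref <- as.matrix(RNifti::readNifti(file.path(dir, "reference.nii.gz"))[, ])
    ref > 0.5
  }
}

#' Write a B0 map as NIfTI with a JSON sidecar
#'
#' @param b0map An [estimate_b0_map()] result.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_b0_map <- function(b0map, path) {
  shift <- b0map$shift
  shift[!b0map$valid] <- NA_real_
  RNifti::writeNifti(shift, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(units = "ppm", invalid = "NA"), sidecar,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Write a contrast map as NIfTI (percent units)
#'
#' @param map A [contrast_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contrast_map <- function(map, path) {
  RNifti::writeNifti(map$values, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(units = "percent", contrast = map$name,
         b0_corrected = map$b0_corrected, denoised = map$denoised,
         smoothing_sigma = map$smoothing_sigma),
    sidecar, auto_unbox = TRUE
  )
  invisible(path)
}

#' Write a statistics report as JSON and readable text
#'
#' @param report A [stats_report()] result.
#' @param stem Output path stem; writes `<stem>.json` and `<stem>.txt`.
#' @return The JSON path, invisibly.
#' @export
write_stats_report <- function(report, stem) {
  json <- paste0(stem, ".json")
  jsonlite::write_json(
    list(metric = report$metric, alpha = report$alpha,
         lmm = as.list(report$lmm), icc = report$icc,
         per_roi = report$per_roi),
    json, auto_unbox = TRUE, digits = NA
  )
  txt <- paste0(stem, ".txt")
  con <- file(txt, "w")
  sink(con); print(report); sink()
  close(con)
  invisible(json)
}

#' Serialize a transform chain
#'
#' Affine stages go into a JSON file (3x3 homogeneous matrices); each
#' displacement stage is written as a two-channel NIfTI next to it.
#'
#' @param chain A `transform_chain`.
#' @param stem Output path stem.
#' @return The JSON path, invisibly.
#' @export
write_transform_chain <- function(chain, stem) {
  stages <- list()
  for (i in seq_along(chain)) {
    s <- chain[[i]]
    if (s$type == "affine") {
      stages[[i]] <- list(type = "affine", sigma = s$sigma,
                          matrix = apply(s$matrix, 1, as.numeric, simplify = FALSE))
    } else {
      f <- sprintf("%s_field_%02d.nii.gz", stem, i)
      RNifti::writeNifti(s$field, f)
      stages[[i]] <- list(type = "displacement", sigma = s$sigma,
                          field = basename(f))
    }
  }
  json <- paste0(stem, ".json")
  jsonlite::write_json(stages, json, auto_unbox = TRUE, digits = NA)
  invisible(json)
}
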