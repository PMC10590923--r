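#' Build a saturation-offset schedule
#'
#' Constructs the list of saturation frequency offsets (in ppm, water = 0 ppm)
#' from piecewise-uniform segments, e.g. a dense sampling near water and
#' progressively coarser sampling out to the far wings. Offsets are sorted and
#' de-duplicated; in symmetric mode every non-zero offset is mirrored about
#' water, which is the layout used for asymmetry analysis.
#'
#' @param segments A list of numeric triplets `c(start, end, step)`, each in
#'   ppm with `step > 0`. Segments may share endpoints; shared endpoints are
#'   de-duplicated.
#' @param sides `"symmetric"` (mirror all offsets about 0 ppm) or
#'   `"one-sided"` (use the segments as given).
#' @return An `offset_schedule` object: a list with `offsets` (sorted numeric
#'   vector), `segments`, and `sides`.
#' @examples
#' sched <- build_offset_schedule(list(c(0, 6, 0.1)), sides = "one-sided")
#' length(sched$offsets) # 61
#' @export
build_offset_schedule <- function(segments, sides = c("symmetric", "one-sided")) {
  sides <- match.arg(sides)
  if (!is.list(segments) || length(segments) == 0) {
    stop("`segments` must be a non-empty list of c(start, end, step) triplets")
  }
  offs <- unlist(lapply(segments, function(s) {
    if (length(s) != 3 || !is.numeric(s)) {
      stop("each segment must be a numeric triplet c(start, end, step)")
    }
    start <- s[[1]]; end <- s[[2]]; step <- s[[3]]
    if (step <= 0) stop("segment step must be > 0")
    if (end < start) stop("segment end must be >= start")
    start + step * seq(0L, floor((end - start) / step + 1e-9))
  }))
  # round to sub-ppb before de-duplication so that e.g. seq() float noise at
  # shared endpoints (6.0 from two segments) collapses to one offset
  offs <- sort(unique(round(offs, 6)))
  if (sides == "symmetric") {
    offs <- sort(unique(c(-offs, offs)))
  }
  if (any(diff(offs) <= 0)) stop("offsets must be strictly monotonic")
  structure(
    list(offsets = offs, segments = segments, sides = sides),
    class = "offset_schedule"
  )
}

#' Default Z-spectrum offset schedule
#'
#' The acquisition schedule used throughout: variably spaced offsets with
#' 0.1 ppm steps over 0-6 ppm, 0.5 ppm over 6-10 ppm, 1 ppm over 10-20 ppm and
#' 10 ppm over 20-100 ppm, mirrored about water (173 offsets in total).
#'
#' @return An [build_offset_schedule()] result in symmetric mode.
#' @export
default_offset_schedule <- function() {
  build_offset_schedule(
    list(c(0, 6, 0.1), c(6, 10, 0.5), c(10, 20, 1), c(20, 100, 10)),
    sides = "symmetric"
  )
}

#' Default WASSR offset schedule
#'
#' Low-power water saturation shift referencing offsets: 0 to 1 ppm in
#' 0.1 ppm steps, acquired on both sides of water (21 offsets). The narrow
#' window brackets the direct-saturation minimum used to estimate the
#' per-voxel B0 shift.
#'
#' @return An [build_offset_schedule()] result restricted to |offset| <= 1 ppm.
#' @export
wassr_offset_schedule <- function() {
  build_offset_schedule(list(c(0, 1, 0.1)), sides = "symmetric")
}

#' @export
print.offset_schedule <- function(x, ...) {
  cat(sprintf(
    "<offset_schedule> %d offsets (%s), %.1f to %.1f ppm\n",
    length(x$offsets), x$sides, min(x$offsets), max(x$offsets)
  ))
  invisible(x)
}

#' Number of offsets in a schedule
#' @param schedule An `offset_schedule`.
#' @return Integer count.
#' @export
n_offsets <- function(schedule) length(schedule$offsets)
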