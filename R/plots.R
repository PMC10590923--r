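#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_point
#'   geom_hline scale_fill_viridis_c labs theme_minimal coord_fixed
#'   position_dodge stat_summary facet_wrap
NULL

#' @export
ggplot2::autoplot

# internal: matrix -> long tibble for raster plots
.map_long <- function(m) {
  tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
}

#' Plot a contrast map
#'
#' @param object A [contrast_map()].
#' @param ... Unused.
#' @return A ggplot raster of the map in percent.
#' @method autoplot contrast_map
#' @export
autoplot.contrast_map <- function(object, ...) {
  d <- .map_long(object$values)
  ggplot(d, aes(x = .data$col, y = -.data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "grey20", name = "%") +
    coord_fixed() +
    labs(title = object$name,
         subtitle = sprintf("B0-corrected: %s | denoised: %s | sigma = %g",
                            object$b0_corrected, object$denoised,
                            object$smoothing_sigma),
         x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot an MTR asymmetry curve
#'
#' @param object A [compute_mtr_asym()] result.
#' @param ... Unused.
#' @return A ggplot line plot against the negative (upfield) offsets.
#' @method autoplot mtr_asym
#' @export
autoplot.mtr_asym <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$offset, y = 100 * .data$asym)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_line() +
    geom_point(size = 0.8) +
    labs(x = "offset (ppm)", y = expression(MTR[asym] ~ "(%)")) +
    theme_minimal()
}

#' Plot a B0 map
#'
#' @param object An [estimate_b0_map()] result.
#' @param ... Unused.
#' @return A ggplot raster of the shift in ppm.
#' @method autoplot b0_map
#' @export
autoplot.b0_map <- function(object, ...) {
  m <- object$shift
  m[!object$valid] <- NA_real_
  d <- .map_long(m)
  ggplot(d, aes(x = .data$col, y = -.data$row, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "grey20", name = "ppm", option = "magma") +
    coord_fixed() +
    labs(title = "B0 shift", x = NULL, y = NULL) +
    theme_minimal()
}

#' Group point plot of ROI means
#'
#' One panel per region showing each subject's ROI mean by group with the
#' group mean overlaid, the layout used for reporting regional group
#' differences.
#'
#' @param table Cohort table (long format).
#' @param metric Metric to plot.
#' @return A ggplot.
#' @export
plot_cohort <- function(table, metric = "noe_mtr") {
  d <- table[table$metric == metric, ]
  ggplot(d, aes(x = .data$group, y = .data$value, colour = .data$group)) +
    geom_point(position = position_dodge(width = 0.2), alpha = 0.8) +
    stat_summary(fun = mean, geom = "point", shape = 3, size = 3,
                 colour = "black") +
    facet_wrap(~ .data$roi, scales = "free_y") +
    labs(x = NULL, y = paste(metric, "(%)")) +
    theme_minimal()
}
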