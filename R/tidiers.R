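#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the mixed-model group effect
#'
#' @param x A [fit_lmm()] result.
#' @param ... Unused.
#' @return One-row tibble: `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @method tidy noe_lmm
#' @export
tidy.noe_lmm <- function(x, ...) {
  tibble(term = "group", estimate = x$estimate, std.error = x$se,
         statistic = x$statistic, p.value = x$p_value)
}

#' Model-level summary of the mixed fit
#'
#' @param x A [fit_lmm()] result.
#' @param ... Unused.
#' @return One-row tibble: `icc`, `sigma`, `logLik`, `singular`, `nobs`.
#' @method glance noe_lmm
#' @export
glance.noe_lmm <- function(x, ...) {
  tibble(icc = x$icc, sigma = stats::sigma(x$model),
         logLik = as.numeric(stats::logLik(x$model)),
         singular = x$singular, nobs = stats::nobs(x$model))
}

#' Tidy a statistics report
#'
#' @param x A [stats_report()] result.
#' @param ... Unused.
#' @return The per-ROI tibble with the metric attached.
#' @method tidy stats_report
#' @export
tidy.stats_report <- function(x, ...) {
  out <- x$per_roi
  out$metric <- x$metric
  out
}

#' @method glance stats_report
#' @export
glance.stats_report <- function(x, ...) {
  tibble(metric = x$metric, estimate = x$lmm$estimate, se = x$lmm$se,
         p_value = x$lmm$p_value, icc = x$icc, alpha = x$alpha)
}
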