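#' ROI means of a contrast map
#'
#' Arithmetic mean of the non-`NA` pixels of each labelled region, returned
#' as cohort-table rows. Regions that are entirely `NA` are dropped with a
#' warning.
#'
#' @param map A [contrast_map()] (or plain matrix, percent).
#' @param labels A [label_image()] aligned to the map grid.
#' @param metric Metric name recorded in the rows.
#' @param subject,group Identifiers recorded in the rows.
#' @return Tibble with `subject`, `group`, `roi`, `metric`, `value`,
#'   `n_pixels`.
#' @export
roi_means <- function(map, labels, metric = "noe_mtr",
                      subject = NA_character_, group = NA_character_) {
  vals <- if (inherits(map, "contrast_map")) map$values else map
  stopifnot(all(dim(vals) == dim(labels$labels)))
  rows <- purrr::map_dfr(seq_len(nrow(labels$roi_table)), function(i) {
    lb <- labels$roi_table$label[i]
    px <- vals[labels$labels == lb]
    px <- px[is.finite(px)]
    if (length(px) == 0) {
      warning("ROI ", labels$roi_table$roi[i], " is entirely NA; dropped")
      return(NULL)
    }
    tibble(subject = subject, group = group, roi = labels$roi_table$roi[i],
           metric = metric, value = mean(px), n_pixels = length(px))
  })
  rows
}

#' Linear mixed-effects model of the group effect
#'
#' Fits `value ~ group + (1 | roi)` to one metric of a cohort table by
#' restricted maximum likelihood: the fixed effect is disease group, the
#' random effect a per-ROI intercept. The group effect is reported with a
#' Wald (normal-approximation) p-value. A singular random-effect fit is
#' reported, not raised.
#'
#' @param table Cohort table (long format, as produced by [roi_means()]).
#' @param metric Which metric to model.
#' @param ref_group Reference level of the group factor (effects are
#'   `other - ref`); default `"WT"` so AD effects are negative when AD is
#'   lower.
#' @return A `noe_lmm` object: list with `model` (the `lmerMod`), `estimate`,
#'   `se`, `statistic`, `p_value`, `icc`, `singular`, `metric`.
#' @export
fit_lmm <- function(table, metric = "noe_mtr", ref_group = "WT") {
  d <- table[table$metric == metric, ]
  if (length(unique(d$group)) < 2) stop("need at least 2 groups")
  if (length(unique(d$roi)) < 2) stop("need at least 2 ROIs")
  d$group <- stats::relevel(factor(d$group), ref = ref_group)
  fit <- lme4::lmer(value ~ group + (1 | roi), data = d, REML = TRUE)
  co <- summary(fit)$coefficients
  est <- co[2, "Estimate"]; se <- co[2, "Std. Error"]; tval <- co[2, "t value"]
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_roi <- vc$vcov[vc$grp == "roi"]
  v_res <- vc$vcov[vc$grp == "Residual"]
  icc <- if (v_roi + v_res > 0) v_roi / (v_roi + v_res) else NaN
  structure(
    list(model = fit, estimate = est, se = se, statistic = tval,
         p_value = 2 * stats::pnorm(-abs(tval)), icc = icc,
         singular = lme4::isSingular(fit), metric = metric),
    class = "noe_lmm"
  )
}

#' @export
print.noe_lmm <- function(x, ...) {
  cat(sprintf(
    "<noe_lmm> %s: group effect %.3f (SE %.3f), Wald p = %.4g; ICC = %.3f%s\n",
    x$metric, x$estimate, x$se, x$p_value, x$icc,
    if (x$singular) " [singular fit]" else ""
  ))
  invisible(x)
}

#' Intraclass correlation coefficient from the mixed model
#'
#' The fraction of total variance attributable to ROI:
#' `var_roi / (var_roi + var_residual)`, with variance components from the
#' REML fit of [fit_lmm()]. Zero total variance is undefined (`NaN`).
#'
#' @inheritParams fit_lmm
#' @return The ICC (scalar).
#' @export
compute_icc <- function(table, metric = "noe_mtr", ref_group = "WT") {
  fit_lmm(table, metric, ref_group)$icc
}

#' Per-ROI ordinary least squares group comparison
#'
#' Regresses the ROI mean on the group indicator separately for each ROI
#' (equivalent to an equal-variance two-sample t-test) and flags regions
#' significant at `alpha`. ROIs with fewer than two subjects in either group
#' are skipped with a warning. An optional Holm adjustment across ROIs is
#' off by default, matching the per-region reporting convention.
#'
#' @inheritParams fit_lmm
#' @param alpha Significance level.
#' @param holm Apply Holm correction across ROIs before flagging.
#' @return Tibble with `roi`, `estimate`, `se`, `statistic`, `p_value`,
#'   `significant`, and `stars` (`"**"` p<0.01, `"*"` p<0.05).
#' @export
per_roi_ols <- function(table, metric = "noe_mtr", alpha = 0.05,
                        ref_group = "WT", holm = FALSE) {
  d <- table[table$metric == metric, ]
  d$group <- stats::relevel(factor(d$group), ref = ref_group)
  out <- purrr::map_dfr(split(d, d$roi), function(dd) {
    if (min(table(dd$group)) < 2) {
      warning("ROI ", dd$roi[1], " has a group with < 2 subjects; skipped")
      return(NULL)
    }
    fit <- stats::lm(value ~ group, data = dd)
    co <- summary(fit)$coefficients
    tibble(roi = dd$roi[1], estimate = co[2, 1], se = co[2, 2],
           statistic = co[2, 3], p_value = co[2, 4])
  })
  p_flag <- if (holm) stats::p.adjust(out$p_value, "holm") else out$p_value
  out$significant <- p_flag < alpha
  out$stars <- dplyr::case_when(p_flag < 0.01 ~ "**", p_flag < 0.05 ~ "*",
                                TRUE ~ "")
  out
}

#' Full statistical report for one metric
#'
#' Runs the mixed model, the ICC, and the per-ROI OLS battery and bundles
#' them, mirroring the reporting convention: overall group effect with Wald
#' p, ICC, and per-region significance flags.
#'
#' @inheritParams per_roi_ols
#' @return A `stats_report` list: `metric`, `lmm` (tibble row), `icc`,
#'   `per_roi` (tibble), `alpha`.
#' @export
stats_report <- function(table, metric = "noe_mtr", alpha = 0.05,
                         ref_group = "WT") {
  n_roi <- length(unique(table$roi[table$metric == metric]))
  if (n_roi >= 2) {
    lmm <- fit_lmm(table, metric, ref_group)
    lmm_row <- tibble(estimate = lmm$estimate, se = lmm$se,
                      statistic = lmm$statistic, p_value = lmm$p_value,
                      singular = lmm$singular)
    icc <- lmm$icc
  } else {
    # a single region cannot support a per-ROI random effect
    lmm_row <- tibble(estimate = NA_real_, se = NA_real_,
                      statistic = NA_real_, p_value = NA_real_,
                      singular = NA)
    icc <- NaN
  }
  structure(
    list(metric = metric,
         lmm = lmm_row,
         icc = icc,
         per_roi = per_roi_ols(table, metric, alpha, ref_group),
         alpha = alpha),
    class = "stats_report"
  )
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("== %s ==\n", x$metric))
  cat(sprintf("Mixed model group effect: %.3f (SE %.3f), p = %.4g\n",
              x$lmm$estimate, x$lmm$se, x$lmm$p_value))
  cat(sprintf("ICC (ROI): %.3f\n", x$icc))
  for (i in seq_len(nrow(x$per_roi))) {
    cat(sprintf("  %-20s %+6.2f  p = %.4g %s\n", x$per_roi$roi[i],
                x$per_roi$estimate[i], x$per_roi$p_value[i], x$per_roi$stars[i]))
  }
  invisible(x)
}
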