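#' Packaged synthetic atlas
#'
#' The atlas stand-in used by the registration stage: the noiseless
#' anatomical image of the canonical phantom layout together with its label
#' image.
#'
#' @param size Slice side in pixels.
#' @return List with `image` (matrix) and `labels` ([label_image()]).
#' @export
phantom_atlas <- function(size = 128) {
  labels <- make_label_phantom(size)
  img <- matrix(0.03, size, size)
  img[labels$brain] <- 0.50
  for (i in seq_along(ROI_NAMES)) img[labels$labels == i] <- ANAT_INTENSITY[[i]]
  img[labels$ventricles] <- 0.95
  list(image = img, labels = labels)
}

#' Pipeline run configuration
#'
#' @param phantom A [phantom_config()] describing the simulated cohort.
#' @param pool_config Fitting configuration, see [default_pool_config()].
#' @param b0_correct,denoise Toggle the preprocessing stages.
#' @param fit Run the voxelwise five-pool fit.
#' @param fit_rois Character vector of ROI names to restrict the fit to
#'   (`NULL` = whole brain mask).
#' @param register Register the packaged atlas to each subject and use the
#'   transferred labels for ROI statistics (otherwise the phantom's own
#'   labels are used).
#' @param uncorrected_smooth_sigma Gaussian sigma (pixels) applied to the
#'   B0-uncorrected NOE_MTR map before ROI statistics.
#' @param alpha Significance level for the statistics stage.
#' @return A `run_config` list.
#' @export
run_config <- function(phantom = phantom_config(), pool_config = default_pool_config(),
                       b0_correct = TRUE, denoise = TRUE, fit = TRUE,
                       fit_rois = NULL, register = FALSE,
                       uncorrected_smooth_sigma = 0.75, alpha = 0.05) {
  structure(
    list(phantom = phantom, pool_config = pool_config,
         b0_correct = b0_correct, denoise = denoise, fit = fit,
         fit_rois = fit_rois, register = register,
         uncorrected_smooth_sigma = uncorrected_smooth_sigma, alpha = alpha),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Scalar options map directly onto [run_config()] and [phantom_config()]
#' arguments; anything omitted keeps its default.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- do.call(phantom_config, modifyList(
    list(), y$phantom %||% list()
  ))
  args <- y[setdiff(names(y), "phantom")]
  args$phantom <- ph
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Simulates the cohort, then per subject: WASSR B0 estimation, spectrum
#' correction, corrected and uncorrected(+smoothed) NOE_MTR maps, optional
#' Casorati SVD denoising and voxelwise five-pool fitting, optional
#' atlas-to-subject registration with label transfer, and ROI means. Group
#' statistics (mixed model, ICC, per-ROI OLS) are run per metric. All maps,
#' tables, reports and a manifest are written under `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `cohort_table`, `reports`, `manifest`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)

  say("simulating cohort (", config$phantom$n_per_group, " per group, ",
      config$phantom$size, "px)")
  cohort <- .stage("simulate", simulate_cohort(config$phantom))
  atlas <- phantom_atlas(config$phantom$size)

  rows <- list()
  for (id in names(cohort$subjects)) {
    sub <- cohort$subjects[[id]]
    say("subject ", id)
    b0 <- .stage("b0_estimate", estimate_b0_map(sub$wassr, sub$zspec$mask))
    zc <- if (config$b0_correct) {
      .stage("b0_correct", apply_b0_correction(sub$zspec, b0))
    } else sub$zspec

    mtr <- .stage("noe_mtr", compute_noe_mtr(zc))
    mtr_unc <- .stage("noe_mtr_uncorrected", gaussian_smooth(
      compute_noe_mtr(sub$zspec), config$uncorrected_smooth_sigma
    ))

    labels_use <- sub$labels
    if (config$register) {
      labels_use <- .stage("register", {
        mask <- skull_strip_fcm(sub$anatomical)
        atl <- histogram_normalize(atlas$image, sub$anatomical,
                                   mask_fixed = mask)
        chain <- multiscale_affine(atl, sub$anatomical, mask = mask)
        chain <- demons_refine(atl, sub$anatomical, chain)
        transfer_labels(atlas$labels, chain)
      })
    }

    sdir <- file.path(out_dir, id)
    dir.create(sdir, showWarnings = FALSE)
    write_b0_map(b0, file.path(sdir, "b0.nii.gz"))
    write_contrast_map(mtr, file.path(sdir, "noe_mtr.nii.gz"))
    write_contrast_map(mtr_unc, file.path(sdir, "noe_mtr_uncorrected.nii.gz"))

    rows[[length(rows) + 1]] <- roi_means(mtr, labels_use, "noe_mtr",
                                          subject = id, group = sub$group)
    rows[[length(rows) + 1]] <- roi_means(mtr_unc, labels_use,
                                          "noe_mtr_uncorrected",
                                          subject = id, group = sub$group)

    if (config$fit) {
      z_fit <- sub$zspec
      if (config$denoise) z_fit <- .stage("denoise", svd_denoise(z_fit)$zspec)
      if (config$b0_correct) z_fit <- .stage("b0_correct_fit",
                                             apply_b0_correction(z_fit, b0))
      fmask <- z_fit$mask
      labels_fit <- labels_use
      if (!is.null(config$fit_rois)) {
        sel <- labels_use$roi_table$label[labels_use$roi_table$roi %in%
                                            config$fit_rois]
        fmask <- fmask & matrix(labels_use$labels %in% sel,
                                nrow(fmask), ncol(fmask))
        # fit metrics are only defined over the fitted regions
        labels_fit$roi_table <-
          labels_fit$roi_table[labels_fit$roi_table$label %in% sel, ]
      }
      fit <- .stage("fit", fit_multipool(z_fit, config$pool_config,
                                         mask = fmask))
      for (p in c("NOE", "amide", "amine", "MT")) {
        pm <- pool_amplitude_map(fit, p)
        write_contrast_map(pm, file.path(sdir, sprintf("pool_%s.nii.gz", p)))
        metric <- c(NOE = "rnoe", amide = "amide", amine = "amine",
                    MT = "mt")[[p]]
        rows[[length(rows) + 1]] <- roi_means(pm, labels_fit, metric,
                                              subject = id, group = sub$group)
      }
      readr::write_csv(fit_table(fit), file.path(sdir, "fit_params.csv"))
    }
  }

  cohort_table <- dplyr::bind_rows(rows)
  readr::write_csv(cohort_table, file.path(out_dir, "cohort_table.csv"))
  readr::write_csv(cohort$truth, file.path(out_dir, "ground_truth.csv"))

  say("statistics")
  reports <- list()
  for (m in unique(cohort_table$metric)) {
    rep <- .stage("stats", stats_report(cohort_table, m, alpha = config$alpha))
    write_stats_report(rep, file.path(out_dir, paste0("stats_", m)))
    reports[[m]] <- rep
  }

  manifest <- list(
    package = "noemri",
    version = as.character(utils::packageVersion("noemri")),
    seed = config$phantom$seed,
    config_hash = rlang::hash(config),
    n_subjects = length(cohort$subjects),
    metrics = names(reports),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(cohort_table = cohort_table, reports = reports,
                 manifest = manifest, out_dir = out_dir))
}
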