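toy_labels <- function() {
  lab <- matrix(0L, 4, 4)
  lab[1:2, 1:2] <- 1L
  lab[3:4, 3:4] <- 2L
  label_image(lab, tibble::tibble(label = 1:2, roi = c("a", "b")))
}

test_that("ROI means reduce to hand-computed pixel averages", {
  lab <- toy_labels()
  m <- matrix(7, 4, 4)
  out <- roi_means(m, lab)
  expect_equal(out$value, c(7, 7))
  vals <- matrix(0, 4, 4)
  vals[1:2, 1:2] <- c(1, 2, 3, 4)
  vals[3:4, 3:4] <- c(10, 20, 30, 40)
  out2 <- roi_means(vals, lab)
  expect_equal(out2$value, c(mean(1:4), mean(c(10, 20, 30, 40))))
  expect_equal(out2$n_pixels, c(4L, 4L))
  # masking pixels only removes them from that ROI's average
  vals[1, 1] <- NA
  out3 <- roi_means(vals, lab)
  expect_equal(out3$value[1], mean(c(2, 3, 4)))
  expect_equal(out3$n_pixels[1], 3L)
  vals[1:2, 1:2] <- NA
  expect_warning(out4 <- roi_means(vals, lab), "entirely NA")
  expect_equal(nrow(out4), 1L)
})

test_that("per-ROI OLS equals the equal-variance two-sample t-test", {
  set.seed(61)
  for (i in 1:8) {
    tab <- dplyr::bind_rows(lapply(c("r1", "r2", "r3"), function(r)
      make_table(rnorm(5, 40), rnorm(5, 39), roi = r)))
    ols <- per_roi_ols(tab)
    for (r in c("r1", "r2", "r3")) {
      d <- tab[tab$roi == r, ]
      tt <- t.test(value ~ group, data = d, var.equal = TRUE)
      expect_equal(ols$p_value[ols$roi == r], tt$p.value, tolerance = 1e-10)
    }
  }
})

test_that("the toy group comparison matches hand arithmetic", {
  wt <- c(40, 41, 40, 39, 40); ad <- c(37, 36, 37, 38, 37)
  ols <- per_roi_ols(make_table(wt, ad))
  expect_equal(ols$estimate, -3)
  # hand-computed pooled t statistic and two-sided p
  sp2 <- (4 * var(wt) + 4 * var(ad)) / 8
  t_hand <- (mean(ad) - mean(wt)) / sqrt(sp2 * (2 / 5))
  expect_equal(ols$statistic, t_hand, tolerance = 1e-12)
  expect_equal(ols$p_value, 2 * pt(-abs(t_hand), df = 8), tolerance = 1e-12)
  expect_true(ols$significant)
  expect_equal(ols$stars, "**")
})

test_that("identical groups produce no significance flags", {
  set.seed(62)
  vals <- rnorm(5, 40, 0.5)
  tab <- make_table(vals, vals)
  ols <- per_roi_ols(tab)
  expect_false(any(ols$significant))
  expect_equal(ols$estimate, 0)
  lmm_tab <- dplyr::bind_rows(lapply(paste0("r", 1:4), function(r)
    make_table(vals, vals, roi = r)))
  fit <- fit_lmm(lmm_tab)
  expect_lt(abs(fit$estimate), 1e-8)
  expect_gt(fit$p_value, 0.05)
})

test_that("the mixed model recovers a simulated group shift", {
  est <- p_neg <- numeric(100)
  for (s in 1:100) {
    set.seed(400 + s)
    roi_eff <- rnorm(8, 0, 2)
    tab <- dplyr::bind_rows(lapply(1:8, function(r)
      make_table(40 + roi_eff[r] + rnorm(5, 0, 0.5),
                 37 + roi_eff[r] + rnorm(5, 0, 0.5),
                 roi = paste0("r", r))))
    fit <- fit_lmm(tab)
    est[s] <- fit$estimate
  }
  expect_lt(abs(mean(est) - (-3)), 0.2)
})

test_that("the group effect on packaged ground truths is negative (AD < WT)", {
  rp <- default_roi_params()
  rp <- rp[rp$roi != "brain_other", ]
  set.seed(63)
  tab <- dplyr::bind_rows(lapply(seq_len(nrow(rp)), function(i)
    tibble::tibble(
      subject = paste0(rp$group[i], 1:5), group = rp$group[i],
      roi = rp$roi[i], metric = "noe_mtr",
      value = rp$noe_mtr[i] + rnorm(5, 0, 0.3), n_pixels = 100L
    )))
  fit <- fit_lmm(tab)
  expect_lt(fit$estimate, 0)
  expect_lt(fit$p_value, 0.05)
})

test_that("ICC spans its limits and matches a moments oracle", {
  # strong ROI structure, tiny noise: ICC near 1
  set.seed(64)
  roi_eff <- seq(-6, 6, length.out = 8)
  tab1 <- dplyr::bind_rows(lapply(1:8, function(r)
    make_table(40 + roi_eff[r] + rnorm(5, 0, 0.01),
               40 + roi_eff[r] + rnorm(5, 0, 0.01), roi = paste0("r", r))))
  expect_gt(compute_icc(tab1), 0.99)

  # no ROI structure: ICC near 0 on average
  iccs <- numeric(100)
  for (s in 1:100) {
    set.seed(500 + s)
    tabn <- dplyr::bind_rows(lapply(1:8, function(r)
      make_table(rnorm(5, 40, 1), rnorm(5, 40, 1), roi = paste0("r", r))))
    iccs[s] <- suppressMessages(compute_icc(tabn))
  }
  expect_lt(mean(iccs), 0.1)

  # balanced-design REML variance components equal the ANOVA moments
  # estimator: MS_roi = sigma2 + n_per_roi * sigma_roi2
  set.seed(65)
  tab2 <- dplyr::bind_rows(lapply(1:6, function(r)
    make_table(rnorm(4, 40 + 2 * r, 0.8), rnorm(4, 39 + 2 * r, 0.8),
               roi = paste0("r", r))))
  fit <- fit_lmm(tab2)
  d <- tab2
  d$group <- factor(d$group)
  aov_fit <- summary(stats::aov(value ~ group + Error(roi), data = d))
  ms_roi <- aov_fit[["Error: roi"]][[1]]["Residuals", "Mean Sq"]
  ms_within <- aov_fit[["Error: Within"]][[1]]["Residuals", "Mean Sq"]
  v_roi_mom <- (ms_roi - ms_within) / 8
  vc <- as.data.frame(lme4::VarCorr(fit$model))
  expect_equal(vc$vcov[vc$grp == "roi"], v_roi_mom, tolerance = 1e-6)
  expect_equal(vc$vcov[vc$grp == "Residual"], ms_within, tolerance = 1e-6)
})

test_that("null simulations flag at the nominal alpha rate", {
  set.seed(66)
  flags <- 0L; total <- 0L
  for (s in 1:1000) {
    tab <- dplyr::bind_rows(lapply(1:8, function(r)
      make_table(rnorm(5, 40, 1), rnorm(5, 40, 1), roi = paste0("r", r))))
    ols <- per_roi_ols(tab)
    flags <- flags + sum(ols$significant)
    total <- total + nrow(ols)
  }
  expect_lt(abs(flags / total - 0.05), 0.01)
})

test_that("reports and tidiers expose consistent columns", {
  set.seed(67)
  tab <- dplyr::bind_rows(lapply(1:4, function(r)
    make_table(rnorm(5, 40, 0.4), rnorm(5, 38, 0.4), roi = paste0("r", r))))
  rep <- stats_report(tab)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_true(all(c("roi", "p_value", "significant") %in% names(tidy(rep))))
  g <- glance(rep)
  expect_equal(g$icc, rep$icc)
  lmm <- fit_lmm(tab)
  expect_equal(tidy(lmm)$estimate, rep$lmm$estimate)
  expect_true(all(c("icc", "logLik") %in% names(glance(lmm))))
  # one-subject groups are skipped with a warning
  bad <- make_table(40, c(37, 38), roi = "tiny")
  expect_warning(out <- per_roi_ols(dplyr::bind_rows(tab, bad)), "skipped")
  expect_false("tiny" %in% out$roi)
})
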