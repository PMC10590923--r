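atlas96 <- function() fixture("atlas96", function() phantom_atlas(96))

test_that("fuzzy c-means skull stripping recovers the drawn head region", {
  atl <- atlas96()
  set.seed(41)
  img <- atl$image + matrix(rnorm(96 * 96, 0, 0.02), 96, 96)
  mask <- skull_strip_fcm(img)
  expect_gt(dice_coefficient(mask, atl$labels$brain), 0.95)
  # single connected component
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  expect_equal(max(as.integer(lab)), 1L)
})

test_that("degenerate intensity histograms fall back to Otsu", {
  img <- matrix(0, 48, 48)
  img[15:35, 15:35] <- 1
  expect_warning(mask <- skull_strip_fcm(img), "Otsu|c-means")
  expect_gt(dice_coefficient(mask, img > 0.5), 0.95)
})

test_that("histogram normalization is monotone and invertible", {
  atl <- atlas96()
  set.seed(42)
  img <- atl$image + matrix(rnorm(96 * 96, 0, 0.02), 96, 96)
  expect_equal(histogram_normalize(img, img), img, tolerance = 1e-6)
  # linear rescale is undone to within one gray level of the 0..1 range
  rescaled <- 0.25 + 0.5 * img
  back <- histogram_normalize(rescaled, img)
  expect_lt(max(abs(back - img)), diff(range(img)) / 256)
  # earth-mover distance between 256-bin histograms shrinks
  emd <- function(a, b) {
    br <- range(c(a, b))
    ha <- hist(a, breaks = seq(br[1], br[2], length.out = 257), plot = FALSE)
    hb <- hist(b, breaks = seq(br[1], br[2], length.out = 257), plot = FALSE)
    sum(abs(cumsum(ha$counts / length(a)) - cumsum(hb$counts / length(b))))
  }
  expect_lt(emd(back, img), emd(rescaled, img))
  expect_warning(histogram_normalize(matrix(2, 8, 8), img), "constant")
})

test_that("self-registration returns an identity affine", {
  atl <- atlas96()
  ch <- multiscale_affine(atl$image, atl$image)
  M <- Reduce(`%*%`, lapply(ch, `[[`, "matrix"), accumulate = FALSE)
  if (is.null(M)) M <- diag(3)
  expect_lt(max(abs(M - diag(3))), 1e-2)
  # demons on identical images stays still
  chd <- demons_refine(atl$image, atl$image, n_iter = 20)
  d <- chd[[length(chd)]]$field
  expect_lt(quantile(sqrt(d[, , 1]^2 + d[, , 2]^2), 0.99), 0.1)
})

test_that("a known affine warp is recovered with Dice >= 0.90", {
  atl <- atlas96()
  center <- c((96 + 1) / 2, (96 + 1) / 2)
  M <- noemri:::.par_to_affine(c(3, 2, 5 * pi / 180, log(1.05), log(1.05), 0),
                               center)
  fixed <- noemri:::.warp_affine(atl$image, solve(M))
  set.seed(43)
  fixed <- fixed + matrix(rnorm(96 * 96, 0, 0.02), 96, 96)
  fixed_lab <- label_image(
    matrix(as.integer(noemri:::.warp_affine(atl$labels$labels * 1.0, solve(M),
                                            "nearest")), 96, 96),
    roi_lookup()
  )
  ch <- multiscale_affine(atl$image, fixed)
  moved <- transfer_labels(atl$labels, ch)
  dice <- vapply(1:8, function(l) dice_coefficient(moved, fixed_lab, l),
                 numeric(1))
  expect_gte(mean(dice), 0.90)
  # the aligned atlas is more similar to the target than the unaligned one
  warped <- chain_apply_image(ch, atl$image)
  expect_gt(noemri:::.mutual_information(warped, fixed),
            noemri:::.mutual_information(atl$image, fixed))
})

test_that("demons strictly improves Dice for a smooth nonlinear warp", {
  atl <- atlas96()
  g <- noemri:::.grid_coords(96, 96)
  wr <- 2.0 * sin(2 * pi * g$c / 96)
  wc <- 2.0 * cos(2 * pi * g$r / 96)
  warped <- matrix(noemri:::.sample_bilinear(atl$image, g$r + wr, g$c + wc),
                   96, 96)
  warped_lab <- label_image(
    matrix(as.integer(noemri:::.sample_nn(atl$labels$labels, g$r + wr,
                                          g$c + wc)), 96, 96),
    roi_lookup()
  )
  cha <- multiscale_affine(atl$image, warped)
  da <- vapply(1:8, function(l)
    dice_coefficient(transfer_labels(atl$labels, cha), warped_lab, l),
    numeric(1))
  chb <- demons_refine(atl$image, warped, cha, n_iter = 50)
  db <- vapply(1:8, function(l)
    dice_coefficient(transfer_labels(atl$labels, chb), warped_lab, l),
    numeric(1))
  expect_gt(mean(db), mean(da))
  expect_true(all(db > 0.85))
})

test_that("label transfer preserves the label set exactly", {
  atl <- fixture("atlas64", function() phantom_atlas(64))
  # identity chain
  ident <- structure(list(), class = "transform_chain")
  expect_identical(transfer_labels(atl$labels, ident)$labels, atl$labels$labels)
  # whole-pixel translation shifts labels exactly
  M <- diag(3); M[1, 3] <- 4; M[2, 3] <- -3
  ch <- structure(list(list(type = "affine", matrix = M, sigma = 0)),
                  class = "transform_chain")
  moved <- transfer_labels(atl$labels, ch)
  expect_identical(moved$labels[1:60, 4:64],
                   atl$labels$labels[5:64, 1:61])
  # random smooth chains never invent labels
  set.seed(44)
  for (i in 1:5) {
    d <- array(rnorm(64 * 64 * 2, 0, 1.5), dim = c(64, 64, 2))
    d <- noemri:::.smooth_field(d, 3)
    ch2 <- structure(
      list(list(type = "affine",
                matrix = noemri:::.par_to_affine(rnorm(6, 0, 0.03) * c(30, 30, 1, 1, 1, 1),
                                                 c(32.5, 32.5)),
                sigma = 0),
           list(type = "displacement", field = d, sigma = 1)),
      class = "transform_chain"
    )
    out <- suppressWarnings(transfer_labels(atl$labels, ch2))
    expect_true(all(out$labels %in% c(0L, atl$labels$roi_table$label)))
  }
})
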