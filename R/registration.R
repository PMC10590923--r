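#' Skull stripping by fuzzy c-means clustering
#'
#' Clusters the intensity histogram into three fuzzy classes (background,
#' tissue, bright fluid), takes the union of the two brightest-centroid
#' classes at membership > 0.5 as candidate brain, keeps the largest
#' connected component and closes it morphologically (disc radius 2). If the
#' image lacks three distinct intensity modes the method falls back to an
#' Otsu threshold with a warning.
#'
#' @param img 2D intensity image (matrix).
#' @param membership Membership cut-off for the bright classes.
#' @return Logical brain mask.
#' @export
skull_strip_fcm <- function(img, membership = 0.5) {
  v <- as.vector(img)
  cand <- tryCatch({
    if (length(unique(signif(v, 6))) < 3) stop("fewer than 3 intensity modes")
    cm <- e1071::cmeans(matrix(v, ncol = 1), centers = 3, m = 2,
                        iter.max = 100)
    bright <- order(as.vector(cm$centers), decreasing = TRUE)[1:2]
    matrix(cm$membership[, bright[1]] > membership |
             cm$membership[, bright[2]] > membership,
           nrow(img), ncol(img))
  }, error = function(e) {
    warning("fuzzy c-means failed (", conditionMessage(e),
            "); falling back to Otsu threshold")
    rng <- range(v)
    sc <- (img - rng[1]) / max(diff(rng), .Machine$double.eps)
    sc > EBImage::otsu(EBImage::Image(sc))
  })
  lab <- EBImage::bwlabel(EBImage::Image(cand * 1))
  tab <- tabulate(as.integer(lab)[as.integer(lab) > 0])
  if (length(tab) == 0) return(matrix(FALSE, nrow(img), ncol(img)))
  biggest <- which.max(tab)
  mask <- matrix(as.integer(lab) == biggest, nrow(img), ncol(img))
  closed <- EBImage::closing(EBImage::Image(mask * 1),
                             EBImage::makeBrush(5, shape = "disc"))
  matrix(as.numeric(closed) > 0.5, nrow(img), ncol(img))
}

#' Histogram-based intensity normalization
#'
#' Monotone quantile mapping of the moving image's masked intensities onto
#' the fixed image's, using 256 quantile landmarks. A constant moving image
#' cannot be matched; it is shifted to the fixed median with a warning.
#'
#' @param moving,fixed 2D images.
#' @param mask_moving,mask_fixed Logical masks over which the histograms are
#'   taken (default: whole image).
#' @param n_landmarks Number of quantile landmarks.
#' @return The intensity-matched moving image.
#' @export
histogram_normalize <- function(moving, fixed, mask_moving = NULL,
                                mask_fixed = NULL, n_landmarks = 256) {
  vm <- if (is.null(mask_moving)) as.vector(moving) else moving[mask_moving]
  vf <- if (is.null(mask_fixed)) as.vector(fixed) else fixed[mask_fixed]
  if (diff(range(vm)) == 0) {
    warning("constant moving image; shifting to the fixed median")
    return(moving - vm[1] + stats::median(vf))
  }
  p <- seq(0, 1, length.out = n_landmarks)
  qm <- quantile(vm, p, names = FALSE, type = 7)
  qf <- quantile(vf, p, names = FALSE, type = 7)
  # collapse ties in the moving quantiles so approx() sees increasing x
  keep <- !duplicated(qm)
  out <- approx(qm[keep], qf[keep], xout = as.vector(moving), rule = 2)$y
  matrix(out, nrow(moving), ncol(moving))
}

#' Multiscale affine registration
#'
#' Registers `moving` (atlas) to `fixed` over a sequence of rounds: in each
#' round both images are blurred with the round's Gaussian sigma (a
#' geometric schedule from `sigma_from` down to `sigma_to`), an incremental
#' affine update (translation, rotation, anisotropic scale, shear) is
#' estimated by maximizing mutual information with a derivative-free
#' Nelder-Mead search, and the update is composed onto the chain. Rounds
#' whose optimized metric is worse than the incumbent are discarded with a
#' warning.
#'
#' @param moving,fixed 2D images on the same grid.
#' @param mask Logical matrix over which the metric is evaluated (default:
#'   whole image).
#' @param n_iter Number of blur/register rounds.
#' @param sigma_from,sigma_to First and last blur sigma (pixels).
#' @param bins Histogram bins for mutual information.
#' @param optim_maxit Nelder-Mead iterations per round.
#' @return A `transform_chain`: list of stages, each
#'   `list(type = "affine", matrix, sigma)`, plus a `metric` trace attribute.
#' @export
multiscale_affine <- function(moving, fixed, mask = NULL, n_iter = 10,
                              sigma_from = 4, sigma_to = 0.4, bins = 32,
                              optim_maxit = 120) {
  stopifnot(all(dim(moving) == dim(fixed)))
  sigmas <- exp(seq(log(sigma_from), log(sigma_to), length.out = n_iter))
  center <- c((nrow(fixed) + 1) / 2, (ncol(fixed) + 1) / 2)
  cum <- diag(3)
  stages <- list()
  trace <- numeric(0)
  best <- -Inf
  for (it in seq_len(n_iter)) {
    mb <- gaussian_smooth(moving, sigmas[it])
    fb <- gaussian_smooth(fixed, sigmas[it])
    obj <- function(par) {
      M <- cum %*% .par_to_affine(par, center)
      -.mutual_information(.warp_affine(mb, M), fb, mask, bins)
    }
    opt <- stats::optim(rep(0, 6), obj, method = "Nelder-Mead",
                        control = list(
                          maxit = optim_maxit,
                          parscale = c(2, 2, 0.05, 0.05, 0.05, 0.05)
                        ))
    metric <- -obj(opt$par)
    ident_metric <- -obj(rep(0, 6))
    if (metric < ident_metric) {
      warning("affine round ", it, " diverged; keeping previous chain")
      trace <- c(trace, ident_metric)
      next
    }
    delta <- .par_to_affine(opt$par, center)
    cum <- cum %*% delta
    stages[[length(stages) + 1]] <- list(type = "affine", matrix = delta,
                                         sigma = sigmas[it])
    trace <- c(trace, metric)
    best <- max(best, metric)
  }
  structure(stages, class = "transform_chain", metric = trace)
}

#' Demons refinement of a transform chain
#'
#' Appends a dense displacement field to an affine chain. The moving image is
#' first resampled through the affine stages; a demons update field is then
#' iterated: the intensity-difference force is smoothed (fluid
#' regularization), composed onto the field (diffeomorphic variant:
#' through the exponential map, so the field stays invertible; additive
#' variant: plain Thirion update), and the field itself is smoothed (elastic
#' regularization, default sigma 1). Folding (negative Jacobian) in more
#' than 1 percent of pixels triggers a warning.
#'
#' @param moving,fixed 2D images on the same grid.
#' @param chain A [multiscale_affine()] result (may be empty).
#' @param n_iter Demons iterations.
#' @param field_sigma,update_sigma Elastic/fluid Gaussian sigmas (pixels).
#' @param variant `"diffeomorphic"` or `"additive"`.
#' @param max_step Cap on the per-iteration displacement update (pixels).
#' @return The chain with a `list(type = "displacement", field, sigma)` stage
#'   appended.
#' @export
demons_refine <- function(moving, fixed, chain = structure(list(), class = "transform_chain"),
                          n_iter = 50, field_sigma = 1.0, update_sigma = 1.0,
                          variant = c("diffeomorphic", "additive"),
                          max_step = 2) {
  variant <- match.arg(variant)
  m0 <- chain_apply_image(chain, moving, interp = "bilinear")
  n1 <- nrow(fixed); n2 <- ncol(fixed)
  d <- array(0, dim = c(n1, n2, 2))
  g <- .grid_coords(n1, n2)
  eps <- 1e-8
  for (it in seq_len(n_iter)) {
    src <- .sample_field(d, g$r, g$c)
    mw <- matrix(.sample_bilinear(m0, g$r + src$r, g$c + src$c), n1, n2)
    diffi <- fixed - mw
    gr <- (rbind(mw[-1, ], mw[n1, ]) - rbind(mw[1, ], mw[-n1, ])) / 2
    gc <- (cbind(mw[, -1], mw[, n2]) - cbind(mw[, 1], mw[, -n2])) / 2
    den <- gr^2 + gc^2 + diffi^2
    scale <- ifelse(den > eps, diffi / den, 0)
    u <- array(0, dim = c(n1, n2, 2))
    u[, , 1] <- pmin(pmax(scale * gr, -max_step), max_step)
    u[, , 2] <- pmin(pmax(scale * gc, -max_step), max_step)
    u <- .smooth_field(u, update_sigma)
    if (variant == "diffeomorphic") {
      d <- .compose_disp(d, .exp_field(u))
    } else {
      d <- d + u
    }
    d <- .smooth_field(d, field_sigma)
  }
  fold <- .folding_fraction(d)
  if (fold > 0.01) {
    warning(sprintf("displacement field folds in %.1f%% of pixels", 100 * fold))
  }
  stages <- c(unclass(chain), list(list(type = "displacement", field = d,
                                        sigma = field_sigma)))
  structure(stages, class = "transform_chain", metric = attr(chain, "metric"))
}

#' @export
print.transform_chain <- function(x, ...) {
  types <- vapply(x, `[[`, character(1), "type")
  cat(sprintf("<transform_chain> %d stage(s): %s\n", length(x),
              paste(types, collapse = " -> ")))
  invisible(x)
}

# internal: map fixed-grid coordinates through the chain to moving
# coordinates. Displacement stages (recorded last) act on the fixed grid
# first; affine stages compose into one matrix applied afterwards.
.chain_coords <- function(chain, n1, n2) {
  g <- .grid_coords(n1, n2)
  r <- g$r; c <- g$c
  disp <- Filter(function(s) s$type == "displacement", chain)
  for (s in rev(disp)) {
    dd <- .sample_field(s$field, r, c)
    r <- r + dd$r; c <- c + dd$c
  }
  aff <- Filter(function(s) s$type == "affine", chain)
  if (length(aff) > 0) {
    M <- Reduce(`%*%`, lapply(aff, `[[`, "matrix"))
    out <- .apply_affine_coords(M, r, c)
    r <- out$r; c <- out$c
  }
  list(r = r, c = c)
}

#' Apply a transform chain to an image
#'
#' @param chain A `transform_chain`.
#' @param img 2D image.
#' @param interp `"bilinear"` or `"nearest"`.
#' @return The resampled image.
#' @export
chain_apply_image <- function(chain, img, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  if (length(chain) == 0) return(img)
  co <- .chain_coords(chain, nrow(img), ncol(img))
  f <- if (interp == "bilinear") .sample_bilinear else .sample_nn
  matrix(f(img, co$r, co$c), nrow(img), ncol(img))
}

#' Transfer ROI labels through a transform chain
#'
#' Resamples a label image through the chain using nearest-neighbour
#' interpolation throughout, so every output value is a member of the input
#' label set. A region mapped entirely off-grid is reported by warning and
#' dropped from the ROI table.
#'
#' @param labels A [label_image()].
#' @param chain A `transform_chain`.
#' @return A [label_image()] on the fixed grid.
#' @export
transfer_labels <- function(labels, chain) {
  warped <- chain_apply_image(chain, labels$labels, interp = "nearest")
  storage.mode(warped) <- "integer"
  lost <- setdiff(labels$roi_table$label, unique(as.vector(warped)))
  tab <- labels$roi_table
  if (length(lost) > 0) {
    warning("ROI(s) lost in transfer: ",
            paste(tab$roi[tab$label %in% lost], collapse = ", "))
    tab <- tab[!tab$label %in% lost, ]
  }
  label_image(warped, tab)
}

#' Dice overlap coefficient
#'
#' `2|A n B| / (|A| + |B|)` between two binary masks, or between one label's
#' footprint in two label images.
#'
#' @param a,b Logical matrices, or [label_image()]s when `label` is given.
#' @param label Optional label value to compare.
#' @return Dice coefficient in `[0, 1]` (`NaN` if both regions are empty).
#' @export
dice_coefficient <- function(a, b, label = NULL) {
  if (!is.null(label)) {
    a <- a$labels == label
    b <- b$labels == label
  }
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NaN)
  2 * sum(a & b) / denom
}
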