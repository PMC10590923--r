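# Internal resampling and transform plumbing shared by the registration
# stage. Coordinates are (row, col), 1-based, continuous; affine matrices are
# 3x3 homogeneous acting on (row, col, 1) and map FIXED coordinates to MOVING
# coordinates (pull-back convention, as used when resampling). Displacement
# fields are nrow x ncol x 2 arrays (d_row, d_col) on the fixed grid.

.grid_coords <- function(n1, n2) {
  list(r = rep(seq_len(n1), times = n2), c = rep(seq_len(n2), each = n1))
}

.sample_bilinear <- function(img, r, c) {
  n1 <- nrow(img); n2 <- ncol(img)
  r <- pmin(pmax(r, 1), n1); c <- pmin(pmax(c, 1), n2)
  r0 <- pmin(floor(r), n1 - 1L); c0 <- pmin(floor(c), n2 - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  img[i00] * (1 - fr) * (1 - fc) + img[i10] * fr * (1 - fc) +
    img[i01] * (1 - fr) * fc + img[i11] * fr * fc
}

.sample_nn <- function(img, r, c) {
  n1 <- nrow(img); n2 <- ncol(img)
  r <- pmin(pmax(round(r), 1), n1); c <- pmin(pmax(round(c), 1), n2)
  img[cbind(r, c)]
}

# parameters: (t_row, t_col, angle, log_scale_row, log_scale_col, shear)
.par_to_affine <- function(par, center) {
  th <- par[3]
  rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  sc <- diag(exp(par[4:5]))
  sh <- matrix(c(1, par[6], 0, 1), 2, 2, byrow = TRUE)
  A <- sc %*% sh %*% rot
  off <- center - A %*% center + par[1:2]
  rbind(cbind(A, off), c(0, 0, 1))
}

.apply_affine_coords <- function(M, r, c) {
  list(r = M[1, 1] * r + M[1, 2] * c + M[1, 3],
       c = M[2, 1] * r + M[2, 2] * c + M[2, 3])
}

.warp_affine <- function(img, M, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  g <- .grid_coords(nrow(img), ncol(img))
  src <- .apply_affine_coords(M, g$r, g$c)
  f <- if (interp == "bilinear") .sample_bilinear else .sample_nn
  matrix(f(img, src$r, src$c), nrow(img), ncol(img))
}

# sample a displacement field at arbitrary coordinates (bilinear per channel)
.sample_field <- function(d, r, c) {
  list(r = .sample_bilinear(d[, , 1], r, c), c = .sample_bilinear(d[, , 2], r, c))
}

# composition of displacement fields: result(x) = u(x) + d(x + u(x))
.compose_disp <- function(d, u) {
  n1 <- dim(u)[1]; n2 <- dim(u)[2]
  g <- .grid_coords(n1, n2)
  ur <- as.vector(u[, , 1]); uc <- as.vector(u[, , 2])
  dd <- .sample_field(d, g$r + ur, g$c + uc)
  out <- array(0, dim = dim(u))
  out[, , 1] <- matrix(ur + dd$r, n1, n2)
  out[, , 2] <- matrix(uc + dd$c, n1, n2)
  out
}

# exponential of a velocity field by scaling and squaring
.exp_field <- function(u) {
  mx <- max(abs(u))
  n <- if (mx <= 0.5) 0L else ceiling(log2(mx / 0.5))
  v <- u / 2^n
  for (i in seq_len(n)) v <- .compose_disp(v, v)
  v
}

.smooth_field <- function(d, sigma) {
  if (sigma <= 0) return(d)
  d[, , 1] <- gaussian_smooth(d[, , 1], sigma)
  d[, , 2] <- gaussian_smooth(d[, , 2], sigma)
  d
}

# fraction of pixels with a non-positive Jacobian determinant of (id + d)
.folding_fraction <- function(d) {
  dr <- d[, , 1]; dc <- d[, , 2]
  grad_r <- function(m) (rbind(m[-1, ], m[nrow(m), ]) - rbind(m[1, ], m[-nrow(m), ])) / 2
  grad_c <- function(m) (cbind(m[, -1], m[, ncol(m)]) - cbind(m[, 1], m[, -ncol(m)])) / 2
  j11 <- 1 + grad_r(dr); j12 <- grad_c(dr)
  j21 <- grad_r(dc); j22 <- 1 + grad_c(dc)
  det <- j11 * j22 - j12 * j21
  mean(det <= 0)
}

# mutual information between two images over a mask, equal-width bins
.mutual_information <- function(a, b, mask = NULL, bins = 32) {
  if (!is.null(mask)) { a <- a[mask]; b <- b[mask] }
  ra <- range(a); rb <- range(b)
  if (diff(ra) == 0 || diff(rb) == 0) return(0)
  ia <- pmin(pmax(floor((a - ra[1]) / diff(ra) * bins) + 1, 1), bins)
  ib <- pmin(pmax(floor((b - rb[1]) / diff(rb) * bins) + 1, 1), bins)
  joint <- tabulate((ia - 1) * bins + ib, bins * bins) / length(a)
  pj <- matrix(joint, bins, bins)
  pa <- colSums(pj); pb <- rowSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / (outer(pb, pa)[nz])))
}
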