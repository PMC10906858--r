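#' Separable Gaussian filter for 2D/3D arrays
#'
#' Smooths an array with an axis-separable Gaussian kernel (radius
#' `ceiling(4*sigma)` per axis) under reflective boundary handling, so
#' total intensity of interior-supported content is conserved. `sigma`
#' may be a scalar (isotropic) or one value per axis; a zero sigma on an
#' axis leaves that axis untouched, and `sigma = 0` returns the input
#' unchanged.
#'
#' @param x numeric vector, matrix or array.
#' @param sigma non-negative standard deviation(s) in pixels/voxels.
#' @return Array of the same shape.
#' @export
gaussian_filter <- function(x, sigma) {
  if (any(sigma < 0)) stop("sigma must be non-negative", call. = FALSE)
  d <- arr_dim(x)
  nd <- length(d)
  if (length(sigma) == 1) sigma <- rep(sigma, nd)
  if (length(sigma) != nd) stop("sigma must be scalar or one per axis", call. = FALSE)
  if (all(sigma == 0)) return(x)
  out <- as.array(x)
  for (ax in seq_len(nd)) {
    if (sigma[ax] == 0 || d[ax] == 1) next
    r <- ceiling(4 * sigma[ax])
    k <- stats::dnorm(seq(-r, r), sd = sigma[ax])
    k <- k / sum(k)
    out <- convolve_axis_reflect(out, k, ax)
  }
  out
}

# 1-d convolution along axis `ax` with reflective padding, vectorized by
# permuting the target axis to the front and operating on a matrix
convolve_axis_reflect <- function(x, k, ax) {
  d <- dim(x)
  nd <- length(d)
  perm <- c(ax, setdiff(seq_len(nd), ax))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = d[ax])
  n <- d[ax]
  r <- (length(k) - 1L) / 2L
  # reflect indices: 1 2 ... n mirrored without repeating edge samples
  # (mode "reflect" about the boundary sample)
  idx <- seq(1L - r, n + r)
  idx <- ifelse(idx < 1L, 2L - idx, idx)
  idx <- ifelse(idx > n, 2L * n - idx, idx)
  # guard extremely wide kernels on tiny axes
  idx <- pmin(pmax(idx, 1L), n)
  mp <- m[idx, , drop = FALSE]
  res <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(k)) {
    res <- res + k[j] * mp[seq_len(n) + (j - 1L), , drop = FALSE]
  }
  out <- array(res, d[perm])
  aperm(out, order(perm))
}
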