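#' Rotation matrices for nucleus placement
#'
#' `rotation_matrix()` builds a 2D in-plane rotation or a 3D rotation by
#' angle `angle` about unit `axis` (Rodrigues' formula);
#' `random_rotation()` draws an angle uniformly in `(0, 2*pi)` and, in
#' 3D, a uniformly random axis.
#'
#' @param angle rotation angle in radians.
#' @param axis unit 3-vector (3D only), in the same axis order as the
#'   array dimensions.
#' @return A 2x2 or 3x3 rotation matrix.
#' @export
rotation_matrix <- function(angle, axis = NULL) {
  if (is.null(axis)) {
    c_ <- cos(angle); s_ <- sin(angle)
    return(matrix(c(c_, s_, -s_, c_), 2, 2))
  }
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' @rdname rotation_matrix
#' @param nd dimensionality, 2 or 3.
#' @export
random_rotation <- function(nd) {
  angle <- stats::runif(1, 0, 2 * pi)
  if (nd == 2) return(rotation_matrix(angle))
  v <- stats::rnorm(3)
  rotation_matrix(angle, v / sqrt(sum(v^2)))
}

#' Rasterize an ellipsoidal nucleus into a boolean mask
#'
#' Sets every voxel whose (optionally rotated) normalized quadratic form
#' is at most 1:
#' \deqn{\sum_i \left(\frac{p'_i - c_i}{s_i\, r}\right)^2 \le 1,}
#' where `p'` are the voxel coordinates rotated about the center `c`,
#' `r` is the nucleus radius and `s` the directional scaling factors.
#' For 2D shapes the third dimension is omitted. Coordinates are
#' voxel-centered array indices in the array's own axis order.
#'
#' @param shape integer vector of array dimensions (2 or 3 long).
#' @param center numeric center, same length as `shape`, inside the image.
#' @param r_nuclei nucleus radius in voxels (> 0).
#' @param scale directional scaling factors, one per axis (default 1).
#' @param rotation `NULL` (no rotation) or a rotation matrix from
#'   [rotation_matrix()] / [random_rotation()].
#' @return Logical array of dimension `shape`.
#' @export
rasterize_ellipsoid <- function(shape, center, r_nuclei, scale = rep(1, length(shape)),
                                rotation = NULL) {
  idx <- ellipsoid_indices(shape, center, r_nuclei, scale, rotation)
  out <- array(FALSE, shape)
  out[idx] <- TRUE
  out
}

# linear voxel indices of the ellipsoid, evaluated inside its bounding box
ellipsoid_indices <- function(shape, center, r_nuclei, scale = rep(1, length(shape)),
                              rotation = NULL) {
  nd <- length(shape)
  if (length(center) != nd)
    stop("center and shape dimensionality mismatch", call. = FALSE)
  if (r_nuclei <= 0) stop("r_nuclei must be positive", call. = FALSE)
  if (any(scale <= 0)) stop("scaling factors must be positive", call. = FALSE)
  if (any(center < 1) || any(center > shape))
    stop("center must lie inside the image", call. = FALSE)
  h <- r_nuclei * max(scale)          # rotation-safe half extent
  lo <- pmax(1L, floor(center - h))
  hi <- pmin(shape, ceiling(center + h))
  ax <- lapply(seq_len(nd), function(i) seq.int(lo[i], hi[i]))
  grid <- as.matrix(expand.grid(ax, KEEP.OUT.ATTRS = FALSE))
  p <- sweep(grid, 2, center)
  if (!is.null(rotation)) p <- p %*% rotation   # rows p %*% R == t(R^T p)
  q <- sweep(p, 2, scale * r_nuclei, "/")
  inside <- rowSums(q^2) <= 1
  sub <- grid[inside, , drop = FALSE]
  mult <- cumprod(c(1, shape[-nd]))
  as.integer(1 + (sub - 1) %*% mult)
}

#' Random B-spline free-form deformation of a mask
#'
#' Distorts a boolean mask with a smooth random displacement field
#' defined by cubic B-spline interpolation of random control-point
#' displacements (uniform in `[-max_displacement, max_displacement]` per
#' axis) on a regular grid of spacing `grid_spacing`. Used to turn exact
#' ellipsoids into the irregular nucleus shapes seen in real data. The
#' warp is applied by backward mapping with nearest-neighbour sampling,
#' so the output stays a crisp boolean mask.
#'
#' @param mask logical 2D/3D array.
#' @param grid_spacing control-grid spacing in voxels.
#' @param max_displacement maximum control-point displacement in voxels;
#'   must stay below `grid_spacing / 2` (fold-free heuristic).
#' @param seed integer seed making the deformation reproducible.
#' @return Logical array of the same shape.
#' @export
deform_bspline <- function(mask, grid_spacing, max_displacement, seed = NULL) {
  if (max_displacement < 0) stop("max_displacement must be non-negative", call. = FALSE)
  if (max_displacement >= grid_spacing / 2)
    stop("max_displacement must be below grid_spacing/2 to keep the warp fold-free",
         call. = FALSE)
  if (max_displacement == 0) return(mask)
  d <- arr_dim(mask)
  nd <- length(d)
  # control grid with a one-cell margin on each side
  n_ctrl <- ceiling(d / grid_spacing) + 3L
  disp <- with_seed(seed, lapply(seq_len(nd), function(i)
    array(stats::runif(prod(n_ctrl), -max_displacement, max_displacement), n_ctrl)))

  grid <- as.matrix(expand.grid(lapply(d, seq_len), KEEP.OUT.ATTRS = FALSE))
  # local B-spline coordinates: control point 2 sits at voxel coordinate 1
  u <- sweep(grid - 1, 2, grid_spacing, "/")
  i0 <- floor(u)
  fr <- u - i0

  bs <- function(f) cbind((1 - f)^3 / 6,
                          (3 * f^3 - 6 * f^2 + 4) / 6,
                          (-3 * f^3 + 3 * f^2 + 3 * f + 1) / 6,
                          f^3 / 6)
  Wax <- lapply(seq_len(nd), function(a) bs(fr[, a]))

  src <- grid * 0
  offs <- as.matrix(expand.grid(rep(list(0:3), nd)))
  mult <- cumprod(c(1, n_ctrl[-nd]))
  for (o in seq_len(nrow(offs))) {
    w <- Wax[[1]][, offs[o, 1] + 1L]
    for (a in seq_len(nd)[-1]) w <- w * Wax[[a]][, offs[o, a] + 1L]
    # lattice point i0+offs-1 lives at 1-based control index i0+offs+1
    cidx <- 1 + sweep(i0, 2, offs[o, ], "+") %*% mult
    for (a in seq_len(nd)) src[, a] <- src[, a] + w * disp[[a]][cidx]
  }
  src <- grid + src                        # backward map: sample input here
  src <- round(src)
  for (a in seq_len(nd)) src[, a] <- pmin(pmax(src[, a], 1L), d[a])
  lin <- as.integer(1 + (src - 1) %*% cumprod(c(1, d[-nd])))
  array(mask[lin], d)
}
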