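#' Equirectangular projection of nuclei on a spherical surface
#'
#' Implements the cartographic projection used for embryos imaged as a
#' spherical surface: the 3D space is considered in spherical
#' coordinates `(r, theta, phi)` about the image center, and for a set
#' of fixed radii the spherical surface is mapped to stacked 2D layers
#' with `(x, y) = (phi, theta)` (equirectangular, latitude-longitude).
#' Points near the poles are stretched over entire rows, as in the real
#' projections.
#'
#' A spherical nucleus of radius `rho` centered at radius `r_c` appears
#' in every layer whose radius `r_k` satisfies `|r_k - r_c| <= rho`; in
#' that layer its footprint is the spherical cap of angular radius
#' `sqrt(rho^2 - (r_k - r_c)^2) / r_k` around its center direction,
#' measured by great-circle distance.
#'
#' @param nuclei data frame with one row per nucleus and columns `label`
#'   (positive integer), `r` (center radius), `theta` (inclination in
#'   `[0, pi]`), `phi` (azimuth in `[0, 2*pi)`), `rho` (nucleus radius).
#' @param radii the fixed projection radii, one per output layer
#'   (13 in the published recipe).
#' @param angular_shape `c(n_theta, n_phi)` pixels of each layer;
#'   pixel pitch is `pi / n_theta` in `theta` and `2*pi / n_phi` in `phi`.
#' @return Integer label array of dimension
#'   `c(length(radii), n_theta, n_phi)` (layers, rows = theta,
#'   columns = phi), with an `n_overlap` attribute counting covering
#'   nuclei per voxel.
#' @export
project_sphere_surface <- function(nuclei, radii, angular_shape) {
  if (any(radii <= 0) || any(duplicated(radii)))
    stop("projection radii must be positive and distinct", call. = FALSE)
  n_theta <- angular_shape[1]; n_phi <- angular_shape[2]
  shp <- c(length(radii), n_theta, n_phi)
  labels <- array(0L, shp)
  n_overlap <- array(0L, shp)
  theta <- (seq_len(n_theta) - 0.5) * pi / n_theta
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  for (i in seq_len(nrow(nuclei))) {
    nc <- nuclei[i, ]
    for (k in seq_along(radii)) {
      dr <- radii[k] - nc$r
      if (abs(dr) > nc$rho) next
      dmax <- sqrt(nc$rho^2 - dr^2) / radii[k]
      rows <- which(abs(theta - nc$theta) <= dmax)
      if (!length(rows)) next
      cosd <- outer(cos(theta[rows]) * cos(nc$theta),
                    rep(1, n_phi)) +
              outer(sin(theta[rows]) * sin(nc$theta), cos(phi - nc$phi))
      hit <- which(acos(pmin(pmax(cosd, -1), 1)) <= dmax, arr.ind = TRUE)
      if (!nrow(hit)) next
      lin <- k + (rows[hit[, 1]] - 1L) * shp[1] + (hit[, 2] - 1L) * shp[1] * shp[2]
      labels[lin] <- nc$label
      n_overlap[lin] <- n_overlap[lin] + 1L
    }
  }
  structure(labels, n_overlap = n_overlap, class = "label_mask")
}

# scene simulation on a spherical embryo surface (runs inside the
# caller's seeded stream)
simulate_sphere_scene <- function(recipe, nucleus) {
  shp <- recipe$image_shape
  if (length(shp) != 3)
    stop("sphere-surface scenes need a 3D image shape (layers, theta, phi)",
         call. = FALSE)
  n_layers <- shp[1]
  # outer radius chosen so the equator is sampled at about 1 voxel/pixel;
  # layers are unit-spaced going inward, the outermost layer last
  r_outer <- shp[3] / (2 * pi)
  radii <- r_outer - (n_layers - seq_len(n_layers))
  if (any(radii <= 0))
    stop("projection radii collapse; increase the angular resolution", call. = FALSE)
  placed <- list()
  labels <- array(0L, shp)
  n_overlap <- array(0L, shp)
  n_placed <- 0L
  attempts_left <- 100L * max(1L, recipe$n_cells)
  while (n_placed < recipe$n_cells && attempts_left > 0L) {
    attempts_left <- attempts_left - 1L
    cand <- data.frame(label = n_placed + 1L,
                       r = stats::runif(1, min(radii), max(radii)),
                       theta = acos(stats::runif(1, -1, 1)),
                       phi = stats::runif(1, 0, 2 * pi),
                       rho = draw_range(nucleus$r_nuclei_range))
    m <- project_sphere_surface(cand, radii, shp[2:3])
    idx <- which(m != 0L)
    if (!length(idx)) next
    if (recipe$overlap == "forbid" && any(labels[idx] != 0L)) next
    n_placed <- n_placed + 1L
    labels[idx] <- n_placed
    n_overlap[idx] <- n_overlap[idx] + 1L
    cand$n_voxels <- length(idx)
    placed[[n_placed]] <- cand
  }
  if (n_placed < recipe$n_cells)
    warning(sprintf("placed %d of %d cells before exhausting attempts",
                    n_placed, recipe$n_cells), call. = FALSE)
  st <- finalize_labels(labels, n_overlap,
                        if (n_placed) do.call(rbind, placed) else
                          data.frame(label = integer(0)))
  attr(st, "radii") <- radii
  st
}
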