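#' Nucleus shape recipe
#'
#' Parameters of the simulated nuclei: the radius range, directional
#' scaling factors of the ellipsoid (in `(s_x, s_y, s_z)` order as the
#' field prints them; each a constant or a `c(min, max)` range drawn
#' uniformly per cell), random rotation, optional B-spline deformation,
#' and the fraction of cells shrunken along two axes to mimic the
#' cylindrical post-mitotic shape.
#'
#' @param r_nuclei_range `c(min, max)` nucleus radius in voxels, or a
#'   single value.
#' @param scale list of directional scaling factors `(s_x, s_y[, s_z])`,
#'   each a constant or a `c(min, max)` uniform range.
#' @param rotate draw a random rotation per cell (angle in `(0, 2*pi)`,
#'   about a random axis in 3D)?
#' @param deform `NULL`, or `list(grid_spacing =, max_displacement =)`
#'   for the random B-spline distortion; `NA` entries are filled from
#'   the defaults `2 * r` and `0.15 * r`.
#' @param shrink_fraction fraction of cells shrunken along two axes.
#' @param shrink_factor scale multiplier applied to the two shrunken axes.
#' @param radius_rule `"fixed"` draws radii from `r_nuclei_range`;
#'   `"inverse-n"` sets the radius to
#'   `r_ref * (n_ref / n_cells)^(1/d)` so nuclei shrink as the scene
#'   gets more crowded (`d` = scene dimensionality).
#' @param r_ref,n_ref reference radius and cell count for
#'   `radius_rule = "inverse-n"`.
#' @return An object of class `"nucleus_recipe"`.
#' @export
nucleus_recipe <- function(r_nuclei_range, scale = list(1, 1, 1), rotate = TRUE,
                           deform = NULL, shrink_fraction = 0, shrink_factor = 0.5,
                           radius_rule = c("fixed", "inverse-n"),
                           r_ref = 10, n_ref = 50) {
  r_nuclei_range <- rep(r_nuclei_range, length.out = 2)
  if (any(r_nuclei_range <= 0)) stop("nucleus radii must be positive", call. = FALSE)
  if (any(unlist(scale) <= 0)) stop("scaling factors must be positive", call. = FALSE)
  if (shrink_fraction < 0 || shrink_fraction > 1)
    stop("shrink_fraction must be in [0,1]", call. = FALSE)
  structure(list(r_nuclei_range = r_nuclei_range, scale = scale, rotate = rotate,
                 deform = deform, shrink_fraction = shrink_fraction,
                 shrink_factor = shrink_factor,
                 radius_rule = match.arg(radius_rule), r_ref = r_ref, n_ref = n_ref),
            class = "nucleus_recipe")
}

#' Scene recipe
#'
#' Describes a simulated field of view: the image shape (array axis
#' order `(z,) y, x`), the foreground region-of-interest model, how many
#' cells to place and whether they may overlap.
#'
#' @param image_shape integer vector of 2 or 3 array dimensions.
#' @param roi one of `"whole-image"`, `"centered-ellipsoid"`
#'   (organism outline), `"centered-sphere-surface"` (embryo surface,
#'   rendered through [project_sphere_surface()]), or
#'   `"random-overlapping-circles"`.
#' @param n_cells number of nuclei to place.
#' @param overlap `"forbid"` (rejection sampling) or `"allow"`.
#' @param roi_fraction half-axes of the centered ROI as a fraction of the
#'   image half-extent.
#' @param n_circles,circle_r_fraction parameters of the
#'   random-overlapping-circles ROI.
#' @param n_layers number of projection layers for the sphere-surface ROI.
#' @param preset name recorded for provenance.
#' @return An object of class `"scene_recipe"`.
#' @export
scene_recipe <- function(image_shape,
                         roi = c("whole-image", "centered-ellipsoid",
                                 "centered-sphere-surface",
                                 "random-overlapping-circles"),
                         n_cells = 20, overlap = c("forbid", "allow"),
                         roi_fraction = 0.9, n_circles = 5,
                         circle_r_fraction = c(0.15, 0.35), n_layers = 13,
                         preset = "generic") {
  if (any(image_shape < 1)) stop("image_shape must be positive", call. = FALSE)
  if (n_cells < 0) stop("n_cells must be non-negative", call. = FALSE)
  structure(list(image_shape = as.integer(image_shape), roi = match.arg(roi),
                 n_cells = as.integer(n_cells), overlap = match.arg(overlap),
                 roi_fraction = roi_fraction, n_circles = n_circles,
                 circle_r_fraction = circle_r_fraction,
                 n_layers = as.integer(n_layers), preset = preset),
            class = "scene_recipe")
}

#' Per-dataset scene presets
#'
#' Named parameterizations reproducing the published simulation recipes:
#' \describe{
#'   \item{`celegans3d`}{nuclei filling a centered ellipsoidal embryo
#'     outline; radii decrease inversely proportional to the cell count;
#'     scales `(1, U(0.5, 1), 0.09)`; 10\% of cells shrunken along two
#'     axes (post-mitotic shape).}
#'   \item{`tribolium3d`}{nuclei densely positioned on a spherical embryo
#'     surface, rendered as 13 stacked equirectangular projections;
#'     radii in `(5, 6)`, scales `(1, 1, 1)`.}
#'   \item{`stemcells2d`}{whole image as ROI, non-overlapping cells,
#'     radii in `(30, 45)`, scales `(U(0.75, 1), 1)`, B-spline
#'     deformation, 0-2 dark nucleoli per cell.}
#'   \item{`hela2d`}{foreground from randomly placed overlapping circular
#'     regions, radii in `(10, 20)`, scales `(U(0.5, 1), 1)`, B-spline
#'     deformation.}
#'   \item{`generic`}{small non-overlapping blobs on a whole-image ROI;
#'     the toy-world default.}
#' }
#' Image shapes default to the published resolutions; pass `image_shape`
#' (and `n_cells`) to work at a smaller scale.
#'
#' @param name preset name.
#' @param image_shape optional override of the image shape (axis order
#'   `(z,) y, x`).
#' @param n_cells optional override of the cell count.
#' @return List with elements `scene` ([scene_recipe()]), `nucleus`
#'   ([nucleus_recipe()]) and `style` ([sketch_style()]).
#' @export
scene_preset <- function(name = c("generic", "celegans3d", "tribolium3d",
                                  "stemcells2d", "hela2d"),
                         image_shape = NULL, n_cells = NULL) {
  name <- match.arg(name)
  p <- switch(name,
    celegans3d = list(
      scene = scene_recipe(image_shape %||% c(35, 512, 708),
                           roi = "centered-ellipsoid",
                           n_cells = n_cells %||% 50, preset = name),
      nucleus = nucleus_recipe(10, scale = list(1, c(0.5, 1), 0.09),
                               radius_rule = "inverse-n", r_ref = 10, n_ref = 50,
                               shrink_fraction = 0.10),
      style = sketch_style()),
    tribolium3d = list(
      scene = scene_recipe(image_shape %||% c(13, 1700, 2450),
                           roi = "centered-sphere-surface",
                           n_cells = n_cells %||% 200, n_layers = 13,
                           preset = name),
      nucleus = nucleus_recipe(c(5, 6), scale = list(1, 1, 1)),
      style = sketch_style()),
    stemcells2d = list(
      scene = scene_recipe(image_shape %||% c(1024, 1024), roi = "whole-image",
                           n_cells = n_cells %||% 20, preset = name),
      nucleus = nucleus_recipe(c(30, 45), scale = list(c(0.75, 1), 1),
                               deform = list(grid_spacing = NA, max_displacement = NA)),
      style = sketch_style(nucleoli = list(count = c(0, 2), darkness = 0.3,
                                           radius = c(2, 4)))),
    hela2d = list(
      scene = scene_recipe(image_shape %||% c(700, 1100),
                           roi = "random-overlapping-circles",
                           n_cells = n_cells %||% 30, preset = name),
      nucleus = nucleus_recipe(c(10, 20), scale = list(c(0.5, 1), 1),
                               deform = list(grid_spacing = NA, max_displacement = NA)),
      style = sketch_style()),
    generic = list(
      scene = scene_recipe(image_shape %||% c(32, 32), roi = "whole-image",
                           n_cells = n_cells %||% 5, preset = name),
      nucleus = nucleus_recipe(c(3, 6), scale = list(1, 1), rotate = TRUE),
      style = sketch_style())
  )
  p
}

draw_range <- function(x) if (length(x) == 2) stats::runif(1, x[1], x[2]) else x

# directional scales (s_x, s_y[, s_z]) drawn per cell and reordered to
# the array axis order ((z,) y, x)
draw_scales <- function(scale, nd) {
  s <- vapply(scale[seq_len(nd)], draw_range, numeric(1))  # (x, y[, z])
  rev(s)
}

roi_mask <- function(recipe) {
  shp <- recipe$image_shape
  switch(recipe$roi,
    "whole-image" = array(TRUE, shp),
    "centered-ellipsoid" = {
      ctr <- (shp + 1) / 2
      r <- max(shp) / 2 * recipe$roi_fraction
      rasterize_ellipsoid(shp, ctr, r, scale = (shp / 2) / r * recipe$roi_fraction)
    },
    "random-overlapping-circles" = {
      out <- array(FALSE, shp)
      for (i in seq_len(recipe$n_circles)) {
        r <- stats::runif(1, recipe$circle_r_fraction[1], recipe$circle_r_fraction[2]) *
          min(shp)
        ctr <- vapply(shp, function(s) stats::runif(1, 1 + r / 2, s - r / 2),
                      numeric(1))
        out[ellipsoid_indices(shp, ctr, r)] <- TRUE
      }
      out
    },
    stop("roi model handled elsewhere", call. = FALSE))
}

#' Simulate an instance label mask
#'
#' Places `n_cells` ellipsoidal nuclei (optionally rotated, deformed and
#' partially shrunken, per the [nucleus_recipe()]) at random locations
#' inside the scene's region of interest. With `overlap = "forbid"`
#' placements are rejection-sampled until disjoint (up to `100 * n`
#' attempts; on exhaustion the scene is returned partially filled with a
#' warning). Labels are contiguous `1..N` with background 0.
#'
#' The returned mask carries attributes: `cells` (a data frame with one
#' row per placed cell: label, center, radius, shrunken flag, voxel
#' count) and `n_overlap` (an integer array counting how many cells
#' cover each voxel — needed for the overlap-darkening sketch rule).
#'
#' For `roi = "centered-sphere-surface"` the scene is built on a sphere
#' and rendered through [project_sphere_surface()]; see there for the
#' geometry.
#'
#' @param recipe a [scene_recipe()].
#' @param nucleus a [nucleus_recipe()].
#' @param seed integer seed; the scene is reproducible per seed.
#' @return Integer label array (class `"label_mask"`).
#' @export
simulate_scene <- function(recipe, nucleus, seed = NULL) {
  stopifnot(inherits(recipe, "scene_recipe"), inherits(nucleus, "nucleus_recipe"))
  with_seed(seed, {
    if (recipe$roi == "centered-sphere-surface")
      return(simulate_sphere_scene(recipe, nucleus))
    shp <- recipe$image_shape
    nd <- length(shp)
    labels <- array(0L, shp)
    n_overlap <- array(0L, shp)
    roi <- roi_mask(recipe)
    roi_idx <- which(roi)
    if (length(roi_idx) == 0) stop("empty region of interest", call. = FALSE)
    cells <- list()
    n_placed <- 0L
    attempts_left <- 100L * max(1L, recipe$n_cells)
    shrink_flags <- logical(0)
    if (recipe$n_cells > 0) {
      n_shrunk <- round(nucleus$shrink_fraction * recipe$n_cells)
      shrink_flags <- sample(rep(c(TRUE, FALSE),
                                 c(n_shrunk, recipe$n_cells - n_shrunk)))
    }
    while (n_placed < recipe$n_cells && attempts_left > 0L) {
      attempts_left <- attempts_left - 1L
      r <- switch(nucleus$radius_rule,
        "fixed" = stats::runif(1, nucleus$r_nuclei_range[1], nucleus$r_nuclei_range[2]),
        "inverse-n" = nucleus$r_ref * (nucleus$n_ref / recipe$n_cells)^(1 / nd))
      sc <- draw_scales(nucleus$scale, nd)
      shrunken <- shrink_flags[n_placed + 1L]
      if (isTRUE(shrunken)) {
        ax <- sample(nd, 2)
        sc[ax] <- sc[ax] * nucleus$shrink_factor
      }
      rot <- if (nucleus$rotate) random_rotation(nd) else NULL
      ctr_lin <- roi_idx[sample.int(length(roi_idx), 1L)]
      ctr <- arrayInd(ctr_lin, shp)[1, ]
      idx <- cell_voxels(shp, ctr, r, sc, rot, nucleus)
      if (length(idx) == 0) next
      if (recipe$overlap == "forbid" && any(labels[idx] != 0L)) next
      n_placed <- n_placed + 1L
      labels[idx] <- n_placed
      n_overlap[idx] <- n_overlap[idx] + 1L
      cells[[n_placed]] <- data.frame(label = n_placed,
                                      t(stats::setNames(ctr, paste0("c", seq_len(nd)))),
                                      r = r, shrunken = isTRUE(shrunken),
                                      n_voxels = length(idx))
    }
    if (n_placed < recipe$n_cells)
      warning(sprintf("placed %d of %d cells before exhausting attempts",
                      n_placed, recipe$n_cells), call. = FALSE)
    finalize_labels(labels, n_overlap,
                    if (n_placed) do.call(rbind, cells) else
                      data.frame(label = integer(0)))
  })
}

cell_voxels <- function(shp, ctr, r, sc, rot, nucleus) {
  if (is.null(nucleus$deform)) {
    return(ellipsoid_indices(shp, ctr, r, sc, rot))
  }
  gs <- nucleus$deform$grid_spacing
  md <- nucleus$deform$max_displacement
  if (is.null(gs) || is.na(gs)) gs <- 2 * r
  if (is.null(md) || is.na(md)) md <- 0.15 * r
  # deform in a local box around the cell, then map back
  h <- ceiling(r * max(sc) + md + 1)
  lo <- pmax(1, floor(ctr - h)); hi <- pmin(shp, ceiling(ctr + h))
  box_dim <- hi - lo + 1L
  local <- array(FALSE, box_dim)
  local[ellipsoid_indices(box_dim, ctr - lo + 1, r, sc, rot)] <- TRUE
  local <- deform_bspline(local, gs, md, seed = NULL)
  sub <- arrayInd(which(local), box_dim)
  sub <- sweep(sub, 2, lo - 1L, "+")
  as.integer(1 + (sub - 1) %*% cumprod(c(1, shp[-length(shp)])))
}

finalize_labels <- function(labels, n_overlap, cells) {
  # contiguous relabeling in case overlapping later cells erased one
  present <- sort(unique(labels[labels > 0L]))
  if (length(present) && !identical(present, seq_along(present))) {
    remap <- integer(max(present)); remap[present] <- seq_along(present)
    labels[labels > 0L] <- remap[labels[labels > 0L]]
    cells <- cells[cells$label %in% present, , drop = FALSE]
    cells$label <- remap[cells$label]
  }
  structure(labels, n_overlap = n_overlap, cells = cells, class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cells <- attr(x, "cells")
  cat(sprintf("Instance label mask %s: %d cells, %.1f%% foreground\n",
              paste(dim(x), collapse = "x"),
              if (is.null(cells)) length(setdiff(unique(as.integer(x)), 0L))
              else nrow(cells),
              100 * mean(x > 0)))
  invisible(x)
}
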