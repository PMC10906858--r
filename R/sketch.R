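#' Sketch rendering style
#'
#' Rendering rules that turn an instance label mask into a coarse
#' intensity sketch: per-cell illumination (constant or drawn uniformly
#' from a range), background level, optional intensity decay along z or
#' radially towards the organism center, optional dark nucleoli, and the
#' dimming rule for overlapping cells (10\% per additional cell by
#' default).
#'
#' @param illumination a single intensity or a `c(min, max)` range in
#'   `[0, 1]` drawn per cell.
#' @param background background intensity in `[0, 1]`.
#' @param decay `NULL`, or `list(type = "z-linear", factor = f)` (the
#'   deepest slice is scaled by `f`, the top slice is unscaled, linear in
#'   between), or `list(type = "radial", factor = f)` (intensity scaled
#'   by `f` at the image center, unscaled at the boundary).
#' @param nucleoli `NULL`, or `list(count = c(min, max), darkness = d,
#'   radius = c(min, max))`: per cell, `count` small circles of the
#'   given radius are placed inside the cell and its intensity is
#'   multiplied by `d` there (barely illuminated nucleoli).
#' @param overlap_darkening fractional dimming per additional
#'   overlapping cell; a voxel covered by `k` cells is scaled by
#'   `(1 - overlap_darkening)^(k - 1)`.
#' @return An object of class `"sketch_style"`.
#' @export
sketch_style <- function(illumination = c(0.4, 0.9), background = 0.05,
                         decay = NULL, nucleoli = NULL, overlap_darkening = 0.10) {
  if (any(illumination < 0 | illumination > 1) || background < 0 || background > 1)
    stop("intensities must be in [0,1]", call. = FALSE)
  if (overlap_darkening < 0 || overlap_darkening >= 1)
    stop("overlap_darkening must be in [0,1)", call. = FALSE)
  structure(list(illumination = illumination, background = background,
                 decay = decay, nucleoli = nucleoli,
                 overlap_darkening = overlap_darkening),
            class = "sketch_style")
}

#' Render an instance label mask into a coarse intensity sketch
#'
#' Each cell is rendered homogeneously at its illumination (drawn from
#' the style's range, or — with `mode = "mean-intensity"` — set to the
#' mean intensity of a supplied reference image within the annotated
#' region). Voxels covered by `k` overlapping cells are dimmed by
#' `(1 - overlap_darkening)^(k - 1)`; nucleoli darken small circles
#' inside cells; an optional linear intensity decay along z or towards
#' the image center is applied last. The output is in `[0, 1]` and
#' shape-aligned with the mask.
#'
#' @param labels integer instance label mask (0 = background), e.g. from
#'   [simulate_scene()].
#' @param style a [sketch_style()].
#' @param seed integer seed for the per-cell random draws.
#' @param reference reference image for `mode = "mean-intensity"`.
#' @param mode `"random"` draws per-cell illumination from the style;
#'   `"mean-intensity"` copies the mean reference intensity per cell.
#' @return Numeric array in `[0, 1]`, same shape as `labels`.
#' @export
render_sketch <- function(labels, style = sketch_style(), seed = NULL,
                          reference = NULL, mode = c("random", "mean-intensity")) {
  mode <- match.arg(mode)
  if (mode == "mean-intensity" && is.null(reference))
    stop("mean-intensity mode needs a reference image", call. = FALSE)
  if (!is.null(reference)) stop_if_shape_mismatch(labels, reference, "labels and reference")
  lab <- as.integer(labels)
  shp <- arr_dim(labels)
  n_lab <- max(lab, 0L)
  with_seed(seed, {
    illum <- if (n_lab == 0) numeric(0) else if (mode == "mean-intensity") {
      vapply(seq_len(n_lab), function(l) mean(reference[lab == l]), numeric(1))
    } else {
      vapply(seq_len(n_lab), function(l) draw_range(style$illumination), numeric(1))
    }
    img <- array(style$background, shp)
    fg <- lab > 0L
    img[fg] <- illum[lab[fg]]
    nov <- attr(labels, "n_overlap")
    if (!is.null(nov) && any(nov > 1L)) {
      k <- nov[fg]
      img[fg] <- img[fg] * (1 - style$overlap_darkening)^(pmax(k, 1L) - 1L)
    }
    if (!is.null(style$nucleoli) && n_lab > 0) {
      for (l in seq_len(n_lab)) {
        vox <- which(lab == l)
        if (!length(vox)) next
        counts <- seq(style$nucleoli$count[1], style$nucleoli$count[2])
        count <- counts[sample.int(length(counts), 1L)]
        for (j in seq_len(count)) {
          ctr <- arrayInd(vox[sample.int(length(vox), 1L)], shp)[1, ]
          r <- draw_range(style$nucleoli$radius)
          circ <- ellipsoid_indices(shp, ctr, r)
          circ <- circ[lab[circ] == l]      # keep nucleoli inside the cell
          img[circ] <- img[circ] * style$nucleoli$darkness
        }
      }
    }
    img <- apply_decay(img, style$decay)
    clip01(img)
  })
}

apply_decay <- function(img, decay) {
  if (is.null(decay)) return(img)
  shp <- arr_dim(img)
  f <- decay$factor
  if (decay$type == "z-linear") {
    if (length(shp) != 3) stop("z-linear decay needs a 3D stack", call. = FALSE)
    prof <- if (shp[1] == 1) 1 else 1 - (1 - f) * (seq_len(shp[1]) - 1) / (shp[1] - 1)
    return(img * array(prof, shp))   # z is the first (fastest) axis
  }
  if (decay$type == "radial") {
    ctr <- (shp + 1) / 2
    ax <- lapply(seq_along(shp), function(i) ((seq_len(shp[i]) - ctr[i]) / (shp[i] / 2))^2)
    d2 <- Reduce(function(a, b) outer(a, b, "+"), ax)
    rel <- sqrt(pmin(array(d2, shp), 1))
    return(img * (f + (1 - f) * rel))
  }
  stop("unknown decay type", call. = FALSE)
}

#' Render cell membranes as bright shared boundaries
#'
#' For datasets with fluorescently labeled membranes the sketch is the
#' inter-cell boundary itself: every labeled voxel with a face neighbour
#' carrying a different label (another cell or background) is set
#' bright, optionally thickened by morphological dilation, and cell
#' interiors stay at the background level. A seam between two touching
#' cells is therefore two voxels wide at `width = 1` (one voxel on each
#' side), and an isolated cell contributes its one-voxel outline.
#'
#' @param labels integer instance label mask.
#' @param width boundary thickness control (>= 1): `width - 1` rounds of
#'   face-neighbourhood dilation are applied to the base boundary.
#' @param style a [sketch_style()]; the boundary intensity is the upper
#'   end of the illumination range, interiors use the background level.
#' @return Numeric array in `[0, 1]`, same shape as `labels`.
#' @export
render_membrane_sketch <- function(labels, width = 1, style = sketch_style()) {
  if (width < 1) stop("width must be at least 1", call. = FALSE)
  lab <- array(as.integer(labels), arr_dim(labels))
  b <- boundary_voxels(lab)
  for (i in seq_len(width - 1)) b <- dilate_faces(b)
  img <- array(style$background, arr_dim(labels))
  img[b] <- max(style$illumination)
  clip01(img)
}

# voxels whose face neighbour carries a different label (foreground side)
boundary_voxels <- function(lab) {
  d <- dim(lab)
  nd <- length(d)
  b <- array(FALSE, d)
  for (ax in seq_len(nd)) {
    for (s in c(-1L, 1L)) {
      nb <- shift_array(lab, ax, s)
      b <- b | (lab > 0L & nb != lab & !is.na(nb))
    }
  }
  b
}

dilate_faces <- function(b) {
  d <- dim(b)
  out <- b
  for (ax in seq_along(d)) {
    for (s in c(-1L, 1L)) {
      nb <- shift_array(b, ax, s)
      nb[is.na(nb)] <- FALSE
      out <- out | nb
    }
  }
  out
}

# shift along axis `ax` by `s`, padding with NA
shift_array <- function(x, ax, s) {
  d <- dim(x)
  idx <- lapply(d, seq_len)
  src <- idx
  src[[ax]] <- idx[[ax]] - s
  out <- array(NA, d)
  keep <- src[[ax]] >= 1 & src[[ax]] <= d[ax]
  dst <- idx; dst[[ax]] <- idx[[ax]][keep]
  src[[ax]] <- src[[ax]][keep]
  out <- do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(x), src, list(drop = FALSE))))))
  out
}

#' Gaussian-smooth a sketch
#'
#' Applies a Gaussian filter with standard deviation `sigma` (reflective
#' boundary) to a sketch before the forward noising process; smoothing
#' prevents unnaturally sharp edges and lets the noisy sketch
#' distribution match the real-image distribution at earlier timesteps.
#' `sigma = 0` returns the sketch unchanged.
#'
#' @param sketch numeric array in `[0, 1]`.
#' @param sigma non-negative smoothing standard deviation in pixels.
#' @return Smoothed array, same shape.
#' @export
smooth_sketch <- function(sketch, sigma) {
  if (any(sigma < 0)) stop("sigma must be non-negative", call. = FALSE)
  gaussian_filter(sketch, sigma)
}
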