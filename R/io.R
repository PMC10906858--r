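#' Read and write intensity images and label masks as TIFF
#'
#' Intensity images are written as 32-bit float (default) or 16-bit
#' unsigned TIFF in `[0, 1]`; 3D volumes (and 2D+t stacks stored with
#' time on the leading axis) become multi-page TIFFs, one page per
#' slice of the first array axis. Label masks are written as 16-bit
#' unsigned TIFF, widened to 32-bit float when more than 65535 labels
#' are present, and read back as integer arrays.
#'
#' @param img numeric array in `[0, 1]` (2D or 3D).
#' @param path file path.
#' @param bits 32 (float) or 16 (unsigned) bits per sample for images.
#' @return Writers return `path` invisibly; readers return the array.
#' @name tiff_io
NULL

#' @rdname tiff_io
#' @export
write_image_tiff <- function(img, path, bits = 32) {
  if (!bits %in% c(16, 32)) stop("bits must be 16 or 32", call. = FALSE)
  pages <- as_pages(img)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' @rdname tiff_io
#' @export
read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  from_pages(pages)
}

#' @rdname tiff_io
#' @param labels integer label array (0 = background).
#' @export
write_label_tiff <- function(labels, path) {
  lab <- array(as.integer(labels), arr_dim(labels))
  mx <- max(lab, 0L)
  if (mx > 65535L) {
    # beyond 16-bit range: store raw label values as 32-bit float
    tiff::writeTIFF(as_pages(lab / 2^31), path, bits.per.sample = 32)
    attr(path, "scale") <- 2^31
  } else {
    tiff::writeTIFF(as_pages(lab / 65535), path, bits.per.sample = 16)
  }
  invisible(path)
}

#' @rdname tiff_io
#' @export
read_label_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  x <- from_pages(pages)
  # 16-bit pages come back in [0,1] at 1/65535 resolution; widened
  # (float) masks were scaled by 2^31 and miss that grid
  v16 <- x * 65535
  if (max(abs(v16 - round(v16))) < 1e-6)
    return(array(as.integer(round(v16)), arr_dim(x)))
  array(as.integer(round(x * 2^31)), arr_dim(x))
}

as_pages <- function(x) {
  d <- arr_dim(x)
  if (length(d) == 2) return(x)
  if (length(d) != 3) stop("only 2D and 3D arrays supported", call. = FALSE)
  lapply(seq_len(d[1]), function(i) array(x[i, , ], d[2:3]))
}

from_pages <- function(pages) {
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 1) return(pages[[1]])
  d <- dim(pages[[1]])
  out <- array(0, c(length(pages), d))
  for (i in seq_along(pages)) out[i, , ] <- pages[[i]]
  out
}
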