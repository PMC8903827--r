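#' 8-bit sRGB raster image
#'
#' A `raster_image` is an integer array of dimension `height x width x 3`
#' holding 8-bit sRGB channel values in \[0, 255\], row-major with the origin
#' at the top-left (row 1 = top). Pixel (x, y) in 0-based image coordinates is
#' `img[y + 1, x + 1, ]`.
#'
#' @param pixels Numeric array `h x w x 3` with values in \[0, 255\].
#' @return A `raster_image` object.
#' @export
raster_image <- function(pixels) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an h x w x 3 array")
  if (any(pixels < 0 | pixels > 255)) stop("channel values must lie in [0, 255]")
  pixels <- round(pixels)
  storage.mode(pixels) <- "integer"
  structure(pixels, class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("raster_image  %d x %d px (width x height), 8-bit sRGB\n",
              image_width(x), image_height(x)))
  invisible(x)
}

#' @rdname raster_image
#' @param img A `raster_image`.
#' @export
image_width <- function(img) dim(img)[2]

#' @rdname raster_image
#' @export
image_height <- function(img) dim(img)[1]

#' Fill a canvas with a uniform CIELAB color
#'
#' @param width,height Canvas size in pixels.
#' @param color A [lab_color()] (converted to sRGB with clipping).
#' @return A `raster_image`.
#' @export
solid_canvas <- function(width, height, color) {
  rgb <- lab_to_srgb(unclass(color))
  raster_image(array(rep(as.numeric(rgb), each = width * height),
                     dim = c(height, width, 3)))
}

#' Read / write PNG images and masks
#'
#' Images are stored as 8-bit sRGB PNG; masks as single-channel PNG with
#' values 0/255.
#'
#' @param path File path.
#' @return `read_image_png()` returns a `raster_image`; `read_mask_png()` a
#'   logical matrix.
#' @export
read_image_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3))
  raster_image(px[, , 1:3, drop = FALSE] * 255)
}

#' @rdname read_image_png
#' @param img A `raster_image` to write.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(unclass(img) / 255, target = path)
  invisible(path)
}

#' @rdname read_image_png
#' @export
read_mask_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  px > 0.5
}

#' @rdname read_image_png
#' @param mask Logical matrix to write.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, target = path)
  invisible(path)
}

# Separable area-averaging (box) resampling weights: rows of the returned
# matrix give, for each output pixel, the fractional overlap of source pixels
# under a uniform rescale n_in -> n_out. Rows sum to 1.
box_weights <- function(n_in, n_out) {
  scale <- n_in / n_out
  w <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j0 <- floor(lo) + 1L
    j1 <- min(ceiling(hi), n_in)
    for (j in j0:j1) {
      overlap <- min(hi, j) - max(lo, j - 1)
      if (overlap > 0) w[i, j] <- overlap
    }
  }
  w / scale
}

#' Resample an image by area averaging
#'
#' Exact box (pixel-area overlap) resampling, the alias-resistant choice for
#' the strong downscales used by the stimulus level table. Output is
#' re-quantized to 8 bits.
#'
#' @param img A `raster_image`.
#' @param width Target width in pixels.
#' @param height Target height; default preserves aspect ratio.
#' @return A `raster_image` of the requested size.
#' @export
resample_area <- function(img, width, height = NULL) {
  w_in <- image_width(img); h_in <- image_height(img)
  if (is.null(height)) height <- max(1L, round(h_in * width / w_in))
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L) stop("target size must be >= 1 px")
  if (width == w_in && height == h_in) return(img)
  wr <- box_weights(h_in, height)   # rows
  wc <- box_weights(w_in, width)    # columns
  out <- array(0, dim = c(height, width, 3))
  for (k in 1:3) out[, , k] <- wr %*% unclass(img)[, , k] %*% t(wc)
  raster_image(pmin(pmax(out, 0), 255))
}

# Resample a logical mask consistently with resample_area: area-average the
# 0/1 field, then threshold at 0.5.
resample_mask <- function(mask, width, height = NULL) {
  h_in <- nrow(mask); w_in <- ncol(mask)
  if (is.null(height)) height <- max(1L, round(h_in * width / w_in))
  if (width == w_in && height == h_in) return(mask)
  box_weights(h_in, height) %*% (mask * 1) %*% t(box_weights(w_in, width)) >= 0.5
}

# Convert an image to an n x 3 pixel matrix and back. Pixel order is R's
# column-major matrix order, matching as.vector() on an aligned mask.
pixels_of <- function(img) {
  d <- dim(img)
  matrix(as.numeric(aperm(unclass(img), c(3, 1, 2))), ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("R", "G", "B")))
}

image_from_pixels <- function(px, height, width) {
  raster_image(aperm(array(t(px), dim = c(3, height, width)), c(2, 3, 1)))
}
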