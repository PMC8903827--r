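#' Stimulus level table
#'
#' The seven joint size-and-brightness degradation levels. Width is the image
#' width a 400-px-wide original is rescaled to; brightness is the multiplier
#' applied to every sRGB channel. L1 is the original; L4 is the smallest and
#' most shaded; half levels are the intermediates used by the adaptive
#' chimpanzee sessions.
#'
#' @return A data frame with columns `level`, `width_px`, `brightness_fraction`.
#' @export
stimulus_levels <- function() {
  data.frame(level = c(1, 1.5, 2, 2.5, 3, 3.5, 4),
             width_px = c(400L, 300L, 200L, 150L, 100L, 75L, 50L),
             brightness_fraction = c(1.00, 0.75, 0.50, 0.42, 0.33, 0.29, 0.25))
}

level_row <- function(level) {
  tab <- stimulus_levels()
  i <- match(level, tab$level)
  if (is.na(i)) stop("unknown stimulus level: ", level)
  tab[i, ]
}

#' Apply a stimulus level to an image
#'
#' Rescales the image width to the level's table width (aspect preserved,
#' area-averaging resampling) and multiplies every sRGB channel by the level's
#' brightness fraction, re-quantizing to 8 bits. Level 1 is the identity.
#'
#' @param img A `raster_image` at original (L1) scale, i.e. 400 px wide.
#' @param level One of 1, 1.5, 2, 2.5, 3, 3.5, 4.
#' @param brightness_space `"srgb"` multiplies the stored 8-bit channels
#'   (image-editor semantics, the default); `"linear"` scales linearized
#'   intensities instead.
#' @return A `raster_image`.
#' @export
apply_level <- function(img, level, brightness_space = c("srgb", "linear")) {
  brightness_space <- match.arg(brightness_space)
  row <- level_row(level)
  if (row$level == 1) return(img)
  out <- resample_area(img, row$width_px)
  f <- row$brightness_fraction
  px <- unclass(out)
  if (brightness_space == "srgb") {
    px <- px * f
  } else {
    lin <- srgb_decode(px / 255) * f
    px <- srgb_encode(lin) * 255
  }
  raster_image(pmin(pmax(px, 0), 255))
}

# sRGB transfer functions (IEC 61966-2-1), used by the linear brightness path
srgb_decode <- function(v) ifelse(v <= 0.04045, v / 12.92,
                                  ((v + 0.055) / 1.055)^2.4)
srgb_encode <- function(v) ifelse(v <= 0.0031308, 12.92 * v,
                                  1.055 * v^(1 / 2.4) - 0.055)

#' Reverse the contrast polarity of the eyeball region
#'
#' Inverts the CIELAB lightness component (L -> 100 - L) of every pixel inside
#' the eyeball mask while leaving chromaticity (a, b) unchanged, then converts
#' back to sRGB with gamut clipping. Pixels outside the mask are untouched.
#' This turns a light-sclera/dark-iris (positive polarity) eye into a
#' dark-sclera/light-iris (negative polarity) eye and vice versa, without
#' changing the iris-sclera color difference.
#'
#' @param img A `raster_image`.
#' @param eyeball_mask Logical matrix aligned with `img`.
#' @param mode `"lab"` (default) inverts CIELAB L; `"grayscale"` inverts the
#'   8-bit luma component instead, leaving chromatic differences R-Y, B-Y
#'   unchanged.
#' @return A `raster_image` with the polarity of the masked region reversed.
#' @export
reverse_polarity <- function(img, eyeball_mask, mode = c("lab", "grayscale")) {
  mode <- match.arg(mode)
  if (!identical(dim(eyeball_mask), dim(img)[1:2]))
    stop("mask and image dimensions differ")
  sel <- as.vector(eyeball_mask)
  if (!any(sel)) return(img)
  px <- pixels_of(img)
  if (mode == "lab") {
    lab <- srgb_to_lab(px[sel, , drop = FALSE])
    lab[, "L"] <- 100 - lab[, "L"]
    px[sel, ] <- lab_to_srgb(lab)
  } else {
    p <- px[sel, , drop = FALSE]
    luma <- p %*% c(0.299, 0.587, 0.114)
    px[sel, ] <- pmin(pmax(p + as.vector(255 - 2 * luma), 0), 255)
  }
  image_from_pixels(px, image_height(img), image_width(img))
}

#' Normalize a stimulus by iris diameter
#'
#' Uniformly rescales the image (and masks) so the horizontal extent of the
#' iris mask equals `target_iris_px`, the size standard all stimuli share so
#' that eye shape and sclera exposure are compared independently of absolute
#' image scale.
#'
#' @param img A `raster_image`.
#' @param masks An [roi_masks()] aligned with `img`.
#' @param target_iris_px Target iris diameter, default 16.
#' @return A list with rescaled `image` and `masks`.
#' @export
normalize_by_iris <- function(img, masks, target_iris_px = 16) {
  d <- mask_width(masks$iris_mask)
  if (d == 0) stop("iris mask is empty")
  scale <- target_iris_px / d
  new_w <- max(1L, round(image_width(img) * scale))
  new_h <- max(1L, round(image_height(img) * scale))
  iris <- resample_mask(masks$iris_mask, new_w, new_h)
  sclera <- resample_mask(masks$sclera_mask, new_w, new_h)
  eyeball <- resample_mask(masks$eyeball_mask, new_w, new_h)
  # re-impose mask consistency at resampled boundaries
  iris <- iris & eyeball
  sclera <- sclera & eyeball & !iris
  list(image = resample_area(img, new_w, new_h),
       masks = roi_masks(iris, sclera, eyeball))
}

#' Crop the eye region to a 4:1 rectangle
#'
#' Returns a window with 4:1 aspect ratio centered on the eyeball mask,
#' padded with the background color where it exceeds the canvas. With
#' `width = NULL` the window is the minimal 4:1 rectangle containing the
#' eyeball mask; passing `width = 400` on a 400 x 400 face reproduces the
#' 400 x 100 eye-region format used for the visual-search task.
#'
#' @param img A `raster_image`.
#' @param masks An [roi_masks()] aligned with `img`.
#' @param width Window width in px, or `NULL` for the minimal containing
#'   window.
#' @param background Pad color as a [lab_color()]; default 50\% gray.
#' @return A list with cropped `image` and `masks`.
#' @export
crop_eye_region <- function(img, masks, width = NULL,
                            background = lab_color(53.585, 0, 0)) {
  m <- masks$eyeball_mask
  if (!any(m)) stop("eyeball mask is empty")
  rows <- range(which(rowSums(m) > 0))
  cols <- range(which(colSums(m) > 0))
  bb_w <- diff(cols) + 1L
  bb_h <- diff(rows) + 1L
  if (is.null(width)) width <- max(bb_w, 4L * bb_h)
  width <- as.integer(width)
  height <- as.integer(ceiling(width / 4))
  ccx <- mean(cols); ccy <- mean(rows)
  x0 <- round(ccx - (width - 1) / 2)
  y0 <- round(ccy - (height - 1) / 2)
  xs <- x0:(x0 + width - 1L)
  ys <- y0:(y0 + height - 1L)

  bg <- as.numeric(lab_to_srgb(unclass(background)))
  out <- array(rep(bg, each = width * height), dim = c(height, width, 3))
  inx <- xs >= 1 & xs <= ncol(m)
  iny <- ys >= 1 & ys <= nrow(m)
  out[iny, inx, ] <- unclass(img)[ys[iny], xs[inx], , drop = FALSE]
  crop_mask <- function(mk) {
    o <- matrix(FALSE, height, width)
    o[iny, inx] <- mk[ys[iny], xs[inx], drop = FALSE]
    o
  }
  list(image = raster_image(out),
       masks = roi_masks(crop_mask(masks$iris_mask),
                         crop_mask(masks$sclera_mask),
                         crop_mask(masks$eyeball_mask)))
}

mask_width <- function(mask) {
  cs <- which(colSums(mask) > 0)
  if (length(cs) == 0) 0L else diff(range(cs)) + 1L
}

mask_height <- function(mask) {
  rs <- which(rowSums(mask) > 0)
  if (length(rs) == 0) 0L else diff(range(rs)) + 1L
}

#' Measure ROI colorimetry and eye shape
#'
#' Computes, for a stimulus image and its ROI masks, the mean CIELAB color of
#' the iris and sclera ROIs, their Euclidean color difference (delta E), and
#' eye-shape metrics (horizontal and vertical extents of the eye opening,
#' width/height ratio, ROI pixel areas).
#'
#' @param img A `raster_image`.
#' @param masks An [roi_masks()] aligned with `img`.
#' @return A `colorimetry_report` list with elements `iris_mean`,
#'   `sclera_mean` (CIELAB triples), `iris_sclera_difference`, `eye_width_px`,
#'   `eye_height_px`, `width_height_ratio`, `iris_area_px`, `sclera_area_px`.
#' @export
measure_colorimetry <- function(img, masks) {
  if (!any(masks$iris_mask)) stop("iris ROI is empty")
  if (!any(masks$sclera_mask)) stop("sclera ROI is empty")
  px <- pixels_of(img)
  roi_mean <- function(mask) colMeans(srgb_to_lab(px[as.vector(mask), , drop = FALSE]))
  iris_mean <- roi_mean(masks$iris_mask)
  sclera_mean <- roi_mean(masks$sclera_mask)
  structure(list(
    iris_mean = iris_mean,
    sclera_mean = sclera_mean,
    iris_sclera_difference = as.numeric(delta_e(iris_mean, sclera_mean)),
    eye_width_px = mask_width(masks$eyeball_mask),
    eye_height_px = mask_height(masks$eyeball_mask),
    width_height_ratio = mask_width(masks$eyeball_mask) /
      mask_height(masks$eyeball_mask),
    iris_area_px = sum(masks$iris_mask),
    sclera_area_px = sum(masks$sclera_mask)),
    class = "colorimetry_report")
}

#' @export
print.colorimetry_report <- function(x, ...) {
  cat(sprintf("iris  mean Lab: %6.2f %6.2f %6.2f   (area %d px)\n",
              x$iris_mean[1], x$iris_mean[2], x$iris_mean[3], x$iris_area_px))
  cat(sprintf("sclera mean Lab: %6.2f %6.2f %6.2f   (area %d px)\n",
              x$sclera_mean[1], x$sclera_mean[2], x$sclera_mean[3],
              x$sclera_area_px))
  cat(sprintf("iris-sclera delta E: %.2f\n", x$iris_sclera_difference))
  cat(sprintf("eye opening: %d x %d px (ratio %.2f)\n",
              x$eye_width_px, x$eye_height_px, x$width_height_ratio))
  invisible(x)
}

#' @rdname measure_colorimetry
#' @param report A `colorimetry_report`.
#' @return `colorimetry_as_row()` returns a one-row data frame suitable for
#'   CSV export.
#' @export
colorimetry_as_row <- function(report) {
  data.frame(iris_L = report$iris_mean[1], iris_a = report$iris_mean[2],
             iris_b = report$iris_mean[3],
             sclera_L = report$sclera_mean[1], sclera_a = report$sclera_mean[2],
             sclera_b = report$sclera_mean[3],
             iris_sclera_difference = report$iris_sclera_difference,
             eye_width_px = report$eye_width_px,
             eye_height_px = report$eye_height_px,
             width_height_ratio = report$width_height_ratio,
             iris_area_px = report$iris_area_px,
             sclera_area_px = report$sclera_area_px,
             row.names = NULL)
}
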