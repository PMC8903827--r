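#' CIELAB color constructor
#'
#' A `lab_color` is a named numeric vector `c(L, a, b)` in CIELAB (D65 white,
#' 2 degree observer): `L` is lightness in \[0, 100\], `a` and `b` are the
#' green-red and blue-yellow opponent axes.
#'
#' @param L Lightness, 0-100.
#' @param a Green-red opponent component.
#' @param b Blue-yellow opponent component.
#' @return A `lab_color` object (named numeric vector of length 3).
#' @examples
#' lab_color(50, 0, 0)
#' @export
lab_color <- function(L, a = 0, b = 0) {
  stopifnot(is.numeric(L), is.numeric(a), is.numeric(b))
  if (L < 0 || L > 100) stop("L must lie in [0, 100]")
  structure(c(L = L, a = a, b = b), class = "lab_color")
}

#' @export
print.lab_color <- function(x, ...) {
  cat(sprintf("CIELAB  L* = %.2f  a* = %.2f  b* = %.2f\n", x[1], x[2], x[3]))
  invisible(x)
}

#' Convert 8-bit sRGB to CIELAB
#'
#' Standard sRGB -> CIELAB conversion under the D65 white point and the
#' 2 degree standard observer.
#'
#' @param rgb Numeric vector of length 3 (one pixel) or an n x 3 matrix of
#'   8-bit sRGB values in \[0, 255\].
#' @return An n x 3 matrix with columns `L`, `a`, `b` (a vector input returns
#'   a 1 x 3 matrix).
#' @seealso [lab_to_srgb()], [delta_e()]
#' @export
srgb_to_lab <- function(rgb) {
  rgb <- rbind_pixels(rgb)
  if (any(rgb < 0 | rgb > 255)) stop("sRGB channels must lie in [0, 255]")
  lab <- grDevices::convertColor(rgb / 255, from = "sRGB", to = "Lab")
  colnames(lab) <- c("L", "a", "b")
  lab
}

#' Convert CIELAB to 8-bit sRGB with gamut clipping
#'
#' Inverse of [srgb_to_lab()]. Out-of-gamut colors are clipped channel-wise to
#' \[0, 255\]; the `clipped` attribute on the result reports whether any pixel
#' needed clipping.
#'
#' @param lab Numeric vector of length 3 or an n x 3 matrix of CIELAB values.
#' @return An n x 3 integer matrix of sRGB channels in \[0, 255\], with a
#'   logical attribute `clipped`.
#' @export
lab_to_srgb <- function(lab) {
  lab <- rbind_pixels(lab)
  srgb <- grDevices::convertColor(lab, from = "Lab", to = "sRGB", clip = NA)
  # clip = NA marks out-of-gamut rows as NA so clipping can be reported
  clipped <- anyNA(srgb)
  if (clipped) {
    srgb2 <- grDevices::convertColor(lab, from = "Lab", to = "sRGB", clip = TRUE)
    srgb[is.na(srgb)] <- srgb2[is.na(srgb)]
  }
  out <- round(pmin(pmax(srgb * 255, 0), 255))
  storage.mode(out) <- "integer"
  colnames(out) <- c("R", "G", "B")
  attr(out, "clipped") <- clipped
  out
}

#' CIELAB Euclidean color difference (delta E)
#'
#' @param lab1,lab2 CIELAB triples (vectors of length 3 or n x 3 matrices).
#' @return Numeric vector of Euclidean distances sqrt(dL^2 + da^2 + db^2).
#' @export
delta_e <- function(lab1, lab2) {
  lab1 <- rbind_pixels(lab1)
  lab2 <- rbind_pixels(lab2)
  sqrt(rowSums((lab1 - lab2)^2))
}

# accept a length-3 vector or n x 3 matrix, always return a matrix
rbind_pixels <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop("expected a pixel triple or an n x 3 matrix")
    x <- matrix(as.numeric(x), ncol = 3L)
  }
  if (ncol(x) != 3L) stop("expected an n x 3 matrix")
  storage.mode(x) <- "double"
  unclass(x)
}
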