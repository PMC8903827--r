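#' Eye stimulus geometry
#'
#' Parametric geometry of a rendered eye stimulus on a square canvas. The eye
#' opening is an ellipse; the iris is a disc clipped to the opening, with a
#' concentric pupil. Averted gaze displaces the iris horizontally by
#' `shift_px`; the uncovered opening remains sclera-colored. The default
#' 6 px shift of a 16 px iris corresponds to an eyeball rotation of about 20
#' degrees, i.e. an eyeball radius of 6 / sin(20 deg) ~ 17.54 px.
#'
#' @param canvas_px Square canvas side, default 400.
#' @param iris_diameter_px Iris diameter, default 16 (the normalization
#'   standard all stimuli are scaled to).
#' @param pupil_diameter_px Pupil diameter, default 7.
#' @param eye_outline_semiaxes_px Numeric length 2: horizontal and vertical
#'   half-widths of the elliptical eye opening.
#' @param eyeball_radius_px Modeled eyeball radius; default `6 / sin(20*pi/180)`.
#' @param gaze One of `"left"`, `"front"`, `"right"` (viewer's perspective).
#' @param shift_px Horizontal iris displacement for averted gaze, default 6.
#' @param species_tag `"human-like"` or `"chimpanzee-like"` (human-like eyes
#'   are horizontally more elongated).
#' @return An `eye_geometry` list.
#' @seealso [gaze_shift_for_angle()] for the rotation-angle parameterization
#'   used by the training stages.
#' @export
eye_geometry <- function(canvas_px = 400,
                         iris_diameter_px = 16,
                         pupil_diameter_px = 7,
                         eye_outline_semiaxes_px = c(30, 10),
                         eyeball_radius_px = 6 / sin(20 * pi / 180),
                         gaze = c("front", "left", "right"),
                         shift_px = 6,
                         species_tag = c("human-like", "chimpanzee-like")) {
  gaze <- match.arg(gaze)
  species_tag <- match.arg(species_tag)
  if (iris_diameter_px > 2 * eye_outline_semiaxes_px[1])
    stop("iris_diameter_px must not exceed the horizontal eye-opening width")
  if (shift_px < 0) stop("shift_px must be >= 0")
  if (shift_px > eyeball_radius_px)
    stop("shift_px cannot exceed the eyeball radius")
  if (pupil_diameter_px >= iris_diameter_px)
    stop("pupil must be smaller than the iris")
  structure(list(canvas_px = canvas_px,
                 iris_diameter_px = iris_diameter_px,
                 pupil_diameter_px = pupil_diameter_px,
                 eye_outline_semiaxes_px = eye_outline_semiaxes_px,
                 eyeball_radius_px = eyeball_radius_px,
                 gaze = gaze, shift_px = shift_px,
                 species_tag = species_tag),
            class = "eye_geometry")
}

#' Horizontal iris shift for a given eyeball rotation
#'
#' Maps an eyeball rotation angle to the on-screen horizontal displacement of
#' the iris, `round(r * sin(theta))` with `r` the eyeball radius. At the
#' default radius the 20 degree test gaze gives 6 px; the 38 and 30 degree
#' training gazes give about 11 and 9 px.
#'
#' @param theta_deg Rotation angle in degrees.
#' @param eyeball_radius_px Eyeball radius, default `6 / sin(20*pi/180)`.
#' @return Integer pixel shift.
#' @export
gaze_shift_for_angle <- function(theta_deg,
                                 eyeball_radius_px = 6 / sin(20 * pi / 180)) {
  as.integer(round(eyeball_radius_px * sin(theta_deg * pi / 180)))
}

#' Eye stimulus appearance
#'
#' CIELAB colors of the stimulus regions. The presets capture the two study
#' species: human-like eyes have a uniformly white (high-L) sclera and a
#' darker iris (positive contrast polarity); chimpanzee-like eyes have a
#' uniformly dark sclera and a brighter iris (negative polarity).
#'
#' @param iris_color,sclera_color,pupil_color,skin_color [lab_color()] values.
#' @param background Canvas background; default 50\% gray, sRGB (128,128,128).
#' @return An `eye_appearance` list.
#' @export
eye_appearance <- function(iris_color, sclera_color, pupil_color, skin_color,
                           background = lab_color(53.585, 0, 0)) {
  cols <- list(iris_color = iris_color, sclera_color = sclera_color,
               pupil_color = pupil_color, skin_color = skin_color,
               background = background)
  for (nm in names(cols)) {
    cl <- cols[[nm]]
    if (length(cl) != 3L || cl[1] < 0 || cl[1] > 100)
      stop(nm, " must be a CIELAB triple with L in [0, 100]")
  }
  structure(cols, class = "eye_appearance")
}

#' @rdname eye_appearance
#' @param species `"human"` or `"chimpanzee"`.
#' @export
appearance_preset <- function(species = c("human", "chimpanzee")) {
  species <- match.arg(species)
  if (species == "human") {
    eye_appearance(iris_color   = lab_color(40, 9, 14),
                   sclera_color = lab_color(90, 1, 4),
                   pupil_color  = lab_color(12, 2, 2),
                   skin_color   = lab_color(65, 12, 16))
  } else {
    eye_appearance(iris_color   = lab_color(65, 10, 25),
                   sclera_color = lab_color(18, 6, 8),
                   pupil_color  = lab_color(10, 2, 3),
                   skin_color   = lab_color(40, 8, 10))
  }
}

#' @rdname eye_geometry
#' @param species `"human"` or `"chimpanzee"`.
#' @inheritParams eye_geometry
#' @export
geometry_preset <- function(species = c("human", "chimpanzee"),
                            gaze = "front", canvas_px = 400) {
  species <- match.arg(species)
  if (species == "human")
    eye_geometry(canvas_px = canvas_px, eye_outline_semiaxes_px = c(30, 10),
                 gaze = gaze, species_tag = "human-like")
  else
    eye_geometry(canvas_px = canvas_px, eye_outline_semiaxes_px = c(22, 10),
                 gaze = gaze, species_tag = "chimpanzee-like")
}

#' Region-of-interest masks for an eye stimulus
#'
#' @param iris_mask,sclera_mask,eyeball_mask Logical matrices aligned with the
#'   stimulus image. Iris and sclera are disjoint and both lie inside the
#'   eyeball (eye-opening) mask; the pupil belongs to none of iris/sclera.
#' @return An `roi_masks` list.
#' @export
roi_masks <- function(iris_mask, sclera_mask, eyeball_mask) {
  if (!identical(dim(iris_mask), dim(sclera_mask)) ||
      !identical(dim(iris_mask), dim(eyeball_mask)))
    stop("masks must share dimensions")
  if (any(iris_mask & sclera_mask)) stop("iris and sclera masks overlap")
  if (any((iris_mask | sclera_mask) & !eyeball_mask))
    stop("iris/sclera masks must lie inside the eyeball mask")
  structure(list(iris_mask = iris_mask, sclera_mask = sclera_mask,
                 eyeball_mask = eyeball_mask), class = "roi_masks")
}

#' Render a parametric eye stimulus
#'
#' Deterministically renders a single eye on a skin-colored elliptical face
#' patch over the gray background, and returns the image together with
#' pixel-aligned iris/sclera/eyeball ROI masks. For averted gaze the iris
#' (and pupil) center is displaced horizontally by `geometry$shift_px`; the
#' opening it uncovers stays sclera-colored, emulating the sclera-fill used
#' when photographic eyes are shifted.
#'
#' @param geometry An [eye_geometry()].
#' @param appearance An [eye_appearance()].
#' @return A list with elements `image` ([raster_image()]) and `masks`
#'   ([roi_masks()]).
#' @examples
#' stim <- render_eye_stimulus(geometry_preset("human"),
#'                             appearance_preset("human"))
#' sum(stim$masks$iris_mask)
#' @export
render_eye_stimulus <- function(geometry, appearance) {
  stopifnot(inherits(geometry, "eye_geometry"),
            inherits(appearance, "eye_appearance"))
  n <- geometry$canvas_px
  cx <- (n - 1) / 2
  cy <- (n - 1) / 2
  x <- matrix(rep(0:(n - 1), each = n), n, n)   # column index (x), 0-based
  y <- matrix(rep(0:(n - 1), times = n), n, n)  # row index (y), 0-based

  a <- geometry$eye_outline_semiaxes_px[1]
  b <- geometry$eye_outline_semiaxes_px[2]
  opening <- ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1

  shift <- switch(geometry$gaze, front = 0,
                  left = -geometry$shift_px, right = geometry$shift_px)
  ix <- cx + shift
  r_iris <- geometry$iris_diameter_px / 2
  r_pupil <- geometry$pupil_diameter_px / 2
  iris_disc <- (x - ix)^2 + (y - cy)^2 <= r_iris^2
  pupil_disc <- (x - ix)^2 + (y - cy)^2 <= r_pupil^2

  iris <- iris_disc & opening & !pupil_disc
  pupil <- pupil_disc & opening
  sclera <- opening & !iris_disc
  # face patch: ellipse comfortably larger than the opening, clipped to canvas
  face <- ((x - cx) / (a * 3))^2 + ((y - cy) / (b * 6))^2 <= 1

  colors <- vapply(appearance, function(cl) as.numeric(lab_to_srgb(unclass(cl))),
                   numeric(3))
  img <- array(0, dim = c(n, n, 3))
  for (k in 1:3) {
    plane <- matrix(colors[k, "background"], n, n)
    plane[face] <- colors[k, "skin_color"]
    plane[sclera] <- colors[k, "sclera_color"]
    plane[iris] <- colors[k, "iris_color"]
    plane[pupil] <- colors[k, "pupil_color"]
    img[, , k] <- plane
  }
  list(image = raster_image(img),
       masks = roi_masks(iris, sclera, opening))
}
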