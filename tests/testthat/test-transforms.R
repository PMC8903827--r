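test_that("the level table holds the seven width/brightness pairs", {
  tab <- stimulus_levels()
  expect_equal(tab$level, c(1, 1.5, 2, 2.5, 3, 3.5, 4))
  expect_equal(tab$width_px, c(400L, 300L, 200L, 150L, 100L, 75L, 50L))
  expect_equal(tab$brightness_fraction,
               c(1.00, 0.75, 0.50, 0.42, 0.33, 0.29, 0.25))
  expect_true(all(diff(tab$width_px) < 0))
  expect_true(all(diff(tab$brightness_fraction) < 0))
})

test_that("apply_level rescales width per the table and L1 is the identity", {
  img <- fixture_stim("human")$image
  expect_identical(unclass(apply_level(img, 1)), unclass(img))
  expect_equal(image_width(apply_level(img, 4)), 50)
  expect_equal(image_width(apply_level(img, 2.5)), 150)
  expect_equal(image_width(apply_level(img, 3.5)), 75)
  expect_error(apply_level(img, 5), "unknown stimulus level")
})

test_that("mean luminance decreases strictly from L1 to L4", {
  img <- fixture_stim("chimpanzee")$image
  lum <- vapply(c(1, 2, 3, 4), function(lv) {
    px <- gazevis:::pixels_of(apply_level(img, lv))
    mean(srgb_to_lab(px)[, "L"])
  }, numeric(1))
  expect_true(all(diff(lum) < 0))
})

test_that("brightness scaling multiplies sRGB channels by the table fraction", {
  img <- solid_canvas(8, 8, lab_color(80))
  v <- unclass(img)[1, 1, 1]
  out <- apply_level(img, 2)  # width 200 irrelevant for a solid canvas
  expect_true(all(abs(unclass(out) - round(v * 0.5)) <= 1))
  lin <- apply_level(img, 2, brightness_space = "linear")
  expect_true(all(unclass(lin) >= unclass(out)))  # gamma-encoded halving is lighter
})

test_that("polarity reversal is an involution within quantization", {
  for (sp in c("human", "chimpanzee")) {
    stim <- fixture_stim(sp)
    rev1 <- reverse_polarity(stim$image, stim$masks$eyeball_mask)
    rev2 <- reverse_polarity(rev1, stim$masks$eyeball_mask)
    sel <- as.vector(stim$masks$eyeball_mask)
    d <- delta_e(srgb_to_lab(gazevis:::pixels_of(stim$image)[sel, ]),
                 srgb_to_lab(gazevis:::pixels_of(rev2)[sel, ]))
    expect_lte(max(d), 1)
    # pixels outside the mask are bit-identical
    px_out <- gazevis:::pixels_of(stim$image)[!sel, ]
    expect_identical(gazevis:::pixels_of(rev1)[!sel, ], px_out)
  }
})

test_that("reversal maps L to 100 - L and preserves chromaticity", {
  stim <- fixture_stim("human")
  rev <- reverse_polarity(stim$image, stim$masks$eyeball_mask)
  sel <- as.vector(stim$masks$sclera_mask)
  lab0 <- srgb_to_lab(gazevis:::pixels_of(stim$image)[sel, ])
  lab1 <- srgb_to_lab(gazevis:::pixels_of(rev)[sel, ])
  # near-white sclera (L ~ 90) becomes near-black (L ~ 10)
  expect_equal(mean(lab1[, "L"]), 100 - mean(lab0[, "L"]), tolerance = 0.5)
  sel_eye <- as.vector(stim$masks$eyeball_mask)
  a0 <- srgb_to_lab(gazevis:::pixels_of(stim$image)[sel_eye, ])
  a1 <- srgb_to_lab(gazevis:::pixels_of(rev)[sel_eye, ])
  expect_lte(mean(abs(a1[, "a"] - a0[, "a"])), 1)
  expect_lte(mean(abs(a1[, "b"] - a0[, "b"])), 1)
})

test_that("reversal preserves the iris-sclera color difference", {
  for (sp in c("human", "chimpanzee")) {
    stim <- fixture_stim(sp)
    rev <- reverse_polarity(stim$image, stim$masks$eyeball_mask)
    d0 <- measure_colorimetry(stim$image, stim$masks)$iris_sclera_difference
    d1 <- measure_colorimetry(rev, stim$masks)$iris_sclera_difference
    expect_lte(abs(d0 - d1), 0.5)
  }
})

test_that("grayscale-mode reversal also inverts polarity in the mask", {
  stim <- fixture_stim("human")
  rev <- reverse_polarity(stim$image, stim$masks$eyeball_mask,
                          mode = "grayscale")
  rep0 <- measure_colorimetry(stim$image, stim$masks)
  rep1 <- measure_colorimetry(rev, stim$masks)
  expect_gt(rep0$sclera_mean["L"], rep0$iris_mean["L"])
  expect_lt(rep1$sclera_mean["L"], rep1$iris_mean["L"])
})

test_that("normalize_by_iris rescales to the target iris extent", {
  stim <- fixture_stim("human")
  # doubled geometry renders at twice the scale; normalization restores it
  big_geom <- eye_geometry(canvas_px = 400, iris_diameter_px = 32,
                           pupil_diameter_px = 14,
                           eye_outline_semiaxes_px = c(60, 20))
  big <- render_eye_stimulus(big_geom, appearance_preset("human"))
  norm <- normalize_by_iris(big$image, big$masks)
  expect_lte(abs(gazevis:::mask_width(norm$masks$iris_mask) - 16), 1)
  expect_equal(image_width(norm$image), 200)  # scale factor 0.5
  ref <- measure_colorimetry(stim$image, stim$masks)
  got <- measure_colorimetry(norm$image, norm$masks)
  expect_lt(abs(got$iris_area_px - ref$iris_area_px) / ref$iris_area_px, 0.10)
  expect_lt(abs(got$sclera_area_px - ref$sclera_area_px) / ref$sclera_area_px,
            0.10)
  # already-normalized input is untouched
  same <- normalize_by_iris(stim$image, stim$masks)
  expect_identical(unclass(same$image), unclass(stim$image))
})

test_that("crop_eye_region produces a containing, idempotent 4:1 window", {
  stim <- fixture_stim("chimpanzee", "right")
  crop <- crop_eye_region(stim$image, stim$masks)
  expect_equal(image_width(crop$image), 4 * image_height(crop$image))
  expect_equal(sum(crop$masks$eyeball_mask), sum(stim$masks$eyeball_mask))
  again <- crop_eye_region(crop$image, crop$masks)
  expect_identical(unclass(again$image), unclass(crop$image))
  # the face-scale window: 400 px wide gives the 400 x 100 format
  wide <- crop_eye_region(stim$image, stim$masks, width = 400)
  expect_equal(dim(unclass(wide$image))[1:2], c(100L, 400L))
})
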