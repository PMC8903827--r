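# Shared fixtures, built once per test run. Rendering is deterministic, so
# these are safe to reuse across test files.

fixture_stim <- local({
  cache <- new.env(parent = emptyenv())
  function(species = "human", gaze = "front") {
    key <- paste(species, gaze, sep = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <- render_eye_stimulus(
        geometry_preset(species, gaze = gaze),
        appearance_preset(species))
    cache[[key]]
  }
})

mask_centroid_x <- function(mask) mean(which(mask, arr.ind = TRUE)[, 2])
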