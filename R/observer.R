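#' Generative observer parameters
#'
#' Parameters of the logistic observer that generates trial-level correct /
#' incorrect responses. Fixed effects are on the logit scale under treatment
#' coding with reference levels chimpanzee species, the lowest level present,
#' and normal polarity — the same coding the fitted models use. Random
#' variation enters as uncorrelated centered-normal draws: a participant
#' intercept plus optional participant slopes for each fixed factor, and a
#' stimulus-individual intercept. The success probability of a trial is
#'
#'   p = g + (1 - g - lambda) * plogis(eta)
#'
#' with guessing floor `g` (default 1/3, the three-alternative chance rate)
#' and lapse rate `lambda`.
#'
#' @param intercept Logit-scale intercept (reference cell).
#' @param species Effect of the human-stimulus condition.
#' @param level Named vector of level effects relative to the lowest level in
#'   the plan, e.g. `c(L2 = -0.5, L3 = -1, L4 = -2)`; levels absent from the
#'   plan are ignored.
#' @param polarity Effect of reversed polarity.
#' @param species_level,species_polarity,level_polarity,species_level_polarity
#'   Interaction effects; the level-indexed ones are named vectors like
#'   `level`.
#' @param sd_participant Participant random-intercept SD.
#' @param sd_participant_slopes Named vector of participant random-slope SDs
#'   for `species`, `polarity`, `level` (one SD shared across level dummies).
#' @param sd_stimulus Stimulus-individual random-intercept SD.
#' @param guess Guessing floor g in \[0, 1), default 1/3.
#' @param lapse Lapse rate lambda in \[0, 0.1\].
#' @return An `observer_params` list.
#' @seealso [observer_presets()], [simulate_responses()]
#' @export
observer_params <- function(intercept = 0, species = 0, level = numeric(0),
                            polarity = 0,
                            species_level = numeric(0), species_polarity = 0,
                            level_polarity = numeric(0),
                            species_level_polarity = numeric(0),
                            sd_participant = 0,
                            sd_participant_slopes = c(species = 0, polarity = 0,
                                                      level = 0),
                            sd_stimulus = 0,
                            guess = 1 / 3, lapse = 0) {
  if (guess < 0 || guess >= 1) stop("guess must lie in [0, 1)")
  if (lapse < 0 || lapse > 0.1) stop("lapse must lie in [0, 0.1]")
  if (sd_participant < 0 || sd_stimulus < 0 || any(sd_participant_slopes < 0))
    stop("random-effect SDs must be >= 0")
  slopes <- c(species = 0, polarity = 0, level = 0)
  slopes[names(sd_participant_slopes)] <- sd_participant_slopes
  structure(list(intercept = intercept, species = species, level = level,
                 polarity = polarity, species_level = species_level,
                 species_polarity = species_polarity,
                 level_polarity = level_polarity,
                 species_level_polarity = species_level_polarity,
                 sd_participant = sd_participant,
                 sd_participant_slopes = slopes,
                 sd_stimulus = sd_stimulus,
                 guess = guess, lapse = lapse),
            class = "observer_params")
}

#' Named observer presets
#'
#' Qualitative generative regimes used for testing and simulation (not fitted
#' values): `"null"` has no condition effects; `"species-only"` adds a
#' human-stimulus advantage; `"full"` adds level degradation plus a species
#' x level x polarity pattern in which polarity reversal (which gives the
#' chimpanzee eye a white sclera) helps chimpanzee stimuli and hurts human
#' stimuli, increasingly so as stimuli degrade, and the human-stimulus
#' advantage grows with degradation.
#'
#' @param name One of `"null"`, `"species-only"`, `"full"`.
#' @param guess Guessing floor applied to the preset (default 0 so that the
#'   generative model matches the plain binomial GLMM that is fitted to it).
#' @return An `observer_params`.
#' @export
observer_presets <- function(name = c("null", "species-only", "full"),
                             guess = 0) {
  name <- match.arg(name)
  switch(name,
    "null" = observer_params(intercept = 0.8, guess = guess),
    "species-only" = observer_params(
      intercept = 0.8, species = 0.8,
      sd_participant = 0.5, sd_stimulus = 0.3, guess = guess),
    "full" = observer_params(
      intercept = 2.2, species = 0.3,
      level = c(L2 = -0.6, L3 = -1.4, L4 = -2.4),
      polarity = 0.5,
      species_level = c(L2 = 0.2, L3 = 0.6, L4 = 1.0),
      species_polarity = -1.0,
      level_polarity = c(L2 = 0.1, L3 = 0.3, L4 = 0.5),
      species_level_polarity = c(L2 = -0.2, L3 = -0.8, L4 = -2.0),
      sd_participant = 0.5,
      sd_participant_slopes = c(species = 0.3, polarity = 0.3, level = 0.3),
      sd_stimulus = 0.3, guess = guess))
}

#' Serialize observer parameters to / from JSON
#'
#' @param params An [observer_params()].
#' @param path File path.
#' @return `read_observer_params()` returns an `observer_params`.
#' @export
write_observer_params <- function(params, path) {
  # named vectors go out as JSON objects so their names survive the trip
  x <- lapply(unclass(params), function(v)
    if (!is.null(names(v))) as.list(v) else v)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_observer_params
#' @export
read_observer_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x <- lapply(x, function(v) {
    if (is.list(v)) {
      u <- unlist(v)
      if (is.null(u)) numeric(0) else u
    } else v
  })
  do.call(observer_params, x)
}

level_label <- function(level) paste0("L", sub("\\.0$", "", format(level)))

named_or_zero <- function(v, labels) {
  out <- stats::setNames(rep(0, length(labels)), labels)
  keep <- intersect(names(v), labels)
  out[keep] <- v[keep]
  out
}

#' Simulate trial-level responses from the generative observer
#'
#' For each participant, draws uncorrelated random effects (participant
#' intercept and slopes, stimulus-individual intercepts), builds the logit
#' linear predictor from the trial's species, level and polarity under
#' treatment coding (reference: chimpanzee, lowest level in the plan, normal
#' polarity), maps it through `p = g + (1 - g - lambda) * plogis(eta)`, and
#' draws the Bernoulli outcome. Reproducible for a given seed.
#'
#' @param plan A trial-plan data frame from the schedule builders.
#' @param params An [observer_params()].
#' @param n_participants Number of simulated participants (>= 1).
#' @param seed Integer seed.
#' @return A data frame with the plan columns plus `participant_id` and
#'   `correct` (0/1), one row per participant x trial.
#' @examples
#' plan <- build_study1_exp1(seed = 1)
#' resp <- simulate_responses(plan, observer_presets("full"), 3, seed = 2)
#' mean(resp$correct)
#' @export
simulate_responses <- function(plan, params, n_participants, seed) {
  stopifnot(inherits(params, "observer_params"))
  if (n_participants < 1L) stop("n_participants must be >= 1")
  set.seed(seed)

  levels_present <- sort(unique(plan$level))
  ref_level <- levels_present[1]
  lev_labels <- level_label(setdiff(levels_present, ref_level))
  b_level <- named_or_zero(params$level, lev_labels)
  b_sp_level <- named_or_zero(params$species_level, lev_labels)
  b_lev_pol <- named_or_zero(params$level_polarity, lev_labels)
  b_sp_lev_pol <- named_or_zero(params$species_level_polarity, lev_labels)

  is_h <- as.numeric(plan$species == "human")
  is_r <- as.numeric(plan$polarity == "reversed")
  lev_key <- level_label(plan$level)
  lev_eff <- function(b) ifelse(lev_key %in% names(b), b[lev_key], 0)

  eta_fixed <- params$intercept +
    params$species * is_h +
    lev_eff(b_level) +
    params$polarity * is_r +
    lev_eff(b_sp_level) * is_h +
    params$species_polarity * is_h * is_r +
    lev_eff(b_lev_pol) * is_r +
    lev_eff(b_sp_lev_pol) * is_h * is_r

  stim_ids <- sort(unique(plan$stimulus_id))
  u_stim <- stats::setNames(stats::rnorm(length(stim_ids), 0, params$sd_stimulus),
                            stim_ids)
  n_trials <- nrow(plan)
  out <- vector("list", n_participants)
  sls <- params$sd_participant_slopes
  lev_dummy <- as.numeric(plan$level != ref_level)
  for (p in seq_len(n_participants)) {
    u0 <- stats::rnorm(1, 0, params$sd_participant)
    u_sp <- stats::rnorm(1, 0, sls["species"])
    u_pol <- stats::rnorm(1, 0, sls["polarity"])
    u_lev <- stats::rnorm(length(lev_labels), 0, sls["level"])
    names(u_lev) <- lev_labels
    eta <- eta_fixed + u0 + u_sp * is_h + u_pol * is_r +
      lev_eff(named_or_zero(u_lev, lev_labels)) +
      u_stim[plan$stimulus_id]
    pr <- params$guess + (1 - params$guess - params$lapse) * stats::plogis(eta)
    df <- plan
    df$participant_id <- sprintf("p%02d", p)
    df$correct <- stats::rbinom(n_trials, 1L, pr)
    out[[p]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
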