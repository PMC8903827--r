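#' @keywords internal
#' Constrained sequential sampler used by all schedule builders.
#'
#' Fills a sequence of length n from a multiset of symbols (named counts),
#' choosing at each position uniformly at random among symbols with remaining
#' count that do not violate the constraints: a maximum run length of equal
#' symbols (max_run), and optionally no repetition of the previous symbol
#' except where block_start resets the adjacency (no_repeat). Dead ends
#' trigger a restart; after max_attempts restarts the builder fails loudly
#' rather than relaxing a constraint.
constrained_sequence <- function(counts, max_run = Inf, no_repeat = FALSE,
                                 block_start = NULL, max_attempts = 10000L) {
  n <- sum(counts)
  syms <- names(counts)
  if (is.null(block_start)) block_start <- rep(FALSE, n)
  for (attempt in seq_len(max_attempts)) {
    left <- counts
    out <- character(n)
    ok <- TRUE
    run_len <- 0L
    for (i in seq_len(n)) {
      cand <- syms[left > 0]
      if (i > 1L && !block_start[i]) {
        if (no_repeat) cand <- setdiff(cand, out[i - 1L])
        if (is.finite(max_run) && run_len >= max_run)
          cand <- setdiff(cand, out[i - 1L])
      }
      if (length(cand) == 0L) { ok <- FALSE; break }
      pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
      out[i] <- pick
      left[pick] <- left[pick] - 1L
      run_len <- if (i > 1L && identical(pick, out[i - 1L]) && !block_start[i])
        run_len + 1L else 1L
    }
    if (ok) return(out)
  }
  stop("could not satisfy schedule constraints after ", max_attempts,
       " attempts")
}

# Near-balanced appearance counts: n_trials spread over ids, differing by at
# most one (e.g. 48 trials over 10 ids -> eight 5s and two 4s, mean 4.8).
balanced_counts <- function(ids, n_trials) {
  base <- n_trials %/% length(ids)
  extra <- n_trials %% length(ids)
  cnt <- rep(base, length(ids))
  if (extra > 0) cnt[sample(length(ids), extra)] <- base + 1L
  stats::setNames(cnt, ids)
}

stimulus_ids <- function(species, n) {
  sprintf("%s%02d", substr(species, 1, 1), seq_len(n))
}

# Assign stimulus individuals to one species' trial slots (consecutive runs of
# block_len per block), no individual in adjacent within-block trials.
assign_stimuli <- function(species, n_trials, n_ids, block_len) {
  ids <- stimulus_ids(species, n_ids)
  counts <- balanced_counts(ids, n_trials)
  starts <- rep(FALSE, n_trials)
  starts[seq(1, n_trials, by = block_len)] <- TRUE
  constrained_sequence(counts, no_repeat = TRUE, block_start = starts)
}

species_order <- function(first_species, n_blocks) {
  other <- setdiff(c("chimpanzee", "human"), first_species)
  rep(c(first_species, other), length.out = n_blocks)
}

#' Build the Study 1 Experiment 1 trial plan (keypress task, normal polarity)
#'
#' 96 trials in 8 blocks of 12; blocks alternate stimulus species starting
#' with `first_species`. Within each block the stimulus level steps up every
#' three trials (L1 L1 L1 L2 L2 L2 L3 L3 L3 L4 L4 L4), so each species x
#' level cell holds 12 trials. Gaze directions are balanced to 32 each with
#' no direction in more than two successive trials; the 10 stimulus
#' individuals per species are balanced to 4-5 appearances (mean 4.8) with no
#' individual repeated in consecutive trials. All trials use normal polarity.
#'
#' @param seed Integer seed; plans are byte-identical given the seed.
#' @param first_species Species of the first block, `"chimpanzee"` or
#'   `"human"` (counterbalanced across participants by the caller).
#' @param n_stimuli Stimulus individuals available per species (default 10).
#' @return A data frame, one row per trial, with columns `experiment_id`,
#'   `session_id`, `block`, `trial_in_block`, `species`, `stimulus_id`,
#'   `level`, `polarity`, `gaze_direction`, `role`.
#' @export
build_study1_exp1 <- function(seed, first_species = c("chimpanzee", "human"),
                              n_stimuli = 10L) {
  first_species <- match.arg(first_species)
  if (n_stimuli < 2L) stop("need at least 2 stimulus individuals per species")
  set.seed(seed)
  sp_blocks <- species_order(first_species, 8L)
  plan <- data.frame(
    experiment_id = "study1-exp1",
    session_id = 1L,
    block = rep(1:8, each = 12L),
    trial_in_block = rep(1:12, times = 8L),
    species = rep(sp_blocks, each = 12L),
    stimulus_id = NA_character_,
    level = rep(rep(c(1, 2, 3, 4), each = 3L), times = 8L),
    polarity = "normal",
    gaze_direction = constrained_sequence(
      c(left = 32L, front = 32L, right = 32L), max_run = 2L),
    role = "test",
    stringsAsFactors = FALSE)
  for (sp in unique(sp_blocks))
    plan$stimulus_id[plan$species == sp] <-
      assign_stimuli(sp, 48L, n_stimuli, 12L)
  plan
}

#' Build the Study 1 Experiment 2 trial plan (keypress task, polarity crossed)
#'
#' 96 trials in 8 alternating-species blocks of 12; each block presents six
#' consecutive L3 trials then six L4 trials, and the block polarity pattern is
#' normal, normal, reversed, reversed, normal, normal, reversed, reversed, so
#' each species x level x polarity cell holds 12 trials. Sequential
#' constraints are as in [build_study1_exp1()].
#'
#' @inheritParams build_study1_exp1
#' @return A trial-plan data frame (same columns as [build_study1_exp1()]).
#' @export
build_study1_exp2 <- function(seed, first_species = c("chimpanzee", "human"),
                              n_stimuli = 10L) {
  first_species <- match.arg(first_species)
  set.seed(seed)
  sp_blocks <- species_order(first_species, 8L)
  pol_blocks <- c("normal", "normal", "reversed", "reversed",
                  "normal", "normal", "reversed", "reversed")
  plan <- data.frame(
    experiment_id = "study1-exp2",
    session_id = 1L,
    block = rep(1:8, each = 12L),
    trial_in_block = rep(1:12, times = 8L),
    species = rep(sp_blocks, each = 12L),
    stimulus_id = NA_character_,
    level = rep(rep(c(3, 4), each = 6L), times = 8L),
    polarity = rep(pol_blocks, each = 12L),
    gaze_direction = constrained_sequence(
      c(left = 32L, front = 32L, right = 32L), max_run = 2L),
    role = "test",
    stringsAsFactors = FALSE)
  for (sp in unique(sp_blocks))
    plan$stimulus_id[plan$species == sp] <-
      assign_stimuli(sp, 48L, n_stimuli, 12L)
  plan
}

#' Build a Study 2 session plan (three-item visual search)
#'
#' 48 trials in 4 alternating-species blocks of 12. For sessions at level
#' 1.5 or higher, each block holds six consecutive baseline trials (L1) then
#' six test trials at the session level (24 baseline + 24 test per session);
#' an L1 session has no baseline/test split. The averted-gaze target location
#' is balanced to 16 per location with no location in more than two
#' successive trials; the six stimulus individuals per species each appear
#' exactly four times, never in consecutive trials.
#'
#' @param seed Integer seed.
#' @param level Session stimulus level, one of 1, 1.5, ..., 4.
#' @param polarity `"normal"` or `"reversed"` (applies to all trials).
#' @param first_species Species of the first block.
#' @param n_stimuli Stimulus individuals per species (default 6).
#' @param session_id Session identifier stored on the rows.
#' @return A trial-plan data frame with `target_location` in place of
#'   `gaze_direction`; `role` is `"baseline"` or `"test"`, and a `phase`
#'   attribute marks the session as `"pre-test"` (level < 2.5) or `"test"`.
#' @export
build_study2_session <- function(seed, level, polarity = c("normal", "reversed"),
                                 first_species = c("chimpanzee", "human"),
                                 n_stimuli = 6L, session_id = 1L) {
  polarity <- match.arg(polarity)
  first_species <- match.arg(first_species)
  if (!level %in% stimulus_levels()$level) stop("unknown stimulus level: ", level)
  set.seed(seed)
  sp_blocks <- species_order(first_species, 4L)
  split <- level >= 1.5
  lev <- if (split) rep(rep(c(1, level), each = 6L), times = 4L) else rep(1, 48L)
  role <- if (split) rep(rep(c("baseline", "test"), each = 6L), times = 4L)
          else rep("baseline", 48L)
  plan <- data.frame(
    experiment_id = "study2",
    session_id = session_id,
    block = rep(1:4, each = 12L),
    trial_in_block = rep(1:12, times = 4L),
    species = rep(sp_blocks, each = 12L),
    stimulus_id = NA_character_,
    level = lev,
    polarity = polarity,
    target_location = constrained_sequence(
      c(left = 16L, center = 16L, right = 16L), max_run = 2L),
    role = role,
    stringsAsFactors = FALSE)
  for (sp in unique(sp_blocks))
    plan$stimulus_id[plan$species == sp] <-
      assign_stimuli(sp, 24L, n_stimuli, 12L)
  attr(plan, "phase") <- if (level >= 2.5) "test" else "pre-test"
  plan
}

#' Trials that count toward the adaptive level criterion
#'
#' In the adaptive chimpanzee sessions, performance is scored on all trials
#' at level 1 plus the test trials at higher levels.
#'
#' @param plan A Study 2 session plan.
#' @return Logical vector over plan rows.
#' @export
target_trials <- function(plan) {
  plan$level == 1 | plan$role == "test"
}

#' Validate the balancing and sequencing contracts of a trial plan
#'
#' Checks the constraints the builders promise: balanced direction/location
#' and stimulus-individual counts, species alternation across blocks, no
#' direction/location run longer than two, and no stimulus individual in
#' consecutive trials. Intended for property tests and pipeline manifests.
#'
#' @param plan A trial-plan data frame from one of the builders.
#' @return Invisibly `TRUE`; stops with a message on the first violated
#'   contract.
#' @export
validate_plan <- function(plan) {
  dir_col <- if ("gaze_direction" %in% names(plan)) "gaze_direction"
             else "target_location"
  runs <- rle(plan[[dir_col]])
  if (any(runs$lengths > 2L))
    stop("a ", dir_col, " appears in more than two successive trials")
  if (length(unique(table(plan[[dir_col]]))) != 1L)
    stop(dir_col, " counts are unbalanced")
  sp <- plan$species[!duplicated(plan$block)]
  if (any(sp[-1] == sp[-length(sp)]))
    stop("blocks do not alternate species")
  same_block <- plan$block[-1] == plan$block[-nrow(plan)]
  rep_id <- plan$stimulus_id[-1] == plan$stimulus_id[-nrow(plan)]
  if (any(same_block & rep_id))
    stop("a stimulus individual appears in consecutive trials")
  cnt <- table(plan$stimulus_id)
  if (diff(range(cnt)) > 1L)
    stop("stimulus individual counts differ by more than one")
  invisible(TRUE)
}
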