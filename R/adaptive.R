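#' Adaptive stimulus-level state
#'
#' Tracks the stimulus level presented to a chimpanzee across sessions. The
#' level starts at 1 and is incremented by `step` (0.5) whenever the target
#' accuracy exceeds `threshold` (85\%) in `consecutive_required` (two)
#' successive sessions at the current level; it never decreases and is capped
#' at 4.
#'
#' @param current_level Starting level (default 1).
#' @param threshold Accuracy that must be exceeded, default 0.85 (strict).
#' @param consecutive_required Number of successive qualifying sessions,
#'   default 2.
#' @param step Level increment, default 0.5.
#' @return An `adaptive_state` list with an `accuracy_history` of sessions at
#'   the current level.
#' @export
adaptive_state <- function(current_level = 1, threshold = 0.85,
                           consecutive_required = 2L, step = 0.5) {
  if (!current_level %in% stimulus_levels()$level)
    stop("unknown stimulus level: ", current_level)
  structure(list(current_level = current_level,
                 accuracy_history = numeric(0),
                 threshold = threshold,
                 consecutive_required = as.integer(consecutive_required),
                 step = step),
            class = "adaptive_state")
}

#' Update the adaptive level after a session
#'
#' Appends the session's target-trial accuracy to the history and increments
#' the level by 0.5 iff the most recent `consecutive_required` accuracies at
#' the current level all exceed the threshold (strictly). The history resets
#' on an increment; the level is capped at 4.
#'
#' @param state An [adaptive_state()].
#' @param session_target_accuracy Proportion correct in target trials, in
#'   \[0, 1\].
#' @return The updated `adaptive_state`.
#' @examples
#' s <- adaptive_state(current_level = 2.5)
#' s <- update_level(s, 0.90)
#' s <- update_level(s, 0.88)
#' s$current_level  # 3.0
#' @export
update_level <- function(state, session_target_accuracy) {
  stopifnot(inherits(state, "adaptive_state"))
  if (session_target_accuracy < 0 || session_target_accuracy > 1)
    stop("accuracy must lie in [0, 1]")
  state$accuracy_history <- c(state$accuracy_history, session_target_accuracy)
  k <- state$consecutive_required
  h <- state$accuracy_history
  if (length(h) >= k && all(utils::tail(h, k) > state$threshold) &&
      state$current_level < 4) {
    state$current_level <- min(state$current_level + state$step, 4)
    state$accuracy_history <- numeric(0)
  }
  state
}

#' Session phase implied by a stimulus level
#'
#' Sessions at level 2.5 or higher form the test phase; lower levels are
#' pre-test.
#'
#' @param level Stimulus level.
#' @return `"pre-test"` or `"test"`.
#' @export
session_phase <- function(level) ifelse(level >= 2.5, "test", "pre-test")

#' Training-stage definition
#'
#' The six training stages of the visual-search task: stage 1 presents a
#' target with no iris; stages 2-4 move the target iris from 38 to 30 to the
#' final 20 degrees; stages 5 and 6 enlarge the stimulus roster from 2 to 4
#' to the final 6 individuals per species.
#'
#' @param stage Integer 1-6.
#' @return A `training_stage` list with fields `stage`, `target_iris`
#'   (`NA` for absent, else the gaze angle in degrees),
#'   `n_stimulus_individuals_per_species`, and the pass-criterion parameters
#'   (`one_session_above = 0.90` strict, `two_session_at_least = 0.80`).
#' @export
training_stage <- function(stage) {
  stage <- as.integer(stage)
  if (stage < 1L || stage > 6L) stop("stage must be 1..6")
  structure(list(
    stage = stage,
    target_iris = c(NA, 38, 30, 20, 20, 20)[stage],
    n_stimulus_individuals_per_species = c(2L, 2L, 2L, 2L, 4L, 6L)[stage],
    one_session_above = 0.90,
    two_session_at_least = 0.80),
    class = "training_stage")
}

#' Evaluate the training-stage pass criterion
#'
#' A chimpanzee passes a training stage when, for EACH stimulus species
#' separately, it scores over 90\% in the latest session or at least 80\% in
#' the latest two consecutive sessions.
#'
#' @param stage A [training_stage()].
#' @param accuracies A data frame with columns `session`, `species`,
#'   `accuracy` (one row per session x species), or a named list of per-
#'   species accuracy vectors ordered by session.
#' @return `"pass"` or `"continue"`.
#' @export
evaluate_training <- function(stage, accuracies) {
  stopifnot(inherits(stage, "training_stage"))
  if (is.data.frame(accuracies)) {
    accuracies <- accuracies[order(accuracies$session), ]
    accuracies <- split(accuracies$accuracy, accuracies$species)
  }
  if (length(accuracies) < 2L)
    stop("accuracies for both stimulus species are required")
  passed <- vapply(accuracies, function(h) {
    if (length(h) < 1L) stop("at least one session is required")
    last1 <- h[length(h)] > stage$one_session_above
    last2 <- length(h) >= 2L &&
      all(utils::tail(h, 2L) >= stage$two_session_at_least)
    last1 || last2
  }, logical(1))
  if (all(passed)) "pass" else "continue"
}

#' Simulate an adaptive session sequence
#'
#' Runs the session-level adaptive loop: builds a Study 2 session plan at the
#' current level, simulates responses for one participant with
#' [simulate_responses()], scores the target trials, and updates the level,
#' until `n_sessions` sessions are complete.
#'
#' @param params An [observer_params()].
#' @param n_sessions Number of sessions to run.
#' @param seed Integer seed (session plans and responses derive from it).
#' @param polarity Polarity of all sessions.
#' @param start_level Level of the first session.
#' @return A data frame with one row per session: `session`, `level`,
#'   `phase`, `target_accuracy`.
#' @export
run_adaptive_sessions <- function(params, n_sessions, seed,
                                  polarity = "normal", start_level = 1) {
  state <- adaptive_state(current_level = start_level)
  out <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    first <- if (s %% 2L == 1L) "chimpanzee" else "human"
    plan <- build_study2_session(seed + s, state$current_level,
                                 polarity = polarity, first_species = first,
                                 session_id = s)
    resp <- simulate_responses(plan, params, n_participants = 1L,
                               seed = seed + 100000L + s)
    tgt <- target_trials(plan)
    acc <- mean(resp$correct[tgt])
    out[[s]] <- data.frame(session = s, level = state$current_level,
                           phase = session_phase(state$current_level),
                           target_accuracy = acc)
    state <- update_level(state, acc)
  }
  do.call(rbind, out)
}
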