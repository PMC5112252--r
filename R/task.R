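#' The 32-stimulus space
#'
#' The task stimuli are frequency-modulated tones varying along five binary
#' dimensions: duration (short/long), intensity (low/high), frequency range
#' (low/high), modulation direction (rising/falling) and modulation speed
#' (slow/fast) — 32 distinct stimuli.  The categorization-relevant dimensions
#' are duration and direction, giving four basic tone categories of eight
#' stimuli each.
#'
#' @return A data frame with 32 rows: `id`, the five 0/1 attribute columns
#'   (`duration`, `intensity`, `frequency`, `direction`, `speed`) and the
#'   task `category` (1..4, determined by duration and direction only).
#' @export
stimulus_set <- function() {
  g <- expand.grid(duration = 0:1, intensity = 0:1, frequency = 0:1,
                   direction = 0:1, speed = 0:1)
  g <- g[, c("duration", "intensity", "frequency", "direction", "speed")]
  g$id <- seq_len(nrow(g))
  g$category <- 1L + g$duration + 2L * g$direction
  g[, c("id", "duration", "intensity", "frequency", "direction", "speed",
        "category")]
}

#' Population-code encoding of a stimulus
#'
#' Each of the five binary dimensions is represented by a pair of units, one
#' of which is active (one-of-two code), so every stimulus maps to a 10-unit
#' binary vector with exactly five ones.
#'
#' @param stim A stimulus id (1..32) or one row of [stimulus_set()].
#' @return Binary input vector of length 10.
#' @export
encode_stimulus <- function(stim) {
  if (is.numeric(stim) && length(stim) == 1) stim <- stimulus_set()[stim, ]
  bits <- as.numeric(stim[c("duration", "intensity", "frequency",
                            "direction", "speed")])
  code <- numeric(10)
  code[2 * seq_along(bits) - 1 + bits] <- 1
  code
}

#' Sample stimulus ids uniformly
#'
#' Trials draw stimuli independently and uniformly over the 32 stimuli, so
#' the target category appears with probability 1/4, matching the 25% target
#' rate of the behavioural design.
#'
#' @param n Number of trials.
#' @return Integer vector of stimulus ids.
#' @export
sample_stimuli <- function(n) sample.int(32L, n, replace = TRUE)

#' Reward contingency of one phase
#'
#' One of the four categories is the target.  Action 1 is the "target
#' response" and action 2 the "non-target response" (nominal labels).  In
#' even phases (0, 2, ...) the target category maps to action 1 and the
#' other categories to action 2; odd phases reverse the mapping, and the
#' re-reversal in phase 2 restores the initial assignment.
#'
#' @param target_category Target category (1..4).
#' @param phase Phase index (0-based).
#' @return An object of class `contingency` with the `target_category`,
#'   `phase`, and the `target_action`/`nontarget_action` mapping.
#' @export
make_contingency <- function(target_category = 1L, phase = 0L) {
  if (!target_category %in% 1:4) stop("target_category must be in 1..4")
  reversed <- phase %% 2 == 1
  structure(list(target_category = as.integer(target_category),
                 phase = as.integer(phase),
                 target_action = if (reversed) 2L else 1L,
                 nontarget_action = if (reversed) 1L else 2L),
            class = "contingency")
}

#' @export
`==.contingency` <- function(e1, e2) {
  e1$target_category == e2$target_category &&
    e1$target_action == e2$target_action &&
    e1$nontarget_action == e2$nontarget_action
}

#' Correct action under a contingency
#'
#' @param stim_category Category (1..4) of the stimulus.
#' @param cont A [make_contingency()].
#' @return 1 or 2.
#' @export
correct_action <- function(stim_category, cont) {
  ifelse(stim_category == cont$target_category, cont$target_action,
         cont$nontarget_action)
}

#' Reward for an action
#'
#' `reward_correct` (default 0.4) iff the action matches the contingency's
#' correct action for the stimulus category, else `reward_incorrect`
#' (default 0).
#'
#' @param action Chosen action (1 or 2).
#' @param stim_category Category of the presented stimulus.
#' @param cont A [make_contingency()].
#' @param lp A [learning_params()] supplying the two reward levels.
#' @return Scalar reward.
#' @export
reward_for <- function(action, stim_category, cont, lp = learning_params()) {
  if (!action %in% 1:2) stop("action must be 1 or 2")
  if (action == correct_action(stim_category, cont)) lp$reward_correct
  else lp$reward_incorrect
}

#' Serial-reversal schedule
#'
#' The contingency is constant within a phase, reversed between consecutive
#' phases, and therefore identical in phases 0 and 2: each learning phase
#' (Initial, first reversal REV01, second reversal REV02) consists of a fixed
#' number of stimulus presentations (default 160).
#'
#' @param trials_per_phase Trials in each phase (>= 1).
#' @param n_phases Number of phases (>= 1, default 3).
#' @param target_category Target category held fixed over the run.
#' @return A list with the per-trial `phase` vector (0-based) and the list of
#'   per-phase `contingencies`.
#' @export
reversal_schedule <- function(trials_per_phase = 160L, n_phases = 3L,
                              target_category = 1L) {
  if (trials_per_phase < 1 || n_phases < 1) stop("counts must be >= 1")
  list(phase = rep(seq_len(n_phases) - 1L, each = trials_per_phase),
       contingencies = lapply(seq_len(n_phases) - 1L, make_contingency,
                              target_category = target_category))
}
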