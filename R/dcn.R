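#' Dynamic control network parameters
#'
#' Constants of the expert-gating subsystem.  `sigma`, `c` and the noise
#' amplitude are the stated simulation values (0.9, 0.2, 0.01); the
#' suppression weight is initialized to the weight cap (4) and the bias
#' weights uniformly in `[0.8, 1.2]`.
#'
#' `wta_self`, `wta_lateral` and `wta_threshold` parametrize the fixed
#' (non-learned) kernel of the competitive field: self-excitation, uniform
#' lateral inhibition and background inhibition of the winner-take-all
#' units, which obey the core shunting dynamics.  Together with the tonic
#' bias activity `p_b` and the vigilance comparison (`error_avg_rate`,
#' `error_fast_rate`, `reset_threshold`) the kernel realizes two regimes:
#' under usual prediction errors the outstar rule tracks the field and locks
#' the selection onto one expert; a sustained higher-than-usual error
#' attracts all bias weights toward `c`, collapsing their differences to
#' the decision-noise level so that the winner is re-drawn — the reset that
#' lets another expert take over.  See the methods vignette for the
#' calibration rationale.
#'
#' @param sigma Attraction gain of the error term (>= 0).
#' @param c Attraction target of the bias weights under high prediction
#'   error.
#' @param noise_amp Amplitude of the uniform symmetric noise term of the
#'   bias learning rule.
#' @param select_noise Amplitude of the per-trial decision noise added to
#'   the winner-take-all drive during selection.  Uniform with bounded
#'   support: it cannot flip a fully locked selection (bias gap larger than
#'   twice the amplitude) but re-draws the winner once a reset has collapsed
#'   the gap.
#' @param inhib_weight Suppression-unit -> motor-unit inhibitory strength.
#' @param bias_init_range Uniform initialization range of the bias weights.
#' @param wta_self Fixed self-excitation of each winner-take-all unit.
#' @param wta_lateral Fixed uniform lateral inhibition between them.
#' @param wta_threshold Constant background inhibition of the field; keeps
#'   units near their activation threshold at low bias drive so that the
#'   competition is noise-dominated after a reset.
#' @param p_b Equilibrium activity of the tonic bias unit; scales the
#'   outstar term relative to the error-driven attraction (a shunting unit
#'   under constant drive equilibrates below its ceiling).
#' @param abs_delta Use the magnitude of the prediction error in the
#'   attraction and noise terms of the bias rule (default), so that both
#'   over- and under-prediction destabilize the selection; `FALSE` uses the
#'   signed error.
#' @param error_avg_rate Rate at which the baseline error expectation of
#'   the control network rises toward the current error trace.  The
#'   baseline falls at the fast rate whenever the trace drops below it, so
#'   it tracks the best recently achieved error level; a strategy change is
#'   detected as a sustained rise above that level.
#' @param error_fast_rate Rate of the fast exponential trace of the error
#'   magnitude (the recently accumulated error).  The attraction and noise
#'   terms are driven by the positive excess of the fast trace over the slow
#'   average: the reset fires on a sustained higher-than-usual prediction
#'   error, not on the (high but falling) error of ongoing acquisition nor
#'   on isolated exploration errors.  Set `error_avg_rate = 0` to disable
#'   the comparison and use the raw per-trial error.
#' @param error_avg_init Initial value of both error traces (the error
#'   scale expected before any learning).
#' @param reset_threshold Vigilance threshold of the orienting comparison:
#'   the attraction toward `c` is engaged (at the full strength of the fast
#'   error trace) only while the fast trace exceeds the slow average by more
#'   than this margin.  Isolated exploration errors stay below the margin;
#'   the sustained error rise after a contingency reversal crosses it.
#' @param max_weight Cap for the bias weights.
#' @return An object of class `dcn_params`.
#' @export
dcn_params <- function(sigma = 0.9, c = 0.2, noise_amp = 0.01,
                       inhib_weight = 4, bias_init_range = c(0.8, 1.2),
                       wta_self = 0.8, wta_lateral = 0.4,
                       select_noise = 0.1,
                       wta_threshold = 0.15, p_b = 0.15,
                       abs_delta = TRUE, error_avg_rate = 0.02,
                       error_fast_rate = 0.35, error_avg_init = 0.4,
                       reset_threshold = 0.08, max_weight = 4) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (noise_amp < 0) stop("noise_amp must be >= 0")
  if (p_b < 0 || p_b > 1) stop("p_b must lie in [0, 1]")
  if (error_avg_rate < 0 || error_avg_rate > 1)
    stop("error_avg_rate must lie in [0, 1]")
  structure(list(sigma = sigma, c = c, noise_amp = noise_amp,
                 select_noise = select_noise, inhib_weight = inhib_weight,
                 bias_init_range = bias_init_range,
                 wta_self = wta_self, wta_lateral = wta_lateral,
                 wta_threshold = wta_threshold, p_b = p_b,
                 abs_delta = abs_delta, error_avg_rate = error_avg_rate,
                 error_fast_rate = error_fast_rate,
                 error_avg_init = error_avg_init,
                 reset_threshold = reset_threshold, max_weight = max_weight),
            class = "dcn_params")
}

#' Initialize the dynamic control network state
#'
#' Draws the bias weights (one per winner-take-all unit, i.e. per expert)
#' uniformly from the initialization range and builds the fixed competitive
#' field.
#'
#' @param n_experts Number of experts to gate.
#' @param params A [dcn_params()].
#' @param up A [unit_params()] used for the field's shunting dynamics.
#' @return An object of class `dcn_state` with bias weights `w`, the fixed
#'   field `conn`, the last equilibrium `wta_activity` and the currently
#'   `selected` expert (NA before the first selection).
#' @export
dcn_init <- function(n_experts, params = dcn_params(), up = unit_params()) {
  if (n_experts < 1) stop("at least one expert is required")
  w <- runif(n_experts, params$bias_init_range[1], params$bias_init_range[2])
  w_ex <- diag(params$wta_self, n_experts)
  w_inh <- matrix(params$wta_lateral, n_experts, n_experts)
  diag(w_inh) <- 0
  conn <- connection_set(w_ex, w_inh, matrix(0, n_experts, n_experts),
                         diag(1, n_experts),
                         mask_inp = diag(1, n_experts),
                         max_weight = max(params$max_weight, params$wta_self,
                                          params$wta_lateral, 1))
  structure(list(w = w, conn = conn, up = up,
                 wta_activity = rep(NA_real_, n_experts),
                 selected = NA_integer_, n_experts = n_experts,
                 delta_bar = params$error_avg_init,
                 delta_fast = params$error_avg_init),
            class = "dcn_state")
}

#' Select an expert by competitive release from inhibition
#'
#' The winner-take-all field is driven by the bias weights (tonic bias unit
#' at activity 1) plus per-unit uniform noise, relaxed to equilibrium with
#' the core shunting dynamics; the maximally active unit wins (exact ties
#' broken uniformly at random).  The winner fully suppresses its paired
#' suppression unit, so the corresponding expert's motor units receive zero
#' suppression while every other expert's motor units receive inhibition of
#' strength `inhib_weight` (see [suppression_input()]).
#'
#' @param dcn A `dcn_state`.
#' @param params A [dcn_params()].
#' @return The updated `dcn_state` with `selected` and `wta_activity` set.
#' @export
dcn_select <- function(dcn, params = dcn_params()) {
  drive <- pmax(dcn$w * 1 + runif(dcn$n_experts, -params$select_noise,
                                  params$select_noise), 0)
  st <- relax_network(dcn$conn, drive, dcn$up,
                      i_inh_ext = params$wta_threshold)
  winners <- which(st$p == max(st$p))
  dcn$selected <- if (length(winners) > 1)
    winners[sample.int(length(winners), 1L)] else winners
  dcn$wta_activity <- st$r
  dcn
}

#' Suppression input onto the motor units
#'
#' @param dcn A `dcn_state` after [dcn_select()].
#' @param layout A [network_layout()].
#' @param params A [dcn_params()].
#' @return External inhibitory input per unit: `inhib_weight` on the motor
#'   units of every non-selected expert, zero elsewhere.
#' @export
suppression_input <- function(dcn, layout, params = dcn_params()) {
  supp <- numeric(layout$n_units)
  for (e in seq_along(layout$motor))
    if (e != dcn$selected) supp[layout$motor[[e]]] <- params$inhib_weight
  supp
}

#' Bias-weight learning of the dynamic control network
#'
#' Applies \eqn{\Delta w = p^\infty_B (p^\infty_{WTA} - w)
#'  + \sigma\,|\delta|\,(c - w) + |\delta|\,\nu} with the tonic bias unit's
#' equilibrium activity \eqn{p^\infty_B}, the equilibrium winner-take-all
#' activities (firing rates) of the current trial, and fresh per-component
#' noise \eqn{\nu} uniform in `[-noise_amp, noise_amp]`.  While the prediction error is low the rule is
#' outstar learning (the bias tracks the field's activity pattern, so the
#' same expert keeps being selected); a sustained higher-than-usual error
#' attracts the weights toward `c` and the selection becomes noise-driven.
#' The attraction is driven by the positive excess of `|delta|` over the
#' control network's running error average (see [dcn_params()]), so the
#' large-but-falling errors of initial acquisition do not destabilize the
#' selection while the sudden error rise after a contingency reversal does.
#' Weights are clipped to `[0, max_weight]`.
#'
#' @param dcn A `dcn_state` holding the current trial's equilibrium
#'   activities.
#' @param delta Reward prediction error of the trial.
#' @param params A [dcn_params()].
#' @param p_b Equilibrium activity of the tonic bias unit (defaults to the
#'   value in `params`).
#' @return The updated `dcn_state`.
#' @export
dcn_update_bias <- function(dcn, delta, params = dcn_params(),
                            p_b = params$p_b) {
  d <- if (params$abs_delta) abs(delta) else delta
  if (params$error_avg_rate > 0) {
    dcn$delta_fast <- (1 - params$error_fast_rate) * dcn$delta_fast +
      params$error_fast_rate * d
    # vigilance: a sustained higher-than-usual error engages the reset
    e <- if (dcn$delta_fast - dcn$delta_bar > params$reset_threshold)
      dcn$delta_fast else 0
    # the baseline tracks the best recently achieved error level: it falls
    # quickly when the trace improves and rises only slowly
    rate <- if (dcn$delta_fast < dcn$delta_bar) params$error_fast_rate
            else params$error_avg_rate
    dcn$delta_bar <- dcn$delta_bar + rate * (dcn$delta_fast - dcn$delta_bar)
  } else e <- d
  nu <- runif(dcn$n_experts, -params$noise_amp, params$noise_amp)
  dw <- p_b * (dcn$wta_activity - dcn$w) + params$sigma * e *
    (params$c - dcn$w) + e * nu
  dcn$w <- pmin(pmax(dcn$w + dw, 0), params$max_weight)
  dcn
}
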