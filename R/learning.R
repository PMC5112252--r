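#' Softmax action-selection probabilities
#'
#' Probability of each eligible output unit winning the competition between
#' actions, \eqn{P(i) = \exp(p_i/\tau) / \sum_j \exp(p_j/\tau)}, computed with
#' max-subtraction for numerical stability.
#'
#' @param values Equilibrium potentials of the eligible motor units.
#' @param tau Softmax temperature (> 0).
#' @return Vector of probabilities summing to 1.
#' @examples
#' action_probabilities(c(0.4, 0.25), tau = 0.15)  # c(0.731.., 0.268..)
#' @export
action_probabilities <- function(values, tau = 0.15) {
  if (length(values) < 1) stop("empty eligible action set (gating failure)")
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0")
  z <- exp((values - max(values)) / tau)
  z / sum(z)
}

#' Sample an action by the softmax rule
#'
#' Draws one eligible unit with the probabilities of
#' [action_probabilities()], using R's current random stream.
#'
#' @inheritParams action_probabilities
#' @return The sampled index into `values` (1-based).
#' @export
select_action <- function(values, tau = 0.15) {
  pr <- action_probabilities(values, tau)
  sample.int(length(pr), 1L, prob = pr)
}

#' Reward prediction error
#'
#' \eqn{\delta = \varrho - Q_a}, the received reward minus the predicted
#' action value (the winning output unit's equilibrium potential).
#'
#' @param rho Received reward.
#' @param q_a Predicted value of the chosen action.
#' @return The prediction error, exact subtraction.
#' @export
prediction_error <- function(rho, q_a) rho - q_a

#' Momentum buffer matching a connection set
#'
#' @param conn A [connection_set()].
#' @return A list of zero matrices `w_ex`, `w_inh`, `w_mod`, `w_inp` with the
#'   same shapes as `conn`.
#' @export
make_velocity <- function(conn) {
  list(w_ex = 0 * conn$w_ex, w_inh = 0 * conn$w_inh,
       w_mod = 0 * conn$w_mod, w_inp = 0 * conn$w_inp)
}

#' Postsynaptic plasticity factors per connection type
#'
#' The postsynaptic factor `f_l` of the three-factor rule differs between
#' connection types, reflecting how each input channel enters the shunting
#' equation: excitatory
#' \eqn{f^{ex}_l = (\beta - p_l)(1 + \gamma I^{mod}_l)}, modulatory
#' \eqn{f^{mod}_l = \gamma (\beta - p_l) I^{ex}_l}, inhibitory
#' \eqn{f^{inh}_l = -(\zeta + p_l)}.
#'
#' @param state A `network_state` at equilibrium.
#' @param params A [unit_params()].
#' @return List of vectors `ex`, `mod`, `inh` over units.
#' @export
plasticity_factors <- function(state, params) {
  list(ex = (params$beta - state$p) * (1 + params$gamma * state$i_mod),
       mod = params$gamma * (params$beta - state$p) * state$i_ex,
       inh = -(params$zeta + state$p))
}

#' Reward-gated weight update (phase 3)
#'
#' Applies the three-factor rule
#' \eqn{\Delta W_{kl} = \eta\,\delta\,\Delta p_l\,f_l(p^\infty_l)\,g(p^\infty_k)}
#' to every connection type, with the type-specific postsynaptic factors of
#' [plasticity_factors()].  Input connections are treated as excitatory with
#' the external input value as the presynaptic term.  The raw update is
#' accumulated into a heavy-ball momentum buffer
#' (`velocity <- momentum * velocity + raw`), weights move by
#' `eta * velocity`, are clipped to `[0, max_weight]` and restricted to the
#' structural masks.
#'
#' @param conn A [connection_set()].
#' @param state Equilibrium `network_state` of the trial.
#' @param acc An `accessory_state` from [propagate_accessory()].
#' @param delta Reward prediction error of the trial.
#' @param lp A [learning_params()].
#' @param velocity Momentum buffer from [make_velocity()].
#' @param i_inp External input feature vector of the trial.
#' @param params A [unit_params()].
#' @return List with updated `conn` and `velocity`.
#' @export
update_weights <- function(conn, state, acc, delta, lp, velocity, i_inp,
                           params = unit_params()) {
  f <- plasticity_factors(state, params)
  post_ex <- acc$delta_p * f$ex
  post_mod <- acc$delta_p * f$mod
  post_inh <- acc$delta_p * f$inh
  r <- state$r
  step <- function(w, v, mask, pre, post)
    update_core(w, v, mask, pre, post, delta, lp$eta, lp$momentum,
                conn$max_weight)
  ex <- step(conn$w_ex, velocity$w_ex, conn$mask_ex, r, post_ex)
  inh <- step(conn$w_inh, velocity$w_inh, conn$mask_inh, r, post_inh)
  mod <- step(conn$w_mod, velocity$w_mod, conn$mask_mod, r, post_mod)
  inp <- step(conn$w_inp, velocity$w_inp, conn$mask_inp, i_inp, post_ex)
  conn$w_ex <- ex$w; conn$w_inh <- inh$w
  conn$w_mod <- mod$w; conn$w_inp <- inp$w
  list(conn = conn,
       velocity = list(w_ex = ex$v, w_inh = inh$v, w_mod = mod$v,
                       w_inp = inp$v))
}
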