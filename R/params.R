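#' Unit (cortical column) parameters
#'
#' Parameters of the shunting membrane equation
#' \deqn{\dot p = -\alpha p + (\beta - p)\,I^{ex}(1 + \gamma I^{mod})
#'       - (\zeta + p)\,I^{inh}}
#' and of the piecewise rate function [firing_rate()].  The defaults are the
#' values used throughout the simulations: `alpha = beta = zeta = 1`,
#' `gamma = 4`.  `a` is the smoothing constant of the rate function; it is not
#' fixed by the model equations and defaults to `0.1`.
#'
#' @param alpha Decay rate of the membrane potential (> 0).
#' @param beta Maximal activity bound (> 0).
#' @param gamma Gain of the modulatory input (> 0).
#' @param zeta Minimal activity bound (> 0); equilibrium potentials lie in
#'   `[-zeta, beta]` for nonnegative inputs.
#' @param a Rate-function smoothing constant (> 0).
#' @return An object of class `unit_params`.
#' @examples
#' up <- unit_params()
#' up$gamma
#' @export
unit_params <- function(alpha = 1, beta = 1, gamma = 4, zeta = 1, a = 0.1) {
  vals <- c(alpha = alpha, beta = beta, gamma = gamma, zeta = zeta, a = a)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all unit parameters must be finite and strictly positive")
  structure(as.list(vals), class = "unit_params")
}

#' Learning-rule parameters
#'
#' Constants of the reward-modulated three-factor plasticity rule and of the
#' softmax action selection.  Defaults are the simulation values: learning
#' rate 0.2, heavy-ball momentum 0.9, softmax temperature 0.15, reward 0.4 on
#' correct and 0 on erroneous trials.
#'
#' @param eta Learning rate (> 0).
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param tau Softmax temperature (> 0).
#' @param reward_correct Reward delivered on correct trials.
#' @param reward_incorrect Reward delivered on erroneous trials.
#' @param accessory_gain Global gain applied to the accessory boost before
#'   the weight update.  The boost is defined only up to a positive
#'   proportionality constant; the gain sets the overall scale of credit
#'   reaching the deeper layers (see the methods vignette).
#' @return An object of class `learning_params`.
#' @export
learning_params <- function(eta = 0.2, momentum = 0.9, tau = 0.15,
                            reward_correct = 0.4, reward_incorrect = 0,
                            accessory_gain = 20) {
  if (!is.finite(eta) || eta <= 0) stop("eta must be > 0")
  if (!is.finite(momentum) || momentum < 0 || momentum >= 1)
    stop("momentum must lie in [0, 1)")
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0")
  if (!is.finite(accessory_gain) || accessory_gain <= 0)
    stop("accessory_gain must be > 0")
  structure(list(eta = eta, momentum = momentum, tau = tau,
                 reward_correct = reward_correct,
                 reward_incorrect = reward_incorrect,
                 accessory_gain = accessory_gain),
            class = "learning_params")
}
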