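#' Piecewise-smooth firing-rate function
#'
#' Maps membrane potentials to mean spike rates,
#' \deqn{g(p) = a + p \;(p \ge 0), \qquad g(p) = a\,e^{p/a} \;(p < 0).}
#' The two branches meet continuously (value `a`, slope 1) at `p = 0`; the
#' rate is strictly positive and nondecreasing everywhere.
#'
#' @param p Vector of membrane potentials.
#' @param a Smoothing constant (> 0).
#' @return Vector of rates, elementwise.
#' @examples
#' firing_rate(c(-0.1, 0, 0.5), a = 0.1)
#' @export
firing_rate <- function(p, a = 0.1) {
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a <= 0)
    stop("rate-function constant a must be a single value > 0")
  ifelse(p >= 0, a + p, a * exp(p / a))
}

#' Derivative of the firing-rate function
#'
#' `g'(p) = 1` for `p >= 0` and `exp(p/a)` for `p < 0`; the derivative is
#' continuous (both branches give 1 at `p = 0`).
#'
#' @inheritParams firing_rate
#' @return Vector of derivatives, elementwise.
#' @export
firing_rate_grad <- function(p, a = 0.1) {
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a <= 0)
    stop("rate-function constant a must be a single value > 0")
  ifelse(p >= 0, 1, exp(p / a))
}

#' Relax a recurrent network to its stable state
#'
#' Integrates the coupled shunting dynamics
#' \deqn{\dot p = -\alpha p + (\beta - p)\,I^{ex}(1 + \gamma I^{mod})
#'       - (\zeta + p)\,I^{inh}}
#' with inputs recomputed from the current rates at every step (see
#' [compute_inputs()]) until the max-norm of \eqn{\dot p} falls below `tol`.
#' The integrator is exponential (per-unit exact for frozen inputs) with step
#' `dt`; it shares the fixed points of the ODE, is stable for arbitrarily
#' strong drive, and keeps potentials inside the shunting bounds
#' `[-zeta, beta]` whenever `i_add = 0`.
#'
#' @param conn A [connection_set()].
#' @param i_inp External input feature vector (length `n_features`).
#' @param params A [unit_params()].
#' @param p0 Initial potentials (default all zero).
#' @param dt Integration step (default 0.1).
#' @param tol Convergence tolerance on the max-norm of `dp/dt` (default 1e-6).
#' @param max_steps Step budget (default 5000).
#' @param i_ex_ext,i_inh_ext Optional extra external excitatory/inhibitory
#'   input per unit (scalar or length `n_units`); used e.g. to clamp
#'   suppression onto gated motor units.
#' @param i_add Optional additive current per unit injected directly into
#'   `dp/dt` (used for sensitivity analyses).
#' @return An object of class `network_state`: a list with the equilibrium
#'   potentials `p`, rates `r`, inputs `i_ex`, `i_inh`, `i_mod`, a `converged`
#'   flag, the final `residual` (max-norm of `dp/dt`) and the number of
#'   `steps` taken.  Non-convergence within `max_steps` is reported through
#'   `converged = FALSE`; the state reached is returned.
#' @examples
#' conn <- connection_set(matrix(0, 1, 1), matrix(0, 1, 1), matrix(0, 1, 1),
#'                        matrix(1, 1, 1))
#' relax_network(conn, i_inp = 1, unit_params())$p  # I/(1+I) = 0.5
#' @export
relax_network <- function(conn, i_inp, params = unit_params(),
                          p0 = NULL, dt = 0.1, tol = 1e-6, max_steps = 5000,
                          i_ex_ext = 0, i_inh_ext = 0, i_add = 0) {
  if (dt <= 0) stop("dt must be > 0")
  if (tol <= 0) stop("tol must be > 0")
  n <- conn$n_units
  if (length(i_inp) != conn$n_features)
    stop("input vector length does not match the number of input features")
  if (is.null(p0)) p0 <- numeric(n)
  ext_ex <- drop(crossprod(conn$w_inp, i_inp)) + rep_len(i_ex_ext, n)
  st <- relax_core(t(conn$w_ex), t(conn$w_inh), t(conn$w_mod),
                   ext_ex, rep_len(i_inh_ext, n), rep_len(i_add, n),
                   params$alpha, params$beta, params$gamma, params$zeta,
                   params$a, p0, dt, tol, as.integer(max_steps))
  st$p <- drop(st$p); st$r <- drop(st$r)
  st$i_ex <- drop(st$i_ex); st$i_inh <- drop(st$i_inh); st$i_mod <- drop(st$i_mod)
  class(st) <- "network_state"
  st
}
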