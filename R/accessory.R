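#' Accessory-network credit propagation (phase 2)
#'
#' After the network has settled (phase 1) and an action `a` has been chosen,
#' the accessory network carries an action-feedback signal backwards through
#' the reciprocal connectivity.  Its steady boost `delta_p[l]` equals the
#' sensitivity of the winning unit's equilibrium potential to a small
#' additive current injected at unit `l`,
#' \eqn{\Delta p_l = \partial p^\infty_a / \partial \xi_l}
#' (proportionality constant fixed to 1).  It is obtained here by solving the
#' adjoint linear system of the dynamics linearized at the equilibrium: with
#' Jacobian `J` of the right-hand side, `delta_p = solve(-t(J), e_a)`.
#'
#' @param conn A [connection_set()].
#' @param state A `network_state` as returned by [relax_network()]; must hold
#'   the equilibrium inputs (`i_ex`, `i_inh`, `i_mod`).
#' @param params A [unit_params()].
#' @param action Index of the winning output unit.
#' @return An object of class `accessory_state`: list with `delta_p` (per-unit
#'   boost vector) and `action`.
#' @details An ill-conditioned linearization (non-hyperbolic equilibrium)
#'   signals an error of class `revlearn_singular_equilibrium`; callers may
#'   catch it and skip the weight update for that trial.
#' @export
propagate_accessory <- function(conn, state, params, action) {
  n <- conn$n_units
  if (length(action) != 1 || action < 1 || action > n)
    stop("action must be a single unit index")
  # solves the adjoint of the Jacobian
  #   d(dp_i/dt)/dp_j = -delta_ij (alpha + Iex_i (1 + g Imod_i) + Iinh_i)
  #     + g'(p_j) [ (b - p_i)(1 + g Imod_i) Wex[j,i]
  #                 + g (b - p_i) Iex_i Wmod[j,i] - (z + p_i) Winh[j,i] ]
  delta_p <- tryCatch(
    drop(accessory_core(conn$w_ex, conn$w_inh, conn$w_mod, state$p,
                        state$i_ex, state$i_inh, state$i_mod,
                        params$alpha, params$beta, params$gamma,
                        params$zeta, params$a, as.integer(action))),
    error = function(e) {
      stop(structure(class = c("revlearn_singular_equilibrium", "error",
                               "condition"),
                     list(message = paste("non-hyperbolic equilibrium:",
                                          conditionMessage(e)),
                          call = sys.call(-1))))
    })
  structure(list(delta_p = delta_p, action = action),
            class = "accessory_state")
}
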