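# Small hand-built networks and oracles shared across test files.

zero_mat <- function(n) matrix(0, n, n)

# A connection set with explicit matrices and all-permissive masks.
small_conn <- function(w_ex = NULL, w_inh = NULL, w_mod = NULL,
                       w_inp = NULL, n = 2, n_feat = 1, max_weight = 4) {
  ones <- matrix(1, n, n)
  connection_set(
    w_ex = if (is.null(w_ex)) zero_mat(n) else w_ex,
    w_inh = if (is.null(w_inh)) zero_mat(n) else w_inh,
    w_mod = if (is.null(w_mod)) zero_mat(n) else w_mod,
    w_inp = if (is.null(w_inp)) matrix(0, n_feat, n) else w_inp,
    mask_ex = ones, mask_inh = ones, mask_mod = ones,
    mask_inp = matrix(1, n_feat, n), max_weight = max_weight)
}

# Random network with mixed connection types, no self-connections.
random_conn <- function(n, n_feat = 3, density = 0.4, scale = 0.4) {
  mk <- function(dens, mx) {
    m <- matrix(runif(n * n) * mx * (runif(n * n) < dens), n, n)
    diag(m) <- 0
    m
  }
  connection_set(mk(density, scale), mk(density, 0.3 * scale),
                 mk(density, 0.5 * scale),
                 matrix(runif(n_feat * n) * scale, n_feat, n))
}

# Finite-difference oracle for the sensitivity of unit `a`'s equilibrium
# potential to additive current injections (independent of the adjoint path).
fd_sensitivity <- function(conn, i_inp, up, a, eps = 1e-5) {
  n <- conn$n_units
  vapply(seq_len(n), function(l) {
    e <- numeric(n); e[l] <- eps
    pp <- relax_network(conn, i_inp, up, i_add = e, tol = 1e-11)$p[a]
    pm <- relax_network(conn, i_inp, up, i_add = -e, tol = 1e-11)$p[a]
    (pp - pm) / (2 * eps)
  }, numeric(1))
}
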