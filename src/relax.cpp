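#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Piecewise-smooth rate function: a + p for p >= 0, a * exp(p / a) for p < 0.
static vec rate_fun(const vec &p, double a) {
  vec r(p.n_elem);
  for (uword i = 0; i < p.n_elem; ++i)
    r[i] = (p[i] >= 0.0) ? (a + p[i]) : (a * std::exp(p[i] / a));
  return r;
}

// Relax the shunting network
//   dp/dt = -alpha p + (beta - p) Iex (1 + gamma Imod) - (zeta + p) Iinh + ext_add
// to its stable state.  Inputs are recomputed from the current rates every
// step (fully coupled system).  The update is an exponential integrator: with
// inputs frozen during one step the equation is linear in p,
//   dp/dt = s - q p,  q = alpha + Iex (1 + gamma Imod) + Iinh,
//                     s = beta Iex (1 + gamma Imod) - zeta Iinh + ext_add,
// which is integrated exactly over dt.  The iteration has the same fixed
// points as the ODE, is stable for arbitrarily strong drive, and keeps p
// inside the shunting bounds whenever ext_add = 0 and p0 starts inside them.
//
// Weight matrices are passed pre-transposed (unit k -> unit l convention, so
// inputs to unit l are column l of W, i.e. row l of W^T) and converted to
// sparse storage once per call; the structural masks make them ~99% zero.
// [[Rcpp::export]]
Rcpp::List relax_core(const Rcpp::NumericMatrix &wexT,
                      const Rcpp::NumericMatrix &winhT,
                      const Rcpp::NumericMatrix &wmodT, const arma::vec &ext_ex,
                      const arma::vec &ext_inh, const arma::vec &ext_add,
                      double alpha, double beta, double gamma_, double zeta,
                      double a, const arma::vec &p0, double dt, double tol,
                      int max_steps) {
  const mat exT(const_cast<double *>(wexT.begin()), wexT.nrow(), wexT.ncol(),
                false, true);
  const mat inhT(const_cast<double *>(winhT.begin()), winhT.nrow(),
                 winhT.ncol(), false, true);
  const mat modT(const_cast<double *>(wmodT.begin()), wmodT.nrow(),
                 wmodT.ncol(), false, true);
  const sp_mat Wex(exT), Winh(inhT), Wmod(modT);
  vec p = p0;
  vec E, H, M;
  double resid = datum::inf;
  bool conv = false;
  int steps = 0;

  for (;;) {
    vec r = rate_fun(p, a);
    E = Wex * r + ext_ex;
    H = Winh * r + ext_inh;
    M = Wmod * r;
    vec drive = E % (1.0 + gamma_ * M);
    vec q = alpha + drive + H;
    vec s = beta * drive - zeta * H + ext_add;
    vec dp = s - q % p;
    resid = norm(dp, "inf");
    if (resid < tol) {
      conv = true;
      break;
    }
    if (steps >= max_steps)
      break;
    vec pinf = s / q;
    p = pinf + (p - pinf) % exp(-q * dt);
    ++steps;
  }

  return Rcpp::List::create(
      Rcpp::Named("p") = p, Rcpp::Named("r") = rate_fun(p, a),
      Rcpp::Named("i_ex") = E, Rcpp::Named("i_inh") = H,
      Rcpp::Named("i_mod") = M, Rcpp::Named("converged") = conv,
      Rcpp::Named("residual") = resid, Rcpp::Named("steps") = steps);
}

// Adjoint solve of the dynamics linearized at the equilibrium: returns the
// sensitivity of unit `action`'s equilibrium potential to additive current
// at every unit, delta_p = solve(-J^T, e_action), with
// J[i,j] = -delta_ij (alpha + Iex_i (1+g Imod_i) + Iinh_i)
//          + g'(p_j) [ c_ex_i Wex[j,i] + c_mod_i Wmod[j,i] - c_inh_i Winh[j,i] ].
// [[Rcpp::export]]
arma::vec accessory_core(const Rcpp::NumericMatrix &wex_,
                         const Rcpp::NumericMatrix &winh_,
                         const Rcpp::NumericMatrix &wmod_, const arma::vec &p,
                         const arma::vec &i_ex, const arma::vec &i_inh,
                         const arma::vec &i_mod, double alpha, double beta,
                         double gamma_, double zeta, double a, int action) {
  const uword n = p.n_elem;
  const mat wex(const_cast<double *>(wex_.begin()), n, n, false, true);
  const mat winh(const_cast<double *>(winh_.begin()), n, n, false, true);
  const mat wmod(const_cast<double *>(wmod_.begin()), n, n, false, true);
  vec gp(n);
  for (uword j = 0; j < n; ++j)
    gp[j] = (p[j] >= 0.0) ? 1.0 : std::exp(p[j] / a);
  vec c_ex = (beta - p) % (1.0 + gamma_ * i_mod);
  vec c_mod = gamma_ * (beta - p) % i_ex;
  vec c_inh = zeta + p;
  vec diag_term = -(alpha + i_ex % (1.0 + gamma_ * i_mod) + i_inh);

  // build J^T directly: J^T[j,i] = J[i,j], with W[j,i] = strength j -> i
  mat JT(n, n);
  for (uword i = 0; i < n; ++i) {
    for (uword j = 0; j < n; ++j)
      JT(j, i) = gp[j] * (c_ex[i] * wex(j, i) + c_mod[i] * wmod(j, i) -
                          c_inh[i] * winh(j, i));
    JT(i, i) += diag_term[i];
  }
  vec e(n, fill::zeros);
  e[action - 1] = 1.0;
  return solve(-JT, e);
}

// Fused three-factor update for one connection matrix:
//   v <- momentum * v + delta * (pre %o% post) * mask
//   w <- clip(w + eta * v, 0, max_w) * mask
// [[Rcpp::export]]
Rcpp::List update_core(const Rcpp::NumericMatrix &w,
                       const Rcpp::NumericMatrix &v,
                       const Rcpp::NumericMatrix &mask,
                       const Rcpp::NumericVector &pre,
                       const Rcpp::NumericVector &post, double delta,
                       double eta, double momentum, double max_w) {
  const R_xlen_t nr = w.nrow(), nc = w.ncol();
  Rcpp::NumericMatrix w2(nr, nc), v2(nr, nc);
  const double *pw = w.begin(), *pv = v.begin(), *pm = mask.begin();
  double *qw = w2.begin(), *qv = v2.begin();
  for (R_xlen_t j = 0; j < nc; ++j) {
    const double pj = post[j] * delta;
    const R_xlen_t off = j * nr;
    for (R_xlen_t i = 0; i < nr; ++i) {
      const R_xlen_t k = off + i;
      if (pm[k] == 0.0) {
        qv[k] = momentum * pv[k];
        qw[k] = 0.0;
      } else {
        double nv = momentum * pv[k] + pj * pre[i];
        double nw = pw[k] + eta * nv;
        qv[k] = nv;
        qw[k] = nw < 0.0 ? 0.0 : (nw > max_w ? max_w : nw);
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("w") = w2, Rcpp::Named("v") = v2);
}
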