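// Training hot loop for the PINN engine.
//
// The network is a tanh MLP with one input (time). The physics loss needs
// the exact derivative of the network output with respect to t, so the
// forward pass propagates a tangent (forward-mode) alongside the values,
// and the backward pass differentiates through both. The math mirrors the
// reference R implementation in R/losses.R, which serves as the generic
// (non-compiled) path for user-defined systems; the two are cross-checked
// in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// ---- built-in ODE systems --------------------------------------------------
// theta layout: logistic (r, K); gene_binding (k_on, k_off)

static void rhs_eval(const std::string& id, const mat& U, const vec& theta,
                     mat& F) {
  if (id == "logistic") {
    const double r = theta[0], K = theta[1];
    F = r * U % (1.0 - U / K);
  } else if (id == "gene_binding") {
    rowvec flux = theta[0] * (U.row(0) % U.row(1)) - theta[1] * U.row(2);
    F.set_size(3, U.n_cols);
    F.row(0) = -flux;
    F.row(1) = -flux;
    F.row(2) = flux;
  } else {
    Rcpp::stop("unknown built-in system id: %s", id);
  }
}

// V = J^T R columnwise, J the state Jacobian of the rhs
static void vjp_eval(const std::string& id, const mat& U, const vec& theta,
                     const mat& R, mat& V) {
  if (id == "logistic") {
    const double r = theta[0], K = theta[1];
    V = R % (r * (1.0 - 2.0 * U / K));
  } else {
    rowvec s = -R.row(0) - R.row(1) + R.row(2);
    V.set_size(3, U.n_cols);
    V.row(0) = theta[0] * (U.row(1) % s);
    V.row(1) = theta[0] * (U.row(0) % s);
    V.row(2) = -theta[1] * s;
  }
}

// g_j = sum over entries of R % df/dtheta_j
static vec param_grad_eval(const std::string& id, const mat& U,
                           const vec& theta, const mat& R) {
  vec g(2);
  if (id == "logistic") {
    const double r = theta[0], K = theta[1];
    g[0] = accu(R % (U % (1.0 - U / K)));
    g[1] = accu(R % (r * (U % U) / (K * K)));
  } else {
    rowvec s = -R.row(0) - R.row(1) + R.row(2);
    g[0] = accu((U.row(0) % U.row(1)) % s);
    g[1] = -accu(U.row(2) % s);
  }
  return g;
}

// ---- output transforms -----------------------------------------------------
// type: 0 identity, 1 constant scale, 2 softplus

static void transform_eval(int type, double scale, const mat& Y,
                           mat& U, mat& D1, mat& D2, bool need_d) {
  switch (type) {
  case 0:
    U = Y;
    if (need_d) { D1.ones(size(Y)); D2.zeros(size(Y)); }
    break;
  case 1:
    U = scale * Y;
    if (need_d) { D1.set_size(size(Y)); D1.fill(scale); D2.zeros(size(Y)); }
    break;
  default: {
    mat S = 1.0 / (1.0 + exp(-Y));
    U = Y;
    U.transform([](double y) { return y > 30.0 ? y : std::log1p(std::exp(y)); });
    U *= scale;
    if (need_d) { D1 = scale * S; D2 = scale * (S % (1.0 - S)); }
  }
  }
}

// ---- training chunk --------------------------------------------------------

// Runs `iterations` full-batch Adam steps starting at global iteration
// iter_offset + 1. Loss components are logged whenever the global iteration
// is a multiple of log_every or equals total_iterations. Returns updated
// weights, ODE parameters, Adam state, the log rows, and the weights at the
// best logged step of this chunk.
// [[Rcpp::export(name = ".cpp_train_chunk")]]
Rcpp::List cpp_train_chunk(Rcpp::List weights_in, Rcpp::NumericVector theta_in,
                           Rcpp::IntegerVector trainable_idx1,
                           std::string system_id,
                           Rcpp::NumericVector t_all_in,
                           int m_d, int m_i, int m_c,
                           Rcpp::NumericMatrix y_obs_in,
                           Rcpp::NumericVector ic_in,
                           Rcpp::NumericVector loss_w_in,
                           double t_scale, int transform_type,
                           double out_scale,
                           int iterations, int iter_offset,
                           int total_iterations,
                           double lr, int log_every,
                           Rcpp::IntegerVector theta_log_in,
                           Rcpp::List adam_in) {
  const int L = weights_in.size();
  std::vector<mat> W(L); std::vector<vec> b(L);
  for (int l = 0; l < L; ++l) {
    Rcpp::List layer = weights_in[l];
    W[l] = Rcpp::as<mat>(layer["W"]);
    b[l] = Rcpp::as<vec>(layer["b"]);
  }
  vec theta = Rcpp::as<vec>(theta_in);
  // positive-flagged parameters take multiplicative (log-space) Adam steps
  ivec theta_log = Rcpp::as<ivec>(theta_log_in);
  uvec tidx = Rcpp::as<uvec>(trainable_idx1);  // 1-based from R
  if (tidx.n_elem) tidx -= 1;
  const int n_theta = static_cast<int>(tidx.n_elem);

  vec t_all = Rcpp::as<vec>(t_all_in);
  const int m = static_cast<int>(t_all.n_elem);
  const int D = static_cast<int>(W[L - 1].n_rows);
  const bool tangent = m_c > 0;
  const bool have_ic = m_i > 0;
  mat y_obs;
  if (m_d > 0) y_obs = Rcpp::as<mat>(y_obs_in);  // D x m_d
  vec ic;
  if (have_ic) ic = Rcpp::as<vec>(ic_in);
  vec loss_w = Rcpp::as<vec>(loss_w_in);

  // Adam state
  std::vector<mat> mW(L), vW(L);
  std::vector<vec> mb(L), vb(L);
  vec mT(std::max(n_theta, 1), fill::zeros), vT(std::max(n_theta, 1), fill::zeros);
  if (adam_in.size() > 0) {
    Rcpp::List aw = adam_in["w"];
    for (int l = 0; l < L; ++l) {
      Rcpp::List st = aw[l];
      mW[l] = Rcpp::as<mat>(st["mW"]); vW[l] = Rcpp::as<mat>(st["vW"]);
      mb[l] = Rcpp::as<vec>(st["mb"]); vb[l] = Rcpp::as<vec>(st["vb"]);
    }
    mT = Rcpp::as<vec>(adam_in["mT"]); vT = Rcpp::as<vec>(adam_in["vT"]);
  } else {
    for (int l = 0; l < L; ++l) {
      mW[l].zeros(size(W[l])); vW[l].zeros(size(W[l]));
      mb[l].zeros(b[l].n_elem); vb[l].zeros(b[l].n_elem);
    }
  }
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;

  // logging
  const int max_rows = iterations / std::max(log_every, 1) + 2;
  mat log_rows(max_rows, 5 + n_theta);
  int n_logged = 0;
  double best_total = datum::inf;
  int best_row = -1;
  std::vector<mat> bestW = W; std::vector<vec> bestb = b; vec best_theta = theta;

  // work buffers (sized on first use, then reused across iterations)
  std::vector<mat> X(L + 1), Xdot(L + 1), Z(L), Zdot(L), S(L);
  mat Y, Ydot, U, Udot, D1, D2, F, Rc, V;
  mat Ubar(D, m), Udotbar, Ybar, Ydotbar, Abar, Adotbar, Zbar, Zdotbar;
  if (tangent) Udotbar.set_size(D, m);
  std::vector<mat> gW(L); std::vector<vec> gb(L);

  const rowvec t_row = conv_to<rowvec>::from(t_all);
  const uword c0 = m_d + m_i;  // first collocation column

  // the (scaled) input row and its tangent seed are constant
  X[0] = t_row / t_scale;
  if (tangent) { Xdot[0].set_size(1, m); Xdot[0].fill(1.0 / t_scale); }

  for (int it_local = 1; it_local <= iterations; ++it_local) {
    const int it = iter_offset + it_local;  // global iteration
    if (it_local % 1000 == 0) Rcpp::checkUserInterrupt();

    // forward + tangent
    for (int l = 0; l < L - 1; ++l) {
      Z[l] = W[l] * X[l];
      Z[l].each_col() += b[l];
      X[l + 1] = tanh(Z[l]);
      if (tangent) {
        S[l] = 1.0 - square(X[l + 1]);   // tanh'
        Zdot[l] = W[l] * Xdot[l];
        Xdot[l + 1] = S[l] % Zdot[l];
      }
    }
    Y = W[L - 1] * X[L - 1];
    Y.each_col() += b[L - 1];
    if (tangent) Ydot = W[L - 1] * Xdot[L - 1];
    transform_eval(transform_type, out_scale, Y, U, D1, D2, true);
    if (tangent) Udot = D1 % Ydot;

    // losses and output adjoints
    double L_data = 0, L_ic = 0, L_phys = 0;
    Ubar.zeros();
    if (tangent) Udotbar.zeros();
    if (m_d > 0) {
      mat Rd = U.cols(0, m_d - 1) - y_obs;
      L_data = accu(square(Rd)) / (m_d * D);
      Ubar.cols(0, m_d - 1) = (loss_w[0] * 2.0 / (m_d * D)) * Rd;
    }
    if (have_ic) {
      vec Ri = U.col(m_d) - ic;
      L_ic = accu(square(Ri)) / D;
      Ubar.col(m_d) += (loss_w[1] * 2.0 / D) * Ri;
    }
    vec g_theta(std::max(n_theta, 1), fill::zeros);
    if (tangent) {
      mat Uc = U.cols(c0, m - 1);
      rhs_eval(system_id, Uc, theta, F);
      Rc = Udot.cols(c0, m - 1) - F;
      L_phys = accu(square(Rc)) / (m_c * D);
      const double sc = loss_w[2] * 2.0 / (m_c * D);
      Udotbar.cols(c0, m - 1) = sc * Rc;
      vjp_eval(system_id, Uc, theta, Rc, V);
      Ubar.cols(c0, m - 1) -= sc * V;
      if (n_theta > 0) {
        vec gp = param_grad_eval(system_id, Uc, theta, Rc);
        for (int j = 0; j < n_theta; ++j) g_theta[j] = -sc * gp[tidx[j]];
      }
    }
    const double total = loss_w[0] * L_data + loss_w[1] * L_ic + loss_w[2] * L_phys;
    if (!std::isfinite(total)) {
      std::string bad;
      if (!std::isfinite(L_data)) bad += " data";
      if (!std::isfinite(L_ic)) bad += " ic";
      if (!std::isfinite(L_phys)) bad += " physics";
      Rcpp::stop("non-finite loss at iteration %d (component:%s)", it,
                 bad.empty() ? " total" : bad.c_str());
    }

    // backward through the output transform and the linear output layer
    if (tangent) {
      Ybar = D1 % Ubar + D2 % Ydot % Udotbar;
      Ydotbar = D1 % Udotbar;
    } else {
      Ybar = D1 % Ubar;
    }
    gW[L - 1] = Ybar * X[L - 1].t();
    if (tangent) gW[L - 1] += Ydotbar * Xdot[L - 1].t();
    gb[L - 1] = sum(Ybar, 1);
    Abar = W[L - 1].t() * Ybar;
    if (tangent) Adotbar = W[L - 1].t() * Ydotbar;

    // hidden layers, deepest first
    for (int l = L - 2; l >= 0; --l) {
      const mat& A = X[l + 1];
      if (tangent) {
        // tanh'' = -2 tanh tanh'; S and Zdot were stored by the forward pass
        Zbar = S[l] % Abar - 2.0 * (A % S[l]) % Zdot[l] % Adotbar;
        Zdotbar = S[l] % Adotbar;
      } else {
        Zbar = (1.0 - square(A)) % Abar;
      }
      gW[l] = Zbar * X[l].t();
      if (tangent) gW[l] += Zdotbar * Xdot[l].t();
      gb[l] = sum(Zbar, 1);
      if (l > 0) {
        Abar = W[l].t() * Zbar;
        if (tangent) Adotbar = W[l].t() * Zdotbar;
      }
    }

    // Adam (bias-corrected)
    const double bc1 = 1.0 - std::pow(beta1, it);
    const double bc2 = 1.0 - std::pow(beta2, it);
    for (int l = 0; l < L; ++l) {
      mW[l] = beta1 * mW[l] + (1.0 - beta1) * gW[l];
      vW[l] = beta2 * vW[l] + (1.0 - beta2) * square(gW[l]);
      W[l] -= lr * (mW[l] / bc1) / (sqrt(vW[l] / bc2) + eps);
      mb[l] = beta1 * mb[l] + (1.0 - beta1) * gb[l];
      vb[l] = beta2 * vb[l] + (1.0 - beta2) * square(gb[l]);
      b[l] -= lr * (mb[l] / bc1) / (sqrt(vb[l] / bc2) + eps);
    }
    if (n_theta > 0) {
      for (int j = 0; j < n_theta; ++j) {
        const bool in_log = theta_log[tidx[j]] != 0;
        double g = g_theta[j];
        if (in_log) g *= theta[tidx[j]];  // chain rule: d/d(log theta)
        mT[j] = beta1 * mT[j] + (1.0 - beta1) * g;
        vT[j] = beta2 * vT[j] + (1.0 - beta2) * g * g;
        const double step = lr * (mT[j] / bc1) / (std::sqrt(vT[j] / bc2) + eps);
        if (in_log) theta[tidx[j]] *= std::exp(-step);
        else theta[tidx[j]] -= step;
      }
    }

    if (it % log_every == 0 || it == total_iterations) {
      log_rows(n_logged, 0) = it;
      log_rows(n_logged, 1) = L_data;
      log_rows(n_logged, 2) = L_ic;
      log_rows(n_logged, 3) = L_phys;
      log_rows(n_logged, 4) = total;
      for (int j = 0; j < n_theta; ++j)
        log_rows(n_logged, 5 + j) = theta[tidx[j]];
      if (total < best_total) {
        best_total = total;
        best_row = n_logged;
        bestW = W; bestb = b; best_theta = theta;
      }
      ++n_logged;
    }
  }

  Rcpp::List weights_out(L), adam_w(L), best_weights(L);
  for (int l = 0; l < L; ++l) {
    weights_out[l] = Rcpp::List::create(Rcpp::Named("W") = W[l],
                                        Rcpp::Named("b") = b[l]);
    best_weights[l] = Rcpp::List::create(Rcpp::Named("W") = bestW[l],
                                         Rcpp::Named("b") = bestb[l]);
    adam_w[l] = Rcpp::List::create(Rcpp::Named("mW") = mW[l],
                                   Rcpp::Named("vW") = vW[l],
                                   Rcpp::Named("mb") = mb[l],
                                   Rcpp::Named("vb") = vb[l]);
  }
  return Rcpp::List::create(
    Rcpp::Named("weights") = weights_out,
    Rcpp::Named("theta") = theta,
    Rcpp::Named("adam") = Rcpp::List::create(Rcpp::Named("w") = adam_w,
                                             Rcpp::Named("mT") = mT,
                                             Rcpp::Named("vT") = vT),
    Rcpp::Named("log") = (n_logged > 0 ? mat(log_rows.rows(0, n_logged - 1))
                                       : mat(0, 5 + n_theta)),
    Rcpp::Named("n_logged") = n_logged,
    Rcpp::Named("best_total") = best_total,
    Rcpp::Named("best_row") = best_row + 1,
    Rcpp::Named("best_weights") = best_weights,
    Rcpp::Named("best_theta") = best_theta);
}
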