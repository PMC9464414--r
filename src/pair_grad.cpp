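// Fused forward + backward pass for one protein pair, and the Adam epoch
// loop built on it.
//
// Per pair, computes the binary cross-entropy loss of the mutual-attention
// classifier and the analytic gradient with respect to every parameter
// block, flattened in the same order as the R-level flatten_params():
// W_1..W_l, U, V, w, Fw, Fb (column-major). The R forward pass
// (gcn_forward / attention_scores / knowledge_select / classify) is the
// reference; tests check these routines against it and against central
// finite differences.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec softmax_stable(const vec& z) {
  vec e = exp(z - z.max());
  return e / accu(e);
}

// Forward + backward for one example; grad is accumulated into `grad`
// (zeroed here). Returns the loss.
static double pair_grad_core(const mat& Atil1, const mat& X01,
                             const mat& Atil2, const mat& X02,
                             const std::vector<mat>& W, const mat& U,
                             const mat& V, const vec& w, const mat& Fw,
                             const vec& Fb, const int label, vec& grad,
                             vec* y_out) {
  const int l = W.size();
  const int d = w.n_elem;
  const int N1 = X01.n_rows, N2 = X02.n_rows;

  // --- forward: shared-weight GCN on both proteins ---
  std::vector<std::vector<mat>> Xs(2), Zs(2);
  const mat* Atils[2] = { &Atil1, &Atil2 };
  const mat* X0s[2] = { &X01, &X02 };
  for (int m = 0; m < 2; ++m) {
    Xs[m].resize(l + 1);
    Zs[m].resize(l);
    Xs[m][0] = *X0s[m];
    for (int t = 0; t < l; ++t) {
      Zs[m][t] = (*Atils[m]) * Xs[m][t];
      Xs[m][t + 1] = clamp(Zs[m][t] * W[t], 0.0, datum::inf);
    }
  }
  const mat& h1 = Xs[0][l];
  const mat& h2 = Xs[1][l];

  // --- forward: mutual attention and knowledge selection ---
  mat P = h1 * U.t();  // N1 x d, row i = (U h1_i)'
  mat Q = h2 * V.t();  // N2 x d
  cube Tc(N1, d, N2);
  mat alpha(N1, N2);
  for (int j = 0; j < N2; ++j) {
    mat M = tanh(P.each_row() + Q.row(j));
    Tc.slice(j) = M;
    alpha.col(j) = M * w;
  }

  vec eta1 = mean(alpha, 1);
  vec eta2 = mean(alpha, 0).t();
  vec p1 = softmax_stable(eta1);
  vec p2 = softmax_stable(eta2);
  vec s1 = h1.t() * p1;
  vec s2 = h2.t() * p2;
  vec sv = join_cols(s1, s2);
  vec y = softmax_stable(Fw * sv + Fb);
  double loss = -std::log(std::max(y(label), 1e-12));
  if (y_out) *y_out = y;

  // --- backward ---
  vec dz = y;
  dz(label) -= 1.0;
  mat gFw = dz * sv.t();
  vec dsv = Fw.t() * dz;
  vec ds1 = dsv.head(d), ds2 = dsv.tail(d);

  vec dp1 = h1 * ds1;
  vec dp2 = h2 * ds2;
  mat dh1 = p1 * ds1.t();
  mat dh2 = p2 * ds2.t();
  vec deta1 = p1 % (dp1 - dot(p1, dp1));
  vec deta2 = p2 % (dp2 - dot(p2, dp2));

  mat dalpha = repmat(deta1 / N2, 1, N2);
  dalpha.each_row() += (deta2 / N1).t();

  vec gw(d, fill::zeros);
  mat dP(N1, d, fill::zeros);
  mat dQ(N2, d, fill::zeros);
  for (int j = 0; j < N2; ++j) {
    const mat& M = Tc.slice(j);
    gw += M.t() * dalpha.col(j);
    mat dPre = (dalpha.col(j) * w.t()) % (1.0 - M % M);
    dP += dPre;
    dQ.row(j) = sum(dPre, 0);
  }
  mat gU = dP.t() * h1;
  mat gV = dQ.t() * h2;
  dh1 += dP * U;
  dh2 += dQ * V;

  std::vector<mat> gW(l);
  for (int t = 0; t < l; ++t) gW[t].zeros(d, d);
  mat* dhs[2] = { &dh1, &dh2 };
  for (int m = 0; m < 2; ++m) {
    mat dX = *dhs[m];
    for (int t = l - 1; t >= 0; --t) {
      mat dPre = dX % conv_to<mat>::from(Xs[m][t + 1] > 0.0);
      gW[t] += Zs[m][t].t() * dPre;
      if (t > 0) dX = (*Atils[m]).t() * (dPre * W[t].t());
    }
  }

  // --- flatten gradient in the R-side parameter order ---
  grad.set_size(l * d * d + 2 * d * d + d + Fw.n_elem + 2);
  uword pos = 0;
  for (int t = 0; t < l; ++t) {
    grad.subvec(pos, pos + d * d - 1) = vectorise(gW[t]);
    pos += d * d;
  }
  grad.subvec(pos, pos + d * d - 1) = vectorise(gU); pos += d * d;
  grad.subvec(pos, pos + d * d - 1) = vectorise(gV); pos += d * d;
  grad.subvec(pos, pos + d - 1) = gw; pos += d;
  grad.subvec(pos, pos + Fw.n_elem - 1) = vectorise(gFw); pos += Fw.n_elem;
  grad.subvec(pos, pos + 1) = dz;
  return loss;
}

// [[Rcpp::export(name = "pair_grad_cpp")]]
Rcpp::List pair_grad_cpp(const arma::mat& Atil1, const arma::mat& X01,
                         const arma::mat& Atil2, const arma::mat& X02,
                         const Rcpp::List& Wlist, const arma::mat& U,
                         const arma::mat& V, const arma::vec& w,
                         const arma::mat& Fw, const arma::vec& Fb,
                         const int label) {
  std::vector<mat> W(Wlist.size());
  for (int t = 0; t < (int)W.size(); ++t) W[t] = Rcpp::as<mat>(Wlist[t]);
  vec grad, y;
  double loss = pair_grad_core(Atil1, X01, Atil2, X02, W, U, V, w, Fw, Fb,
                               label, grad, &y);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("y") = y,
                            Rcpp::Named("grad") = grad);
}

// One epoch of Adam with per-pair (batch size 1) updates over an already
// sampled sequence of examples. X0s/Atils are per-structure feature lists;
// i1/i2/labels describe the sampled pairs (1-based structure indices).
// theta/mstate/vstate are the flat parameter and Adam moment vectors; step
// is the update counter before this epoch. Returns updated state and the
// epoch mean loss.
// [[Rcpp::export(name = "epoch_train_cpp")]]
Rcpp::List epoch_train_cpp(const Rcpp::List& X0s, const Rcpp::List& Atils,
                           const arma::ivec& i1, const arma::ivec& i2,
                           const arma::ivec& labels, const arma::vec& theta0,
                           const arma::vec& m0, const arma::vec& v0,
                           const int step0, const double lr, const int l,
                           const int d, const double b1, const double b2,
                           const double eps) {
  const int n_struct = X0s.size();
  std::vector<mat> X0(n_struct), Atil(n_struct);
  for (int i = 0; i < n_struct; ++i) {
    X0[i] = Rcpp::as<mat>(X0s[i]);
    Atil[i] = Rcpp::as<mat>(Atils[i]);
  }

  vec theta = theta0, mstate = m0, vstate = v0;
  int step = step0;
  double total_loss = 0.0;

  // parameter blocks viewed out of theta each step (theta is small)
  std::vector<mat> W(l);
  mat U(d, d), V(d, d), Fw(2, 2 * d);
  vec w(d), Fb(2);
  vec grad;

  for (uword q = 0; q < i1.n_elem; ++q) {
    uword pos = 0;
    for (int t = 0; t < l; ++t) {
      W[t] = reshape(theta.subvec(pos, pos + d * d - 1), d, d);
      pos += d * d;
    }
    U = reshape(theta.subvec(pos, pos + d * d - 1), d, d); pos += d * d;
    V = reshape(theta.subvec(pos, pos + d * d - 1), d, d); pos += d * d;
    w = theta.subvec(pos, pos + d - 1); pos += d;
    Fw = reshape(theta.subvec(pos, pos + 2 * d * 2 - 1), 2, 2 * d);
    pos += 2 * d * 2;
    Fb = theta.subvec(pos, pos + 1);

    const int a = i1(q) - 1, b = i2(q) - 1;
    total_loss += pair_grad_core(Atil[a], X0[a], Atil[b], X0[b], W, U, V, w,
                                 Fw, Fb, labels(q), grad, nullptr);
    ++step;
    mstate = b1 * mstate + (1.0 - b1) * grad;
    vstate = b2 * vstate + (1.0 - b2) * square(grad);
    vec mhat = mstate / (1.0 - std::pow(b1, step));
    vec vhat = vstate / (1.0 - std::pow(b2, step));
    theta -= lr * mhat / (sqrt(vhat) + eps);
  }

  return Rcpp::List::create(Rcpp::Named("theta") = theta,
                            Rcpp::Named("m") = mstate,
                            Rcpp::Named("v") = vstate,
                            Rcpp::Named("step") = step,
                            Rcpp::Named("mean_loss") = total_loss / i1.n_elem);
}
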