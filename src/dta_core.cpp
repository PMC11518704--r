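// Compiled core of the bilinear attention drug-target network: forward pass
// and reverse-mode gradients for one (molecule graph, protein sequence)
// pair, plus batch accumulation. Mirrors the architecture documented in
// R/dta_model.R; all state lives in the R parameter list, so the C++ layer
// is stateless and deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;
using arma::uvec;

static mat relu(const mat& x) { return arma::clamp(x, 0.0, arma::datum::inf); }

struct Params {
  mat W0;
  std::vector<mat> Wg;
  mat Ep;
  std::vector<mat> Cw;
  std::vector<rowvec> Cb;
  mat U, V;
  rowvec q;
  mat Wc1;
  rowvec bc1;
  vec wc2;
  double bc2;
};

static Params unpack(const List& p) {
  Params P;
  P.W0 = as<mat>(p["W0"]);
  List wg = p["Wg"], cw = p["Cw"], cb = p["Cb"];
  for (int l = 0; l < 3; ++l) {
    P.Wg.push_back(as<mat>(wg[l]));
    P.Cw.push_back(as<mat>(cw[l]));
    P.Cb.push_back(as<rowvec>(cb[l]));
  }
  P.Ep = as<mat>(p["Ep"]);
  P.U = as<mat>(p["U"]);
  P.V = as<mat>(p["V"]);
  P.q = as<rowvec>(p["q"]);
  P.Wc1 = as<mat>(p["Wc1"]);
  P.bc1 = as<rowvec>(p["bc1"]);
  P.wc2 = as<vec>(p["wc2"]);
  P.bc2 = as<double>(p["bc2"]);
  return P;
}

static mat im2col(const mat& X, int k) {
  int L = (int)X.n_rows - k + 1;
  if (L < 1) stop("protein too short for convolution kernel %d", k);
  mat Z(L, k * X.n_cols);
  for (int j = 0; j < k; ++j) {
    Z.cols(j * X.n_cols, (j + 1) * X.n_cols - 1) = X.rows(j, j + L - 1);
  }
  return Z;
}

struct Cache {
  mat M, A;
  std::vector<mat> Hs, Ps, Ss;   // Hs has 4 entries
  std::vector<mat> Pin, Zs, Qs;  // Pin has 4 entries
  mat u_pre, u, v_pre, v, uq, alpha, Av;
  rowvec f, z_pre, z;
  double logit, p;
};

static Cache forward(const Params& P, const mat& M, const mat& A,
                     const uvec& prot_idx, const arma::ivec& kernels) {
  Cache c;
  c.M = M; c.A = A;
  c.Hs.resize(4); c.Ps.resize(3); c.Ss.resize(3);
  c.Hs[0] = M * P.W0;
  for (int l = 0; l < 3; ++l) {
    c.Ss[l] = A * c.Hs[l];
    c.Ps[l] = c.Ss[l] * P.Wg[l];
    c.Hs[l + 1] = relu(c.Ps[l]);
  }
  c.Pin.resize(4); c.Zs.resize(3); c.Qs.resize(3);
  c.Pin[0] = P.Ep.rows(prot_idx);
  for (int l = 0; l < 3; ++l) {
    c.Zs[l] = im2col(c.Pin[l], kernels[l]);
    c.Qs[l] = c.Zs[l] * P.Cw[l];
    c.Qs[l].each_row() += P.Cb[l];
    c.Pin[l + 1] = relu(c.Qs[l]);
  }
  c.u_pre = c.Hs[3] * P.U; c.u = relu(c.u_pre);
  c.v_pre = c.Pin[3] * P.V; c.v = relu(c.v_pre);
  c.uq = c.u; c.uq.each_row() %= P.q;
  mat Lm = c.uq * c.v.t();
  c.alpha = arma::exp(Lm - Lm.max());
  c.alpha /= arma::accu(c.alpha);
  c.Av = c.alpha * c.v;
  c.f = arma::sum(c.u % c.Av, 0);
  c.z_pre = c.f * P.Wc1 + P.bc1;
  c.z = arma::clamp(c.z_pre, 0.0, arma::datum::inf);
  c.logit = arma::dot(c.z, P.wc2) + P.bc2;
  c.p = 1.0 / (1.0 + std::exp(-c.logit));
  return c;
}

struct Grads {
  mat W0;
  std::vector<mat> Wg;
  mat Ep;
  std::vector<mat> Cw;
  std::vector<rowvec> Cb;
  mat U, V;
  rowvec q;
  mat Wc1;
  rowvec bc1;
  vec wc2;
  double bc2;
  void init(const Params& P) {
    W0 = arma::zeros(arma::size(P.W0));
    Ep = arma::zeros(arma::size(P.Ep));
    U = arma::zeros(arma::size(P.U));
    V = arma::zeros(arma::size(P.V));
    q = arma::zeros<rowvec>(P.q.n_elem);
    Wc1 = arma::zeros(arma::size(P.Wc1));
    bc1 = arma::zeros<rowvec>(P.bc1.n_elem);
    wc2 = arma::zeros<vec>(P.wc2.n_elem);
    bc2 = 0.0;
    for (int l = 0; l < 3; ++l) {
      Wg.push_back(arma::zeros(arma::size(P.Wg[l])));
      Cw.push_back(arma::zeros(arma::size(P.Cw[l])));
      Cb.push_back(arma::zeros<rowvec>(P.Cb[l].n_elem));
    }
  }
};

static void backward(const Params& P, const Cache& c, const uvec& prot_idx,
                     const arma::ivec& kernels, double y, double w, Grads& G) {
  int Dp = (int)P.Ep.n_cols;
  double dlogit = w * (c.p - y);

  G.wc2 += dlogit * c.z.t();
  G.bc2 += dlogit;
  rowvec dz = dlogit * P.wc2.t();
  rowvec dz_pre = dz % arma::conv_to<rowvec>::from(c.z_pre > 0);
  G.Wc1 += c.f.t() * dz_pre;
  G.bc1 += dz_pre;
  rowvec df = (P.Wc1 * dz_pre.t()).t();

  mat du = c.Av; du.each_row() %= df;
  mat dAv = c.u; dAv.each_row() %= df;
  mat dalpha = dAv * c.v.t();
  mat dv = c.alpha.t() * dAv;

  double s = arma::accu(c.alpha % dalpha);
  mat dLm = c.alpha % (dalpha - s);

  mat duq = dLm * c.v;
  dv += dLm.t() * c.uq;
  G.q += arma::sum(c.u % duq, 0);
  mat duq_q = duq; duq_q.each_row() %= P.q;
  du += duq_q;

  mat du_pre = du % arma::conv_to<mat>::from(c.u_pre > 0);
  G.U += c.Hs[3].t() * du_pre;
  mat dHd = du_pre * P.U.t();
  mat dv_pre = dv % arma::conv_to<mat>::from(c.v_pre > 0);
  G.V += c.Pin[3].t() * dv_pre;
  mat dPp = dv_pre * P.V.t();

  mat dH = dHd;
  for (int l = 2; l >= 0; --l) {
    mat dP = dH % arma::conv_to<mat>::from(c.Ps[l] > 0);
    G.Wg[l] += c.Ss[l].t() * dP;
    dH = c.A.t() * (dP * P.Wg[l].t());
  }
  G.W0 += c.M.t() * dH;

  mat dP = dPp;
  for (int l = 2; l >= 0; --l) {
    mat dQ = dP % arma::conv_to<mat>::from(c.Qs[l] > 0);
    G.Cw[l] += c.Zs[l].t() * dQ;
    G.Cb[l] += arma::sum(dQ, 0);
    mat dZ = dQ * P.Cw[l].t();
    int k = kernels[l], Lout = (int)dZ.n_rows;
    mat dPin = arma::zeros(c.Pin[l].n_rows, Dp);
    for (int j = 0; j < k; ++j) {
      dPin.rows(j, j + Lout - 1) += dZ.cols(j * Dp, (j + 1) * Dp - 1);
    }
    dP = dPin;
  }
  for (arma::uword i = 0; i < prot_idx.n_elem; ++i) {
    G.Ep.row(prot_idx[i]) += dP.row(i);
  }
}

static List pack_grads(const Grads& G) {
  return List::create(
    Named("W0") = G.W0,
    Named("Wg") = List::create(G.Wg[0], G.Wg[1], G.Wg[2]),
    Named("Ep") = G.Ep,
    Named("Cw") = List::create(G.Cw[0], G.Cw[1], G.Cw[2]),
    Named("Cb") = List::create(
      NumericVector(G.Cb[0].begin(), G.Cb[0].end()),
      NumericVector(G.Cb[1].begin(), G.Cb[1].end()),
      NumericVector(G.Cb[2].begin(), G.Cb[2].end())),
    Named("U") = G.U,
    Named("V") = G.V,
    Named("q") = NumericVector(G.q.begin(), G.q.end()),
    Named("Wc1") = G.Wc1,
    Named("bc1") = NumericVector(G.bc1.begin(), G.bc1.end()),
    Named("wc2") = G.wc2,
    Named("bc2") = G.bc2
  );
}

static double bce(double p, double y) {
  p = std::min(std::max(p, 1e-12), 1.0 - 1e-12);
  return -(y * std::log(p) + (1.0 - y) * std::log(1.0 - p));
}

// Forward pass for one pair; returns probability and the attention map.
// [[Rcpp::export(name = ".cpp_dta_forward")]]
List cpp_dta_forward(const arma::mat& M, const arma::mat& A,
                     const arma::uvec& prot_idx1, const List& params,
                     const arma::ivec& kernels) {
  Params P = unpack(params);
  Cache c = forward(P, M, A, prot_idx1 - 1, kernels);
  return List::create(Named("p") = c.p, Named("logit") = c.logit,
                      Named("attention") = c.alpha);
}

// Summed (optionally sample-weighted) gradients and total loss over a
// minibatch of pairs. graphs: list of list(M, A); prots: list of 1-based
// index vectors; w: per-sample loss weights.
// [[Rcpp::export(name = ".cpp_dta_batch_grad")]]
List cpp_dta_batch_grad(const List& graphs, const List& prots,
                        const arma::vec& y, const arma::vec& w,
                        const List& params, const arma::ivec& kernels) {
  Params P = unpack(params);
  Grads G; G.init(P);
  double loss = 0.0;
  int n = graphs.size();
  NumericVector probs(n);
  for (int i = 0; i < n; ++i) {
    List g = graphs[i];
    uvec idx = as<uvec>(prots[i]) - 1;
    Cache c = forward(P, as<mat>(g["M"]), as<mat>(g["A"]), idx, kernels);
    backward(P, c, idx, kernels, y[i], w[i], G);
    loss += w[i] * bce(c.p, y[i]);
    probs[i] = c.p;
  }
  List out = pack_grads(G);
  return List::create(Named("grads") = out, Named("loss") = loss,
                      Named("prob") = probs);
}

// Probabilities for a list of pairs.
// [[Rcpp::export(name = ".cpp_dta_predict")]]
NumericVector cpp_dta_predict(const List& graphs, const List& prots,
                              const List& params, const arma::ivec& kernels) {
  Params P = unpack(params);
  int n = graphs.size();
  NumericVector probs(n);
  for (int i = 0; i < n; ++i) {
    List g = graphs[i];
    Cache c = forward(P, as<mat>(g["M"]), as<mat>(g["A"]),
                      as<uvec>(prots[i]) - 1, kernels);
    probs[i] = c.p;
  }
  return probs;
}
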