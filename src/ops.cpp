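// Hot numerical kernels for the network: 1-D convolutions (forward and
// backward), row-wise softmax/log-softmax, and the CTC forward-backward
// recursion. R-side autodiff ops delegate here.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
NumericVector cpp_row_max(const NumericMatrix& x) {
  int n = x.nrow(), m = x.ncol();
  NumericVector out(n, NEG_INF);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i)
      if (x(i, j) > out[i]) out[i] = x(i, j);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_softmax_rows(const NumericMatrix& x) {
  int n = x.nrow(), m = x.ncol();
  NumericMatrix out(n, m);
  std::vector<double> mx(n, NEG_INF), sum(n, 0.0);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i)
      if (x(i, j) > mx[i]) mx[i] = x(i, j);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) {
      double e = std::exp(x(i, j) - mx[i]);
      out(i, j) = e;
      sum[i] += e;
    }
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) out(i, j) /= sum[i];
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_logsoftmax_rows(const NumericMatrix& x) {
  int n = x.nrow(), m = x.ncol();
  NumericMatrix out(n, m);
  std::vector<double> mx(n, NEG_INF), sum(n, 0.0);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i)
      if (x(i, j) > mx[i]) mx[i] = x(i, j);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) sum[i] += std::exp(x(i, j) - mx[i]);
  for (int i = 0; i < n; ++i) sum[i] = mx[i] + std::log(sum[i]);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) out(i, j) = x(i, j) - sum[i];
  return out;
}

// 1-D convolution along rows (time), same padding:
// out(t, co) = b[co] + sum_{k, ci} x(t*stride - pl + k, ci) * W(k*Cin + ci, co)
// with pl = (kernel - 1) / 2 and out-of-range rows treated as zero.
// [[Rcpp::export]]
NumericMatrix cpp_conv1d_fwd(const NumericMatrix& x, const NumericMatrix& W,
                             const NumericVector& b, int kernel, int stride) {
  int T = x.nrow(), Cin = x.ncol(), Cout = W.ncol();
  int pl = (kernel - 1) / 2;
  int Lout = (T - 1) / stride + 1;
  NumericMatrix out(Lout, Cout);
  for (int co = 0; co < Cout; ++co)
    for (int t = 0; t < Lout; ++t) out(t, co) = b[co];
  for (int k = 0; k < kernel; ++k) {
    for (int ci = 0; ci < Cin; ++ci) {
      int wrow = k * Cin + ci;
      for (int co = 0; co < Cout; ++co) {
        double w = W(wrow, co);
        if (w == 0.0) continue;
        for (int t = 0; t < Lout; ++t) {
          int src = t * stride - pl + k;
          if (src < 0 || src >= T) continue;
          out(t, co) += x(src, ci) * w;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv1d_bwd(const NumericMatrix& x, const NumericMatrix& W,
                    const NumericMatrix& g, int kernel, int stride) {
  int T = x.nrow(), Cin = x.ncol(), Cout = W.ncol();
  int pl = (kernel - 1) / 2;
  int Lout = g.nrow();
  NumericMatrix dx(T, Cin), dW(kernel * Cin, Cout);
  NumericVector db(Cout);
  for (int co = 0; co < Cout; ++co) {
    double s = 0.0;
    for (int t = 0; t < Lout; ++t) s += g(t, co);
    db[co] = s;
  }
  for (int k = 0; k < kernel; ++k) {
    for (int ci = 0; ci < Cin; ++ci) {
      int wrow = k * Cin + ci;
      for (int co = 0; co < Cout; ++co) {
        double w = W(wrow, co), acc = 0.0;
        for (int t = 0; t < Lout; ++t) {
          int src = t * stride - pl + k;
          if (src < 0 || src >= T) continue;
          double gv = g(t, co);
          acc += x(src, ci) * gv;
          dx(src, ci) += w * gv;
        }
        dW(wrow, co) = acc;
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Depthwise 1-D convolution, stride 1, same padding. W: kernel x C.
// [[Rcpp::export]]
NumericMatrix cpp_dwconv_fwd(const NumericMatrix& x, const NumericMatrix& W,
                             const NumericVector& b) {
  int T = x.nrow(), C = x.ncol(), K = W.nrow();
  int pl = (K - 1) / 2;
  NumericMatrix out(T, C);
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < T; ++t) {
      double acc = b[c];
      int k0 = std::max(0, pl - t), k1 = std::min(K, T + pl - t);
      for (int k = k0; k < k1; ++k) acc += x(t - pl + k, c) * W(k, c);
      out(t, c) = acc;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_dwconv_bwd(const NumericMatrix& x, const NumericMatrix& W,
                    const NumericMatrix& g) {
  int T = x.nrow(), C = x.ncol(), K = W.nrow();
  int pl = (K - 1) / 2;
  NumericMatrix dx(T, C), dW(K, C);
  NumericVector db(C);
  for (int c = 0; c < C; ++c) {
    double s = 0.0;
    for (int t = 0; t < T; ++t) s += g(t, c);
    db[c] = s;
    for (int k = 0; k < K; ++k) {
      double w = W(k, c), acc = 0.0;
      int t0 = std::max(0, pl - k), t1 = std::min(T, T + pl - k);
      for (int t = t0; t < t1; ++t) {
        double gv = g(t, c);
        acc += x(t - pl + k, c) * gv;
        dx(t - pl + k, c) += w * gv;
      }
      dW(k, c) = acc;
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}
static inline double lse3(double a, double b, double c) {
  return lse2(lse2(a, b), c);
}

// CTC forward-backward in log space. lp: T x V log-probabilities (column 0
// is the blank), target: 1-based label columns (2..V). Returns the loss
// -log P(target), feasibility, and optionally the gradient wrt lp.
// [[Rcpp::export]]
List cpp_ctc(const NumericMatrix& lp, const IntegerVector& target,
             bool want_grad) {
  int T = lp.nrow(), V = lp.ncol(), L = target.size();
  int reps = 0;
  for (int i = 1; i < L; ++i) if (target[i] == target[i - 1]) ++reps;
  if (L + reps > T) {
    return List::create(_["loss"] = R_PosInf, _["feasible"] = false,
                        _["grad"] = want_grad ? NumericMatrix(T, V)
                                              : NumericMatrix(0, 0));
  }
  int S = 2 * L + 1;
  std::vector<int> ext(S, 0);  // 0-based symbol columns
  for (int i = 0; i < L; ++i) ext[2 * i + 1] = target[i] - 1;
  std::vector<bool> skip_ok(S, false);
  for (int s = 2; s < S; ++s)
    skip_ok[s] = ext[s] != 0 && ext[s] != ext[s - 2];
  std::vector<double> alpha(T * S, NEG_INF), beta;
  auto A = [&](int t, int s) -> double& { return alpha[t * S + s]; };
  A(0, 0) = lp(0, ext[0]);
  if (S > 1) A(0, 1) = lp(0, ext[1]);
  for (int t = 1; t < T; ++t) {
    for (int s = 0; s < S; ++s) {
      double v = A(t - 1, s);
      if (s >= 1) v = lse2(v, A(t - 1, s - 1));
      if (s >= 2 && skip_ok[s]) v = lse2(v, A(t - 1, s - 2));
      A(t, s) = (v == NEG_INF) ? NEG_INF : v + lp(t, ext[s]);
    }
  }
  double logZ = A(T - 1, S - 1);
  if (S > 1) logZ = lse2(logZ, A(T - 1, S - 2));
  double loss = -logZ;
  if (!want_grad) {
    return List::create(_["loss"] = loss, _["feasible"] = std::isfinite(loss),
                        _["grad"] = NumericMatrix(0, 0));
  }
  if (!std::isfinite(loss)) {
    return List::create(_["loss"] = R_PosInf, _["feasible"] = false,
                        _["grad"] = NumericMatrix(T, V));
  }
  beta.assign(T * S, NEG_INF);
  auto B = [&](int t, int s) -> double& { return beta[t * S + s]; };
  B(T - 1, S - 1) = lp(T - 1, ext[S - 1]);
  if (S > 1) B(T - 1, S - 2) = lp(T - 1, ext[S - 2]);
  for (int t = T - 2; t >= 0; --t) {
    for (int s = 0; s < S; ++s) {
      double v = B(t + 1, s);
      if (s + 1 < S) v = lse2(v, B(t + 1, s + 1));
      if (s + 2 < S && skip_ok[s + 2]) v = lse2(v, B(t + 1, s + 2));
      B(t, s) = (v == NEG_INF) ? NEG_INF : v + lp(t, ext[s]);
    }
  }
  // occupancy sums are probabilities (<= 1), so plain linear accumulation
  // is numerically safe here
  NumericMatrix grad(T, V);
  for (int t = 0; t < T; ++t) {
    for (int s = 0; s < S; ++s) {
      double occ = A(t, s) + B(t, s) - lp(t, ext[s]) - logZ;
      if (occ != NEG_INF) grad(t, ext[s]) -= std::exp(occ);
    }
  }
  return List::create(_["loss"] = loss, _["feasible"] = true,
                      _["grad"] = grad);
}

// ---- fused multi-head attention (BLAS-backed via Armadillo) ----
// Q: Tq x d, K/V: Tk x d (post-projection; Tq == Tk for self-attention,
// rectangular for cross-attention). posmode: 0 = plain dot-product,
// 1 = relative position scores with Transformer-XL shift (self-attention
// only; Kp: (2Tq-1) x d, column p of the score matrix = offset Tq-1-p),
// 2 = absolute position scores, no shift (Kp: Tk x d). bc/bp: length-d
// content/position biases added to Q. mask: optional additive Tq x Tk
// matrix. Returns the concatenated context (Tq x d) and per-head
// attention probabilities (Tq x Tk*H) reused by the backward pass.
// [[Rcpp::export]]
Rcpp::List cpp_mhsa_fwd(const arma::mat& Q, const arma::mat& K,
                        const arma::mat& V, const arma::mat& Kp,
                        const arma::vec& bc, const arma::vec& bp,
                        const arma::mat& mask, int H, int posmode) {
  int Tq = Q.n_rows, Tk = K.n_rows, d = Q.n_cols, dk = d / H;
  if (posmode == 1 && Tq != Tk)
    Rcpp::stop("relative position scores require self-attention");
  double scale = 1.0 / std::sqrt((double)dk);
  bool has_mask = (int)mask.n_rows == Tq && (int)mask.n_cols == Tk;
  arma::mat out(Tq, d), P(Tq, (size_t)Tk * H);
  for (int h = 0; h < H; ++h) {
    arma::span cs(h * dk, (h + 1) * dk - 1);
    arma::mat Qc = Q.cols(cs);
    if (posmode) Qc.each_row() += bc.subvec(h * dk, (h + 1) * dk - 1).t();
    arma::mat S = Qc * K.cols(cs).t();
    if (posmode) {
      arma::mat Qp = Q.cols(cs);
      Qp.each_row() += bp.subvec(h * dk, (h + 1) * dk - 1).t();
      arma::mat BD = Qp * Kp.cols(cs).t();
      if (posmode == 1) {
        for (int i = 0; i < Tq; ++i)
          for (int j = 0; j < Tk; ++j) S(i, j) += BD(i, Tq - 1 - i + j);
      } else {
        S += BD;
      }
    }
    S *= scale;
    if (has_mask) S += mask;
    // row-wise softmax
    arma::vec mx = arma::max(S, 1);
    S.each_col() -= mx;
    S = arma::exp(S);
    S.each_col() /= arma::sum(S, 1);
    P.cols((size_t)h * Tk, (size_t)(h + 1) * Tk - 1) = S;
    out.cols(cs) = S * V.cols(cs);
  }
  return Rcpp::List::create(Rcpp::_["out"] = out, Rcpp::_["P"] = P);
}

// [[Rcpp::export]]
Rcpp::List cpp_mhsa_bwd(const arma::mat& g, const arma::mat& Q,
                        const arma::mat& K, const arma::mat& V,
                        const arma::mat& Kp, const arma::vec& bc,
                        const arma::vec& bp, const arma::mat& P,
                        int H, int posmode) {
  int Tq = Q.n_rows, Tk = K.n_rows, d = Q.n_cols, dk = d / H;
  double scale = 1.0 / std::sqrt((double)dk);
  arma::mat dQ(Tq, d, arma::fill::zeros), dK(Tk, d, arma::fill::zeros),
      dV(Tk, d, arma::fill::zeros);
  arma::mat dKp(posmode ? Kp.n_rows : 0, posmode ? d : 0, arma::fill::zeros);
  arma::vec dbc(posmode ? d : 0, arma::fill::zeros),
      dbp(posmode ? d : 0, arma::fill::zeros);
  for (int h = 0; h < H; ++h) {
    arma::span cs(h * dk, (h + 1) * dk - 1);
    arma::mat Ph = P.cols((size_t)h * Tk, (size_t)(h + 1) * Tk - 1);
    arma::mat gh = g.cols(cs);
    arma::mat dP = gh * V.cols(cs).t();
    dV.cols(cs) = Ph.t() * gh;
    arma::vec rs = arma::sum(dP % Ph, 1);
    arma::mat dS = Ph % (dP.each_col() - rs) * scale;
    // content term
    arma::mat dQc = dS * K.cols(cs);
    dQ.cols(cs) += dQc;
    arma::mat Qc = Q.cols(cs);
    if (posmode) {
      Qc.each_row() += bc.subvec(h * dk, (h + 1) * dk - 1).t();
      dbc.subvec(h * dk, (h + 1) * dk - 1) = arma::sum(dQc, 0).t();
    }
    dK.cols(cs) = dS.t() * Qc;
    if (posmode) {
      // position term through the (shifted) layout
      arma::mat dBD;
      if (posmode == 1) {
        dBD.zeros(Tq, Kp.n_rows);
        for (int i = 0; i < Tq; ++i)
          for (int j = 0; j < Tk; ++j) dBD(i, Tq - 1 - i + j) += dS(i, j);
      } else {
        dBD = dS;
      }
      arma::mat Qp = Q.cols(cs);
      Qp.each_row() += bp.subvec(h * dk, (h + 1) * dk - 1).t();
      arma::mat dQp = dBD * Kp.cols(cs);
      dQ.cols(cs) += dQp;
      dbp.subvec(h * dk, (h + 1) * dk - 1) = arma::sum(dQp, 0).t();
      dKp.cols(cs) = dBD.t() * Qp;
    }
  }
  return Rcpp::List::create(Rcpp::_["dQ"] = dQ, Rcpp::_["dK"] = dK,
                            Rcpp::_["dV"] = dV, Rcpp::_["dKp"] = dKp,
                            Rcpp::_["dbc"] = dbc, Rcpp::_["dbp"] = dbp);
}
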