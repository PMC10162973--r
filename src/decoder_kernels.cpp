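// Fused forward/backward pass of the compact orientation decoder.
//
// Mirrors the reference implementation in R/decoder.R: the per-channel
// affine of the first batch norm is folded through the depthwise spatial
// convolution, and its batch statistics come in closed form from the lag
// moments (mB, CB) of the fixed input batch. The R reference is kept and
// the test suite asserts numerical equivalence between the two paths.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;
using arma::uword;

namespace {

struct Config {
  int K, L, mult, pf, R, T, nout, M8, P, Tp, Tq, Fdim;
};

Config read_config(const List& cfg) {
  Config c;
  c.K = as<int>(cfg["n_temporal_kernels"]);
  c.L = as<int>(cfg["temporal_kernel_len"]);
  c.mult = as<int>(cfg["spatial_depth_multiplier"]);
  c.pf = as<int>(cfg["pool_factor"]);
  c.R = as<int>(cfg["n_rois"]);
  c.T = as<int>(cfg["n_samples"]);
  c.nout = as<int>(cfg["n_outputs"]);
  c.M8 = c.K * c.mult;
  c.P = (c.L - 1) / 2;
  c.Tp = c.T + c.L - 1;
  c.Tq = c.T / c.pf;
  c.Fdim = c.M8 * c.Tq;
  return c;
}

// temporal convolution of channel signals, one kernel row per channel
void conv_time(const cube& Spad, const mat& wm, cube& U, const Config& c) {
  for (uword b = 0; b < U.n_slices; ++b)
    for (int t = 0; t < c.T; ++t)
      for (int m = 0; m < c.M8; ++m) {
        double acc = 0.0;
        for (int j = 0; j < c.L; ++j) acc += wm(m, j) * Spad(m, t + j, b);
        U(m, t, b) = acc;
      }
}

// scatter counterpart used by the backward pass
void conv_scatter(const cube& G, const mat& wm, cube& H, const Config& c) {
  H.zeros();
  for (uword b = 0; b < G.n_slices; ++b)
    for (int t = 0; t < c.T; ++t)
      for (int m = 0; m < c.M8; ++m) {
        double g = G(m, t, b);
        if (g == 0.0) continue;
        for (int j = 0; j < c.L; ++j) H(m, t + j, b) += wm(m, j) * g;
      }
}

mat softmax_cols(const mat& O) {
  mat E = O;
  for (uword j = 0; j < E.n_cols; ++j) {
    E.col(j) -= E.col(j).max();
    E.col(j) = arma::exp(E.col(j));
    E.col(j) /= arma::accu(E.col(j));
  }
  return E;
}

NumericVector nv(const vec& x) {
  return NumericVector(x.begin(), x.end());
}

}  // namespace

// One full training iteration on a prepared batch: forward (training-mode
// batch norm), cross-entropy, gradients of every parameter. `drop_mask` is
// drawn in R so RNG semantics stay with the caller.
// [[Rcpp::export]]
List cnn_train_step(const List& params, const List& cfg_list,
                    const NumericVector& Xarr, const NumericVector& mB_,
                    const NumericMatrix& CB_, const NumericMatrix& Y_,
                    const IntegerVector& y01,
                    const Nullable<NumericMatrix>& drop_mask_) {
  Config c = read_config(cfg_list);
  const int B = Xarr.size() / (c.R * c.T);
  const double eps_bn = 1e-5;

  mat Wt = as<mat>(params["Wt"]);
  vec g1 = as<vec>(params["g1"]), b1 = as<vec>(params["b1"]);
  mat Ws = as<mat>(params["Ws"]);
  vec g2 = as<vec>(params["g2"]), b2 = as<vec>(params["b2"]);
  mat Wd = as<mat>(params["Wd"]);
  vec bd = as<vec>(params["bd"]);
  vec mB = as<vec>(mB_);
  mat CB = as<mat>(CB_);
  mat Y = as<mat>(Y_);

  const cube X(const_cast<double*>(Xarr.begin()), c.R, c.T, B, false, true);
  const mat Xr(const_cast<double*>(Xarr.begin()), c.R, c.T * B, false, true);

  arma::uvec km(c.M8);
  for (int m = 0; m < c.M8; ++m) km[m] = m / c.mult;

  // spatial combination first (BN1 folds through it)
  mat S8 = Ws * Xr;                         // M8 x (T*B)
  cube Spad(c.M8, c.Tp, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    Spad.slice(b).cols(c.P, c.P + c.T - 1) =
        mat(S8.colptr((size_t)b * c.T), c.M8, c.T, false, true);

  // closed-form batch statistics of the temporal convolution
  vec mu1 = Wt * mB;
  vec e2(c.K), var1(c.K);
  for (int k = 0; k < c.K; ++k) {
    e2[k] = arma::as_scalar(Wt.row(k) * CB * Wt.row(k).t());
    var1[k] = std::max(e2[k] - mu1[k] * mu1[k], 0.0);
  }
  vec sd1 = arma::sqrt(var1 + eps_bn);
  vec a1 = g1 / sd1;
  vec c1 = b1 - g1 % mu1 / sd1;

  mat wm(c.M8, c.L);
  for (int m = 0; m < c.M8; ++m) wm.row(m) = Wt.row(km[m]);
  cube U(c.M8, c.T, B);
  conv_time(Spad, wm, U, c);

  vec Vs = arma::sum(Ws, 1);
  cube Z(c.M8, c.T, B);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < c.T; ++t)
      for (int m = 0; m < c.M8; ++m)
        Z(m, t, b) = a1[km[m]] * U(m, t, b) + c1[km[m]] * Vs[m];

  // second batch norm: per output channel over (t, b)
  const double n2 = (double)c.T * B;
  vec mu2(c.M8, arma::fill::zeros), m2sq(c.M8, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < c.T; ++t)
      for (int m = 0; m < c.M8; ++m) {
        mu2[m] += Z(m, t, b);
        m2sq[m] += Z(m, t, b) * Z(m, t, b);
      }
  mu2 /= n2;
  vec var2 = m2sq / n2 - mu2 % mu2;
  var2.transform([](double v) { return v < 0 ? 0.0 : v; });
  vec sd2 = arma::sqrt(var2 + eps_bn);

  cube Zh(c.M8, c.T, B), Pact(c.M8, c.T, B);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < c.T; ++t)
      for (int m = 0; m < c.M8; ++m) {
        Zh(m, t, b) = (Z(m, t, b) - mu2[m]) / sd2[m];
        double p = g2[m] * Zh(m, t, b) + b2[m];
        Pact(m, t, b) = p;
      }

  // average pooling + flatten (channel-fastest order, matching the R path)
  mat Qf(c.Fdim, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int tq = 0; tq < c.Tq; ++tq)
      for (int m = 0; m < c.M8; ++m) {
        double acc = 0.0;
        for (int p = 0; p < c.pf; ++p) {
          double v = Pact(m, tq * c.pf + p, b);
          acc += v > 0 ? v : 0.0;
        }
        Qf(m + tq * c.M8, b) = acc / c.pf;
      }

  mat Qd = Qf;
  bool has_mask = drop_mask_.isNotNull();
  mat mask;
  if (has_mask) {
    mask = as<mat>(drop_mask_.get());
    Qd %= mask;
  }

  mat O = Wd * Qd;
  O.each_col() += bd;
  mat probs = softmax_cols(O);
  double loss = 0.0;
  for (int b = 0; b < B; ++b)
    loss -= std::log(std::max(probs(y01[b], b), 1e-12));
  loss /= B;

  // ---- backward ----
  mat dO = (probs - Y) / B;
  mat dWd = dO * Qd.t();
  vec dbd = arma::sum(dO, 1);
  mat dQd = Wd.t() * dO;
  if (has_mask) dQd %= mask;

  cube dP(c.M8, c.T, B);
  for (int b = 0; b < B; ++b)
    for (int tq = 0; tq < c.Tq; ++tq)
      for (int m = 0; m < c.M8; ++m) {
        double g = dQd(m + tq * c.M8, b) / c.pf;
        for (int p = 0; p < c.pf; ++p) {
          int t = tq * c.pf + p;
          dP(m, t, b) = Pact(m, t, b) > 0 ? g : 0.0;
        }
      }

  vec dg2(c.M8, arma::fill::zeros), db2(c.M8, arma::fill::zeros);
  vec mean_dZh(c.M8, arma::fill::zeros), mean_dZhZh(c.M8, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < c.T; ++t)
      for (int m = 0; m < c.M8; ++m) {
        double dp = dP(m, t, b), zh = Zh(m, t, b);
        dg2[m] += dp * zh;
        db2[m] += dp;
        double dzh = dp * g2[m];
        mean_dZh[m] += dzh;
        mean_dZhZh[m] += dzh * zh;
      }
  mean_dZh /= n2;
  mean_dZhZh /= n2;

  cube G(c.M8, c.T, B);
  vec sumG(c.M8, arma::fill::zeros), Dm(c.M8, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < c.T; ++t)
      for (int m = 0; m < c.M8; ++m) {
        double dzh = dP(m, t, b) * g2[m];
        double g = (dzh - mean_dZh[m] - Zh(m, t, b) * mean_dZhZh[m]) / sd2[m];
        G(m, t, b) = g;
        sumG[m] += g;
        Dm[m] += g * U(m, t, b);
      }

  cube H(c.M8, c.Tp, B);
  conv_scatter(G, wm, H, c);

  // dWs = a1[km] * (H x Xpad^T over (tau, b)) + c1[km] * sumG (per row)
  mat dWs(c.M8, c.R, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const mat& Hs = H.slice(b);                 // M8 x Tp
    const mat Xs(const_cast<double*>(X.slice_memptr(b)), c.R, c.T, false,
                 true);
    dWs += Hs.cols(c.P, c.P + c.T - 1) * Xs.t();  // padded cols hit zeros
  }
  for (int m = 0; m < c.M8; ++m) {
    dWs.row(m) *= a1[km[m]];
    dWs.row(m) += c1[km[m]] * sumG[m];
  }

  mat A33(c.L, c.M8, arma::fill::zeros);
  for (uword b = 0; b < (uword)B; ++b)
    for (int t = 0; t < c.T; ++t)
      for (int m = 0; m < c.M8; ++m) {
        double g = G(m, t, b);
        if (g == 0.0) continue;
        for (int j = 0; j < c.L; ++j) A33(j, m) += g * Spad(m, t + j, b);
      }

  mat dWt(c.K, c.L, arma::fill::zeros);
  vec dg1(c.K, arma::fill::zeros), db1(c.K, arma::fill::zeros);
  for (int k = 0; k < c.K; ++k) {
    vec Ak(c.L, arma::fill::zeros);
    double Dk = 0.0, Gk = 0.0;
    for (int m = 0; m < c.M8; ++m) {
      if ((int)km[m] != k) continue;
      Ak += A33.col(m);
      Dk += Dm[m];
      Gk += Vs[m] * sumG[m];
    }
    vec Cw = CB * Wt.row(k).t();
    vec dinv = -(Cw - mu1[k] * mB) / (sd1[k] * sd1[k] * sd1[k]);
    dWt.row(k) = (a1[k] * Ak + g1[k] * Dk * dinv -
                  g1[k] * Gk * (mB / sd1[k] + mu1[k] * dinv)).t();
    dg1[k] = Dk / sd1[k] - mu1[k] / sd1[k] * Gk;
    db1[k] = Gk;
  }

  return List::create(
      _["loss"] = loss,
      _["grads"] = List::create(_["Wt"] = dWt, _["g1"] = nv(dg1),
                                _["b1"] = nv(db1), _["Ws"] = dWs,
                                _["g2"] = nv(dg2), _["b2"] = nv(db2),
                                _["Wd"] = dWd, _["bd"] = nv(dbd)),
      _["mu1"] = nv(mu1), _["var1"] = nv(var1), _["mu2"] = nv(mu2),
      _["var2"] = nv(var2));
}

// Lag moments of a batch for the closed-form batch-norm statistics of the
// temporal convolution: mB[j] and CB[j, j'] are the mean over (roi, valid
// t, trial) of the zero-padded input at lags j and j'.
// [[Rcpp::export]]
List conv1_lag_stats_cpp(const NumericVector& Xarr, int R, int T, int L) {
  const int B = Xarr.size() / (R * T);
  const int P = (L - 1) / 2;
  const int Tp = T + L - 1;
  const double n = (double)R * T * B;
  const cube X(const_cast<double*>(Xarr.begin()), R, T, B, false, true);

  // padded per-lag cross sums over (r, b) as a function of tau
  mat CB(L, L, arma::fill::zeros);
  vec mB(L, arma::fill::zeros);
  vec s0(Tp, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int t = 0; t < T; ++t) {
      double acc = 0.0;
      const double* col = X.slice_colptr(b, t);
      for (int r = 0; r < R; ++r) acc += col[r];
      s0[t + P] += acc;
    }
  vec cs0 = arma::cumsum(s0);
  for (int j = 0; j < L; ++j)
    mB[j] = (cs0[j + T - 1] - (j > 0 ? cs0[j - 1] : 0.0)) / n;

  for (int d = 0; d < L; ++d) {
    // q[tau] = sum over (r, b) of xpad(tau) * xpad(tau + d); xpad is X
    // shifted by P with zeros outside [P, P + T)
    vec q(Tp, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      const double* sl = X.slice_memptr(b);
      for (int t = 0; t + d < T; ++t) {
        const double* c1 = sl + (size_t)t * R;
        const double* c2 = sl + (size_t)(t + d) * R;
        double acc = 0.0;
        for (int r = 0; r < R; ++r) acc += c1[r] * c2[r];
        q[t + P] += acc;
      }
    }
    vec cq = arma::cumsum(q);
    for (int j = 0; j + d < L; ++j) {
      int hi = std::min(j + T - 1, Tp - d - 1);
      double v = (cq[hi] - (j > 0 ? cq[j - 1] : 0.0)) / n;
      CB(j, j + d) = v;
      CB(j + d, j) = v;
    }
  }
  return List::create(_["mB"] = nv(mB), _["CB"] = CB);
}

// Evaluation-mode forward pass (running statistics, no dropout).
// [[Rcpp::export]]
List cnn_eval_forward(const List& params, const List& cfg_list,
                      const NumericVector& Xarr, const List& running) {
  Config c = read_config(cfg_list);
  const int B = Xarr.size() / (c.R * c.T);
  const double eps_bn = 1e-5;

  mat Wt = as<mat>(params["Wt"]);
  vec g1 = as<vec>(params["g1"]), b1 = as<vec>(params["b1"]);
  mat Ws = as<mat>(params["Ws"]);
  vec g2 = as<vec>(params["g2"]), b2 = as<vec>(params["b2"]);
  mat Wd = as<mat>(params["Wd"]);
  vec bd = as<vec>(params["bd"]);
  vec mu1 = as<vec>(running["mu1"]), var1 = as<vec>(running["var1"]);
  vec mu2 = as<vec>(running["mu2"]), var2 = as<vec>(running["var2"]);

  const mat Xr(const_cast<double*>(Xarr.begin()), c.R, c.T * B, false, true);
  arma::uvec km(c.M8);
  for (int m = 0; m < c.M8; ++m) km[m] = m / c.mult;

  mat S8 = Ws * Xr;
  cube Spad(c.M8, c.Tp, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    Spad.slice(b).cols(c.P, c.P + c.T - 1) =
        mat(S8.colptr((size_t)b * c.T), c.M8, c.T, false, true);

  vec sd1 = arma::sqrt(var1 + eps_bn);
  vec a1 = g1 / sd1;
  vec c1 = b1 - g1 % mu1 / sd1;
  mat wm(c.M8, c.L);
  for (int m = 0; m < c.M8; ++m) wm.row(m) = Wt.row(km[m]);
  cube U(c.M8, c.T, B);
  conv_time(Spad, wm, U, c);
  vec Vs = arma::sum(Ws, 1);
  vec sd2 = arma::sqrt(var2 + eps_bn);

  mat Qf(c.Fdim, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int tq = 0; tq < c.Tq; ++tq)
      for (int m = 0; m < c.M8; ++m) {
        double acc = 0.0;
        for (int p = 0; p < c.pf; ++p) {
          int t = tq * c.pf + p;
          double z = a1[km[m]] * U(m, t, b) + c1[km[m]] * Vs[m];
          double pa = g2[m] * (z - mu2[m]) / sd2[m] + b2[m];
          acc += pa > 0 ? pa : 0.0;
        }
        Qf(m + tq * c.M8, b) = acc / c.pf;
      }

  mat O = Wd * Qf;
  O.each_col() += bd;
  mat probs = softmax_cols(O);
  return List::create(_["O"] = O, _["probs"] = probs);
}
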