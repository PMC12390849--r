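// Recurrent kernels for tiny behavioural RNNs.
//
// All sequences are laid out one row per trial.  The hidden state used to
// produce the policy at trial t is the state *before* the trial-t input is
// consumed; `starts` marks 1-based rows where the state resets to zero
// (session / block boundaries).  Forward passes cache the gate activations
// needed by the corresponding backward passes.  Hidden sizes are tiny
// (1-50), so everything is written as explicit loops over preallocated
// buffers; no per-trial allocations.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double sig(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static std::vector<bool> start_flags(const IntegerVector& starts, int T) {
  std::vector<bool> f(T, false);
  for (int i = 0; i < starts.size(); ++i) {
    int s = starts[i] - 1;
    if (s >= 0 && s < T) f[s] = true;
  }
  return f;
}

// ---------------------------------------------------------------------------
// Vanilla GRU (vector inputs)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_gru_forward(const List& w, const arma::mat& X,
                     const IntegerVector& starts) {
  const arma::mat Wir = w["Wir"], Wiz = w["Wiz"], Win = w["Win"];
  const arma::mat Whr = w["Whr"], Whz = w["Whz"], Whn = w["Whn"];
  const arma::vec bir = w["bir"], biz = w["biz"], bin = w["bin"];
  const arma::vec bhr = w["bhr"], bhz = w["bhz"], bhn = w["bhn"];
  const int T = X.n_rows, d = Whr.n_rows, k = X.n_cols;
  std::vector<bool> st = start_flags(starts, T);

  arma::mat H(T, d), R(T, d), Z(T, d), N(T, d), M(T, d);
  std::vector<double> h(d, 0.0), ar(d), az(d), am(d);
  for (int t = 0; t < T; ++t) {
    if (st[t]) std::fill(h.begin(), h.end(), 0.0);
    for (int i = 0; i < d; ++i) {
      H(t, i) = h[i];
      double sr = bir[i] + bhr[i], sz = biz[i] + bhz[i];
      double sn = bin[i], sm = bhn[i];
      for (int j = 0; j < k; ++j) {
        double x = X(t, j);
        sr += Wir(i, j) * x; sz += Wiz(i, j) * x; sn += Win(i, j) * x;
      }
      for (int j = 0; j < d; ++j) {
        double hj = h[j];
        sr += Whr(i, j) * hj; sz += Whz(i, j) * hj; sm += Whn(i, j) * hj;
      }
      ar[i] = sr; az[i] = sz; am[i] = sm;
      N(t, i) = sn;   // partial: input drive; completed below with r * m
    }
    for (int i = 0; i < d; ++i) {
      double r = sig(ar[i]), z = sig(az[i]);
      double n = std::tanh(N(t, i) + r * am[i]);
      R(t, i) = r; Z(t, i) = z; N(t, i) = n; M(t, i) = am[i];
      h[i] = (1.0 - z) * n + z * h[i];
    }
  }
  return List::create(_["H"] = H, _["R"] = R, _["Z"] = Z, _["N"] = N,
                      _["M"] = M);
}

// [[Rcpp::export]]
List cpp_gru_backward(const List& w, const arma::mat& X, const List& fwd,
                      const arma::mat& dH, const IntegerVector& starts) {
  const arma::mat Wir = w["Wir"], Wiz = w["Wiz"], Win = w["Win"];
  const arma::mat Whr = w["Whr"], Whz = w["Whz"], Whn = w["Whn"];
  const arma::mat H = fwd["H"], R = fwd["R"], Z = fwd["Z"], N = fwd["N"],
                  M = fwd["M"];
  const int T = X.n_rows, d = Whr.n_rows, k = X.n_cols;
  std::vector<bool> st = start_flags(starts, T);

  arma::mat dWir(d, k, arma::fill::zeros), dWiz(d, k, arma::fill::zeros),
      dWin(d, k, arma::fill::zeros);
  arma::mat dWhr(d, d, arma::fill::zeros), dWhz(d, d, arma::fill::zeros),
      dWhn(d, d, arma::fill::zeros);
  arma::vec dbir(d, arma::fill::zeros), dbiz(d, arma::fill::zeros),
      dbin(d, arma::fill::zeros), dbhr(d, arma::fill::zeros),
      dbhz(d, arma::fill::zeros), dbhn(d, arma::fill::zeros);
  arma::mat dX(T, k, arma::fill::zeros);

  std::vector<double> g(d, 0.0), gh(d), dan(d), dar(d), daz(d), dm(d);
  for (int t = T - 1; t >= 0; --t) {
    for (int i = 0; i < d; ++i) gh[i] = dH(t, i);
    bool used = (t < T - 1) && !st[t + 1];
    if (used) {
      for (int i = 0; i < d; ++i) {
        double r = R(t, i), z = Z(t, i), n = N(t, i), m = M(t, i);
        double h = H(t, i), gi = g[i];
        double dn = gi * (1.0 - z);
        double dz = gi * (h - n);
        gh[i] += gi * z;
        double a_n = dn * (1.0 - n * n);
        dan[i] = a_n;
        dm[i] = a_n * r;
        dar[i] = (a_n * m) * (r * (1.0 - r));
        daz[i] = dz * (z * (1.0 - z));
        dbin[i] += a_n;
        dbhn[i] += dm[i];
        dbir[i] += dar[i]; dbhr[i] += dar[i];
        dbiz[i] += daz[i]; dbhz[i] += daz[i];
      }
      for (int i = 0; i < d; ++i) {
        double di = dan[i], dmi = dm[i], dri = dar[i], dzi = daz[i];
        for (int j = 0; j < k; ++j) {
          double x = X(t, j);
          dWin(i, j) += di * x; dWir(i, j) += dri * x; dWiz(i, j) += dzi * x;
          dX(t, j) += Win(i, j) * di + Wir(i, j) * dri + Wiz(i, j) * dzi;
        }
        for (int j = 0; j < d; ++j) {
          double hj = H(t, j);
          dWhn(i, j) += dmi * hj; dWhr(i, j) += dri * hj;
          dWhz(i, j) += dzi * hj;
          gh[j] += Whn(i, j) * dmi + Whr(i, j) * dri + Whz(i, j) * dzi;
        }
      }
    }
    g = gh;
  }
  return List::create(
      _["Wir"] = dWir, _["Wiz"] = dWiz, _["Win"] = dWin, _["Whr"] = dWhr,
      _["Whz"] = dWhz, _["Whn"] = dWhn, _["bir"] = dbir, _["biz"] = dbiz,
      _["bin"] = dbin, _["bhr"] = dbhr, _["bhz"] = dbhz, _["bhn"] = dbhn,
      _["dX"] = dX);
}

// ---------------------------------------------------------------------------
// Switching GRU (discrete input codes select weight sets)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_sgru_forward(const List& w, const IntegerVector& codes,
                      const IntegerVector& starts) {
  const arma::cube Whr = w["Whr"], Whz = w["Whz"], Whn = w["Whn"];
  const arma::mat bir = w["bir"], biz = w["biz"], bin = w["bin"];
  const arma::mat bhr = w["bhr"], bhz = w["bhz"], bhn = w["bhn"];
  const int T = codes.size(), d = Whr.n_rows;
  std::vector<bool> st = start_flags(starts, T);

  arma::mat H(T, d), R(T, d), Z(T, d), N(T, d), M(T, d);
  std::vector<double> h(d, 0.0), ar(d), az(d), am(d);
  for (int t = 0; t < T; ++t) {
    if (st[t]) std::fill(h.begin(), h.end(), 0.0);
    int c = codes[t] - 1;
    for (int i = 0; i < d; ++i) {
      H(t, i) = h[i];
      double sr = bir(i, c) + bhr(i, c);
      double sz = biz(i, c) + bhz(i, c);
      double sm = bhn(i, c);
      for (int j = 0; j < d; ++j) {
        double hj = h[j];
        sr += Whr(i, j, c) * hj; sz += Whz(i, j, c) * hj;
        sm += Whn(i, j, c) * hj;
      }
      ar[i] = sr; az[i] = sz; am[i] = sm;
    }
    for (int i = 0; i < d; ++i) {
      double r = sig(ar[i]), z = sig(az[i]);
      double n = std::tanh(bin(i, c) + r * am[i]);
      R(t, i) = r; Z(t, i) = z; N(t, i) = n; M(t, i) = am[i];
      h[i] = (1.0 - z) * n + z * h[i];
    }
  }
  return List::create(_["H"] = H, _["R"] = R, _["Z"] = Z, _["N"] = N,
                      _["M"] = M);
}

// [[Rcpp::export]]
List cpp_sgru_backward(const List& w, const IntegerVector& codes,
                       const List& fwd, const arma::mat& dH,
                       const IntegerVector& starts) {
  const arma::cube Whr = w["Whr"], Whz = w["Whz"], Whn = w["Whn"];
  const arma::mat H = fwd["H"], R = fwd["R"], Z = fwd["Z"], N = fwd["N"],
                  M = fwd["M"];
  const int T = codes.size(), d = Whr.n_rows, K = Whr.n_slices;
  std::vector<bool> st = start_flags(starts, T);

  arma::cube dWhr(d, d, K, arma::fill::zeros), dWhz(d, d, K, arma::fill::zeros),
      dWhn(d, d, K, arma::fill::zeros);
  arma::mat dbir(d, K, arma::fill::zeros), dbiz(d, K, arma::fill::zeros),
      dbin(d, K, arma::fill::zeros), dbhr(d, K, arma::fill::zeros),
      dbhz(d, K, arma::fill::zeros), dbhn(d, K, arma::fill::zeros);

  std::vector<double> g(d, 0.0), gh(d), dan(d), dar(d), daz(d), dm(d);
  for (int t = T - 1; t >= 0; --t) {
    for (int i = 0; i < d; ++i) gh[i] = dH(t, i);
    bool used = (t < T - 1) && !st[t + 1];
    if (used) {
      int c = codes[t] - 1;
      for (int i = 0; i < d; ++i) {
        double r = R(t, i), z = Z(t, i), n = N(t, i), m = M(t, i);
        double h = H(t, i), gi = g[i];
        double dn = gi * (1.0 - z);
        double dz = gi * (h - n);
        gh[i] += gi * z;
        double a_n = dn * (1.0 - n * n);
        dan[i] = a_n;
        dm[i] = a_n * r;
        dar[i] = (a_n * m) * (r * (1.0 - r));
        daz[i] = dz * (z * (1.0 - z));
        dbin(i, c) += a_n;
        dbhn(i, c) += dm[i];
        dbir(i, c) += dar[i]; dbhr(i, c) += dar[i];
        dbiz(i, c) += daz[i]; dbhz(i, c) += daz[i];
      }
      for (int i = 0; i < d; ++i) {
        double dmi = dm[i], dri = dar[i], dzi = daz[i];
        for (int j = 0; j < d; ++j) {
          double hj = H(t, j);
          dWhn(i, j, c) += dmi * hj; dWhr(i, j, c) += dri * hj;
          dWhz(i, j, c) += dzi * hj;
          gh[j] += Whn(i, j, c) * dmi + Whr(i, j, c) * dri +
                   Whz(i, j, c) * dzi;
        }
      }
    }
    g = gh;
  }
  return List::create(_["Whr"] = dWhr, _["Whz"] = dWhz, _["Whn"] = dWhn,
                      _["bir"] = dbir, _["biz"] = dbiz, _["bin"] = dbin,
                      _["bhr"] = dbhr, _["bhz"] = dbhz, _["bhn"] = dbhn);
}

// ---------------------------------------------------------------------------
// Switching linear network: h' = W^{(x)} h + b^{(x)}
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_slin_forward(const List& w, const IntegerVector& codes,
                      const IntegerVector& starts) {
  const arma::cube W = w["W"];
  const arma::mat b = w["b"];
  const int T = codes.size(), d = W.n_rows;
  std::vector<bool> st = start_flags(starts, T);
  arma::mat H(T, d);
  std::vector<double> h(d, 0.0), h2(d);
  for (int t = 0; t < T; ++t) {
    if (st[t]) std::fill(h.begin(), h.end(), 0.0);
    int c = codes[t] - 1;
    for (int i = 0; i < d; ++i) {
      H(t, i) = h[i];
      double s = b(i, c);
      for (int j = 0; j < d; ++j) s += W(i, j, c) * h[j];
      h2[i] = s;
    }
    h = h2;
  }
  return List::create(_["H"] = H);
}

// [[Rcpp::export]]
List cpp_slin_backward(const List& w, const IntegerVector& codes,
                       const List& fwd, const arma::mat& dH,
                       const IntegerVector& starts) {
  const arma::cube W = w["W"];
  const arma::mat H = fwd["H"];
  const int T = codes.size(), d = W.n_rows, K = W.n_slices;
  std::vector<bool> st = start_flags(starts, T);
  arma::cube dW(d, d, K, arma::fill::zeros);
  arma::mat db(d, K, arma::fill::zeros);
  std::vector<double> g(d, 0.0), gh(d);
  for (int t = T - 1; t >= 0; --t) {
    for (int i = 0; i < d; ++i) gh[i] = dH(t, i);
    bool used = (t < T - 1) && !st[t + 1];
    if (used) {
      int c = codes[t] - 1;
      for (int i = 0; i < d; ++i) {
        double gi = g[i];
        db(i, c) += gi;
        for (int j = 0; j < d; ++j) {
          dW(i, j, c) += gi * H(t, j);
          gh[j] += W(i, j, c) * gi;
        }
      }
    }
    g = gh;
  }
  return List::create(_["W"] = dW, _["b"] = db);
}

// row-wise softmax with max subtraction (hot path helper)
// [[Rcpp::export]]
arma::mat cpp_row_softmax(const arma::mat& S) {
  arma::mat P(S.n_rows, S.n_cols);
  for (arma::uword t = 0; t < S.n_rows; ++t) {
    double m = S(t, 0);
    for (arma::uword j = 1; j < S.n_cols; ++j) m = std::max(m, S(t, j));
    double tot = 0.0;
    for (arma::uword j = 0; j < S.n_cols; ++j) {
      double e = std::exp(S(t, j) - m);
      P(t, j) = e; tot += e;
    }
    for (arma::uword j = 0; j < S.n_cols; ++j) P(t, j) /= tot;
  }
  return P;
}
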