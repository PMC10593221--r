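// Core of the normalized-cut cell bipartition: Gaussian-kernel similarity
// graph on feature distances, second generalized eigenvector of the graph
// Laplacian, and the exact-Ncut sweep along the eigenvector ordering.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat pairwise_sqdist(const arma::mat& X) {
  arma::vec s = arma::sum(arma::square(X), 1);
  arma::mat D = -2.0 * (X * X.t());
  D.each_col() += s;
  D.each_row() += s.t();
  D.elem(arma::find(D < 0)).zeros();
  return D;
}

// [[Rcpp::export(name = ".ncut_core")]]
List ncut_core(const arma::mat& X, double bw_scale,
               Nullable<NumericVector> warm_start) {
  const int n = X.n_rows;
  if (n < 2) stop("need at least 2 cells");
  arma::mat D2 = pairwise_sqdist(X);

  // bandwidth: median off-diagonal distance
  arma::vec tri(n * (n - 1) / 2);
  int idx = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) tri(idx++) = std::sqrt(D2(i, j));
  double med = arma::median(tri);
  bool no_signal = (med <= 0.0);
  double sigma = no_signal ? 1.0 : med * bw_scale;

  arma::mat W = arma::exp(-D2 / (2.0 * sigma * sigma));
  arma::vec deg = arma::sum(W, 1);
  arma::vec dis = 1.0 / arma::sqrt(deg);

  // second largest eigenvector of N = D^{-1/2} W D^{-1/2}
  arma::mat Nm = W;
  Nm.each_col() %= dis;
  Nm.each_row() %= dis.t();
  arma::vec x2(n);
  if (n <= 250) {
    arma::vec eval;
    arma::mat evec;
    arma::eig_sym(eval, evec, Nm);
    x2 = evec.col(n - 2);
  } else {
    arma::vec v1 = arma::sqrt(deg);
    v1 /= arma::norm(v1);
    arma::vec v(n);
    if (warm_start.isNotNull() &&
        NumericVector(warm_start).size() == n) {
      v = as<arma::vec>(NumericVector(warm_start));
    } else {
      for (int i = 0; i < n; ++i) v(i) = (i % 2 == 0) ? 1.0 : -1.0;
    }
    v -= v1 * arma::dot(v1, v);
    double nv = arma::norm(v);
    if (nv < 1e-12) {
      v = arma::linspace<arma::vec>(-1.0, 1.0, n);
      v -= v1 * arma::dot(v1, v);
      nv = arma::norm(v);
    }
    v /= nv;
    // the eigenvector only feeds an ordering + exact-Ncut sweep, so a
    // moderate tolerance suffices
    arma::vec prev = v;
    for (int it = 0; it < 250; ++it) {
      arma::vec w = Nm * v;
      w -= v1 * arma::dot(v1, w);
      double nw = arma::norm(w);
      if (nw < 1e-14) break;
      w /= nw;
      v = w;
      if ((it + 1) % 5 == 0) {
        if (arma::norm(v - prev) < 1e-6 || arma::norm(v + prev) < 1e-6) break;
        prev = v;
      }
    }
    x2 = v;
  }
  arma::vec gev = x2 % dis; // generalized eigenvector of (D - W) x = lambda D x

  // sweep: exact Ncut of every split along the eigenvector ordering
  arma::uvec ord = arma::sort_index(gev, "ascend");
  arma::vec ncuts(n - 1);
  double total = arma::accu(deg);
  double cut = 0.0, assocL = 0.0;
  arma::vec wl(n, arma::fill::zeros); // wl(i) = sum_{j in L} W(i, j)
  for (int s = 0; s < n - 1; ++s) {
    const int v_ = ord(s);
    cut += deg(v_) - 2.0 * wl(v_) - W(v_, v_);
    assocL += deg(v_);
    wl += W.col(v_);
    double assocR = total - assocL;
    if (assocL <= 0.0 || assocR <= 0.0)
      ncuts(s) = arma::datum::inf;
    else
      ncuts(s) = cut / assocL + cut / assocR;
  }
  return List::create(_["order"] = IntegerVector(ord.begin(), ord.end()),
                      _["ncut"] = NumericVector(ncuts.begin(), ncuts.end()),
                      _["eigvec"] = NumericVector(gev.begin(), gev.end()),
                      _["sigma"] = sigma,
                      _["no_signal"] = no_signal);
}

// Exact Ncut value of a given bipartition (used by tests and the sweep
// cross-check). side: logical vector, TRUE = left part.
// [[Rcpp::export(name = ".ncut_value")]]
double ncut_value(const arma::mat& X, const LogicalVector& side,
                  double sigma) {
  const int n = X.n_rows;
  arma::mat D2 = pairwise_sqdist(X);
  arma::mat W = arma::exp(-D2 / (2.0 * sigma * sigma));
  arma::vec deg = arma::sum(W, 1);
  double cut = 0.0, aL = 0.0, aR = 0.0;
  for (int i = 0; i < n; ++i) {
    if (side[i]) aL += deg(i); else aR += deg(i);
    for (int j = 0; j < n; ++j)
      if (side[i] && !side[j]) cut += W(i, j);
  }
  if (aL <= 0.0 || aR <= 0.0) return R_PosInf;
  return cut / aL + cut / aR;
}
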