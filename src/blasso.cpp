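#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Generalized boosted-lasso coordinate path for the nonnegative, Lp-penalized
// Poisson objective J(phi; t) = L(phi) + t * sum_i phi_i^p.
//
// Every move changes one coordinate by +/- eps (never below 0). A move that
// decreases J at the current t by more than xi is taken with t unchanged;
// otherwise the forward step minimizing L is taken and t is relaxed to
//   min(t, [L(old) - L(new)] / [pen(new) - pen(old)]),
// the local exchange rate between fit improvement and penalty increase
// (for p = 1 the denominator reduces to eps, the original lasso form).
// Iteration stops when t <= 0 or max_iters is reached.

static inline double pen_pow(double v, double p) {
  return v <= 0.0 ? 0.0 : std::pow(v, p);
}

// [[Rcpp::export]]
List blasso_path_cpp(NumericMatrix A, NumericVector X, double eps, double xi,
                     double p, int max_iters, double lambda_floor,
                     bool keep_phi) {
  const int S = A.nrow(), n = A.ncol();
  const double log_floor = std::log(lambda_floor);

  std::vector<int> pos;                   // rows with X > 0
  for (int s = 0; s < S; ++s) if (X[s] > 0) pos.push_back(s);

  // per-column: positive-count rows where the column has weight
  std::vector< std::vector<int> > posnz(n);
  NumericVector colsum(n);
  for (int i = 0; i < n; ++i) {
    double cs = 0.0;
    for (int s = 0; s < S; ++s) cs += A(s, i);
    colsum[i] = cs;
    for (size_t q = 0; q < pos.size(); ++q) {
      if (A(pos[q], i) > 0) posnz[i].push_back(pos[q]);
    }
  }

  std::vector<double> lam(S, 0.0), loglam(S, log_floor);
  std::vector<int> iphi(n, 0);            // phi_i = iphi_i * eps
  double sumlam = 0.0;

  double sumXpos = 0.0;
  for (size_t q = 0; q < pos.size(); ++q) sumXpos += X[pos[q]];
  double L = -log_floor * sumXpos;        // L at phi = 0

  // L after a single +/- eps move on coordinate i
  auto move_L = [&](int i, int dir) {
    double newsum = sumlam + dir * eps * colsum[i];
    double dlog = 0.0;
    for (size_t q = 0; q < posnz[i].size(); ++q) {
      int s = posnz[i][q];
      double nl = lam[s] + dir * eps * A(s, i);
      double lg = nl > lambda_floor ? std::log(nl) : log_floor;
      dlog += X[s] * (lg - loglam[s]);
    }
    return L + (newsum - sumlam) - dlog;
  };
  auto apply_move = [&](int i, int dir) {
    sumlam += dir * eps * colsum[i];
    for (int s = 0; s < S; ++s) {
      double a = A(s, i);
      if (a > 0) {
        lam[s] += dir * eps * a;
        loglam[s] = lam[s] > lambda_floor ? std::log(lam[s]) : log_floor;
      }
    }
    iphi[i] += dir;
  };

  // initial forward step
  int jstar = -1;
  double bestL = R_PosInf;
  for (int i = 0; i < n; ++i) {
    double Li = move_L(i, +1);
    if (Li < bestL) { bestL = Li; jstar = i; }
  }
  double t = (L - bestL) / pen_pow(eps, p);

  std::vector<double> rec_t, rec_L, rec_J;
  std::vector<int> rec_h, rec_kind;       // kind: 1 forward, -1 backward
  std::vector< std::vector<double> > rec_phi;
  std::map<int, std::pair<double, int> > best_by_h;   // h -> (L, k)
  std::map<int, std::vector<double> > best_phi_by_h;
  std::map<int, double> best_t_by_h;

  auto phi_now = [&]() {
    std::vector<double> v(n);
    for (int i = 0; i < n; ++i) v[i] = iphi[i] * eps;
    return v;
  };
  auto record = [&](int kind) {
    int h = 0;
    double pen = 0.0;
    for (int i = 0; i < n; ++i) {
      if (iphi[i] > 0) { ++h; pen += pen_pow(iphi[i] * eps, p); }
    }
    int k = (int) rec_t.size();
    rec_t.push_back(t);
    rec_L.push_back(L);
    rec_J.push_back(L + t * pen);
    rec_h.push_back(h);
    rec_kind.push_back(kind);
    if (keep_phi) rec_phi.push_back(phi_now());
    if (h >= 1) {
      auto it = best_by_h.find(h);
      if (it == best_by_h.end() || L < it->second.first) {
        best_by_h[h] = std::make_pair(L, k);
        best_phi_by_h[h] = phi_now();
        best_t_by_h[h] = t;
      }
    }
  };

  std::string terminated_by = "t_nonpositive";

  if (t <= 0.0 || n == 0) {
    // no informative first step (e.g. all counts zero): empty model
    record(1);
  } else {
    apply_move(jstar, +1);
    L = bestL;
    record(1);

    int k = 0;
    while (t > 0.0) {
      if (++k > max_iters) { terminated_by = "max_iters"; break; }
      // steepest +/- eps descent on J at current t
      int bi = -1, bdir = 0;
      double bdJ = R_PosInf, bL = 0.0;
      int fi = -1;                         // best forward step by L
      double fL = R_PosInf;
      for (int i = 0; i < n; ++i) {
        double phi_i = iphi[i] * eps;
        double Lf = move_L(i, +1);
        double dJf = (Lf - L) + t * (pen_pow(phi_i + eps, p) - pen_pow(phi_i, p));
        if (dJf < bdJ) { bdJ = dJf; bi = i; bdir = +1; bL = Lf; }
        if (Lf < fL) { fL = Lf; fi = i; }
        if (iphi[i] > 0) {
          double Lb = move_L(i, -1);
          double dJb = (Lb - L) +
            t * (pen_pow(phi_i - eps, p) - pen_pow(phi_i, p));
          if (dJb < bdJ) { bdJ = dJb; bi = i; bdir = -1; bL = Lb; }
        }
      }
      if (bdJ < -xi) {
        apply_move(bi, bdir);
        L = bL;
        record(bdir);
      } else {
        double phi_f = iphi[fi] * eps;
        double pen_inc = pen_pow(phi_f + eps, p) - pen_pow(phi_f, p);
        double tnew = (L - fL) / pen_inc;
        if (tnew < t) t = tnew;
        apply_move(fi, +1);
        L = fL;
        record(1);
      }
    }
  }

  int K = (int) rec_t.size();
  NumericMatrix phimat;
  if (keep_phi) {
    phimat = NumericMatrix(K, n);
    for (int k = 0; k < K; ++k)
      for (int i = 0; i < n; ++i) phimat(k, i) = rec_phi[k][i];
  }

  int G = (int) best_by_h.size();
  IntegerVector g_h(G), g_k(G);
  NumericVector g_L(G), g_t(G);
  NumericMatrix g_phi(G, n);
  int gi = 0;
  for (auto it = best_by_h.begin(); it != best_by_h.end(); ++it, ++gi) {
    g_h[gi] = it->first;
    g_L[gi] = it->second.first;
    g_k[gi] = it->second.second;
    g_t[gi] = best_t_by_h[it->first];
    const std::vector<double>& ph = best_phi_by_h[it->first];
    for (int i = 0; i < n; ++i) g_phi(gi, i) = ph[i];
  }

  return List::create(
    _["t"] = rec_t, _["L"] = rec_L, _["J"] = rec_J,
    _["h"] = rec_h, _["kind"] = rec_kind,
    _["phi"] = keep_phi ? (SEXP) phimat : R_NilValue,
    _["group_h"] = g_h, _["group_k"] = g_k, _["group_L"] = g_L,
    _["group_t"] = g_t, _["group_phi"] = g_phi,
    _["terminated_by"] = terminated_by
  );
}
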