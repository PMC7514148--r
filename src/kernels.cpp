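#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// copy an R column-major matrix into a flat row-major buffer so that one
// tuple's coordinates are contiguous
static std::vector<double> row_major(const NumericMatrix &M) {
  const int n = M.nrow(), d = M.ncol();
  std::vector<double> out((size_t)n * d);
  for (int c = 0; c < d; ++c)
    for (int i = 0; i < n; ++i) out[(size_t)i * d + c] = M(i, c);
  return out;
}

// max-norm distance between rows i and j of a row-major buffer
static inline double block_dist(const double *B, int d, int i, int j) {
  const double *a = B + (size_t)i * d, *b = B + (size_t)j * d;
  double m = std::fabs(a[0] - b[0]);
  for (int c = 1; c < d; ++c) {
    double v = std::fabs(a[c] - b[c]);
    if (v > m) m = v;
  }
  return m;
}

//' KSG neighbour counts for conditional mutual information I(F; X | P).
//'
//' Joint space is (F, P, X) under the max norm, so the joint distance is the
//' max of the three block distances. For each point i and each K in Ks,
//' eps_i(K) is the distance to the K-th nearest neighbour in the joint
//' space; counts are the numbers of points strictly within eps_i(K) in the
//' marginal spaces (F,P), (P,X) and (P) (Kraskov algorithm 1).
//'
//' @noRd
// [[Rcpp::export(name = ".ksg_counts")]]
List ksg_counts(NumericMatrix Fm, NumericMatrix Pm, NumericMatrix Xm,
                IntegerVector Ks) {
  const int n = Fm.nrow();
  const int nq = Ks.size();
  int kmax = 0;
  for (int q = 0; q < nq; ++q) {
    if (Ks[q] > kmax) kmax = Ks[q];
    if (q > 0 && Ks[q] < Ks[q - 1]) stop("Ks must be sorted ascending");
  }
  if (n <= kmax + 1) stop("not enough points for requested K");
  const int dF = Fm.ncol(), dP = Pm.ncol(), dX = Xm.ncol();
  std::vector<double> Fb = row_major(Fm), Pb = row_major(Pm),
                      Xb = row_major(Xm);
  const bool uni = (dF == 1 && dP == 1 && dX == 1);
  const double *f = Fb.data(), *p_ = Pb.data(), *x = Xb.data();

  // pass 1: kmax smallest joint distances per point (insertion lists)
  std::vector<double> knn((size_t)n * kmax,
                          std::numeric_limits<double>::infinity());
  for (int i = 0; i < n; ++i) {
    double *ki = &knn[(size_t)i * kmax];
    double kiw = ki[kmax - 1];
    const double fi = f[uni ? i : 0], pi = p_[uni ? i : 0],
                 xi = x[uni ? i : 0];
    for (int j = i + 1; j < n; ++j) {
      double d;
      if (uni) {
        d = std::fabs(fi - f[j]);
        double dp = std::fabs(pi - p_[j]);
        if (dp > d) d = dp;
        double dx = std::fabs(xi - x[j]);
        if (dx > d) d = dx;
      } else {
        d = block_dist(Fb.data(), dF, i, j);
        double dp = block_dist(Pb.data(), dP, i, j);
        if (dp > d) d = dp;
        double dx = block_dist(Xb.data(), dX, i, j);
        if (dx > d) d = dx;
      }
      if (d < kiw) {
        int q = kmax - 1;
        while (q > 0 && ki[q - 1] > d) { ki[q] = ki[q - 1]; --q; }
        ki[q] = d;
        kiw = ki[kmax - 1];
      }
      double *kj = &knn[(size_t)j * kmax];
      if (d < kj[kmax - 1]) {
        int q = kmax - 1;
        while (q > 0 && kj[q - 1] > d) { kj[q] = kj[q - 1]; --q; }
        kj[q] = d;
      }
    }
  }

  // eps per point per requested K (nondecreasing across q)
  std::vector<double> eps((size_t)n * nq);
  for (int i = 0; i < n; ++i)
    for (int q = 0; q < nq; ++q)
      eps[(size_t)i * nq + q] = knn[(size_t)i * kmax + (Ks[q] - 1)];

  IntegerMatrix cFP(n, nq), cPX(n, nq), cP(n, nq);
  // pass 2: strict-inequality marginal counts
  for (int i = 0; i < n; ++i) {
    const double *ei = &eps[(size_t)i * nq];
    const double fi = f[uni ? i : 0], pi = p_[uni ? i : 0],
                 xi = x[uni ? i : 0];
    for (int j = i + 1; j < n; ++j) {
      const double *ej = &eps[(size_t)j * nq];
      double dFv, dPv, dXv;
      if (uni) {
        dFv = std::fabs(fi - f[j]);
        dPv = std::fabs(pi - p_[j]);
        dXv = std::fabs(xi - x[j]);
      } else {
        dFv = block_dist(Fb.data(), dF, i, j);
        dPv = block_dist(Pb.data(), dP, i, j);
        dXv = block_dist(Xb.data(), dX, i, j);
      }
      const double dP = dPv;
      double m1 = dFv > dPv ? dFv : dPv;   // (F,P)
      double m2 = dXv > dPv ? dXv : dPv;   // (P,X)
      for (int q = nq - 1; q >= 0; --q) {
        bool any = false;
        if (m1 < ei[q]) { ++cFP(i, q); any = true; }
        if (m2 < ei[q]) { ++cPX(i, q); any = true; }
        if (dP < ei[q]) { ++cP(i, q);  any = true; }
        if (m1 < ej[q]) { ++cFP(j, q); any = true; }
        if (m2 < ej[q]) { ++cPX(j, q); any = true; }
        if (dP < ej[q]) { ++cP(j, q);  any = true; }
        if (!any) break;  // eps nondecreasing in q: smaller q cannot match
      }
    }
  }
  return List::create(_["n_fp"] = cFP, _["n_px"] = cPX, _["n_p"] = cP,
                      _["eps"] = NumericVector(eps.begin(), eps.end()));
}

//' Locally weighted nearest-neighbour estimate (simplex / cross map).
//'
//' For each prediction point, finds its `nnbr` nearest library points by
//' Euclidean distance in the embedding, excluding library points whose time
//' index is within `exclude_radius` of the prediction point's own, and
//' returns the exponentially weighted average of the library points' target
//' values: w_i = exp(-d_i / d_1), normalised. If the nearest distance is 0,
//' zero-distance neighbours get weight 1 and the rest weight 0 (the limit
//' of the weight rule).
//'
//' @noRd
// [[Rcpp::export(name = ".xmap_estimate")]]
NumericVector xmap_estimate(NumericMatrix pts, NumericVector target,
                            IntegerVector lib, IntegerVector pred,
                            IntegerVector tidx, int nnbr,
                            int exclude_radius) {
  const int E = pts.ncol();
  const int nl = lib.size(), np = pred.size();
  NumericVector out(np, NA_REAL);
  std::vector<double> nd(nnbr);
  std::vector<int> ni(nnbr);
  for (int p = 0; p < np; ++p) {
    const int ip = pred[p] - 1;
    int used = 0;
    double worst = std::numeric_limits<double>::infinity();
    for (int l = 0; l < nl; ++l) {
      const int jl = lib[l] - 1;
      if (std::abs(tidx[jl] - tidx[ip]) <= exclude_radius) continue;
      double d2 = 0.0;
      for (int c = 0; c < E; ++c) {
        double v = pts(ip, c) - pts(jl, c);
        d2 += v * v;
        if (d2 >= worst && used == nnbr) break;
      }
      if (used < nnbr) {
        nd[used] = d2; ni[used] = jl; ++used;
        if (used == nnbr) {
          // establish sorted order
          for (int a = 1; a < nnbr; ++a) {
            double dv = nd[a]; int iv = ni[a]; int b = a;
            while (b > 0 && nd[b - 1] > dv) { nd[b] = nd[b - 1]; ni[b] = ni[b - 1]; --b; }
            nd[b] = dv; ni[b] = iv;
          }
          worst = nd[nnbr - 1];
        }
      } else if (d2 < worst) {
        int b = nnbr - 1;
        while (b > 0 && nd[b - 1] > d2) { nd[b] = nd[b - 1]; ni[b] = ni[b - 1]; --b; }
        nd[b] = d2; ni[b] = jl;
        worst = nd[nnbr - 1];
      }
    }
    if (used == 0) continue;
    if (used < nnbr) {  // partial sort for the short list
      for (int a = 1; a < used; ++a) {
        double dv = nd[a]; int iv = ni[a]; int b = a;
        while (b > 0 && nd[b - 1] > dv) { nd[b] = nd[b - 1]; ni[b] = ni[b - 1]; --b; }
        nd[b] = dv; ni[b] = iv;
      }
    }
    double d1 = std::sqrt(nd[0]);
    double sw = 0.0, sv = 0.0;
    if (d1 <= 0.0) {
      for (int a = 0; a < used; ++a)
        if (nd[a] <= 0.0) { sw += 1.0; sv += target[ni[a]]; }
    } else {
      for (int a = 0; a < used; ++a) {
        double w = std::exp(-std::sqrt(nd[a]) / d1);
        sw += w; sv += w * target[ni[a]];
      }
    }
    out[p] = sv / sw;
  }
  return out;
}
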