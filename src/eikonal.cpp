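// Anisotropic eikonal solver on tetrahedral meshes (fast iterative method).
//
// Travel time along a unit direction d inside element e is sqrt(d' M_e d),
// with M_e the symmetric positive-definite slowness-squared tensor
// (units: time^2 / length^2). Node updates use the exact piecewise-linear
// local solver: minimize over the opposite face of each incident tet
//   T(x4) = min_{lambda in simplex} lambda'(t1,t2,t3) + ||x4 - x(lambda)||_M
// with closed-form root for the interior stationary point and edge/vertex
// fallbacks.
#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <vector>
using namespace Rcpp;

struct Met {
  double xx, yy, zz, xy, xz, yz;
};

static inline double quad(const Met& M, const double* a, const double* b) {
  return M.xx * a[0] * b[0] + M.yy * a[1] * b[1] + M.zz * a[2] * b[2] +
         M.xy * (a[0] * b[1] + a[1] * b[0]) +
         M.xz * (a[0] * b[2] + a[2] * b[0]) +
         M.yz * (a[1] * b[2] + a[2] * b[1]);
}

static inline double mnorm(const Met& M, const double* a) {
  double q = quad(M, a, a);
  return q > 0.0 ? std::sqrt(q) : 0.0;
}

// two-point update: knowns (xa,ta), (xb,tb), target xq
static double solve2(const double* xa, double ta, const double* xb, double tb,
                     const double* xq, const Met& M) {
  double p[3] = {xa[0] - xb[0], xa[1] - xb[1], xa[2] - xb[2]};
  double w[3] = {xq[0] - xb[0], xq[1] - xb[1], xq[2] - xb[2]};
  const double tau = ta - tb;
  const double a = quad(M, p, p), b = quad(M, p, w), c = quad(M, w, w);
  double best = R_PosInf;
  if (a > 0.0) {
    const double denom = 1.0 - tau * tau / a;
    const double num = c - b * b / a;
    if (denom > 1e-14 && num >= 0.0) {
      const double s = std::sqrt(num / denom);
      const double lam = (b - s * tau) / a;
      if (lam >= 0.0 && lam <= 1.0) {
        double z[3] = {w[0] - lam * p[0], w[1] - lam * p[1], w[2] - lam * p[2]};
        best = tb + lam * tau + mnorm(M, z);
      }
    }
  }
  // endpoint fallbacks
  double dzb = mnorm(M, w);
  double za[3] = {xq[0] - xa[0], xq[1] - xa[1], xq[2] - xa[2]};
  double dza = mnorm(M, za);
  best = std::min(best, tb + dzb);
  best = std::min(best, ta + dza);
  return best;
}

// three-point update on face (x1,t1),(x2,t2),(x3,t3) -> xq
static double solve3(const double* x1, double t1, const double* x2, double t2,
                     const double* x3, double t3, const double* xq,
                     const Met& M) {
  double P1[3] = {x1[0] - x3[0], x1[1] - x3[1], x1[2] - x3[2]};
  double P2[3] = {x2[0] - x3[0], x2[1] - x3[1], x2[2] - x3[2]};
  double w[3] = {xq[0] - x3[0], xq[1] - x3[1], xq[2] - x3[2]};
  const double A11 = quad(M, P1, P1), A12 = quad(M, P1, P2),
               A22 = quad(M, P2, P2);
  const double b1 = quad(M, P1, w), b2 = quad(M, P2, w), c = quad(M, w, w);
  const double det = A11 * A22 - A12 * A12;
  double best = R_PosInf;
  if (det > 1e-20) {
    const double i11 = A22 / det, i12 = -A12 / det, i22 = A11 / det;
    const double tau1 = t1 - t3, tau2 = t2 - t3;
    // s^2 (1 - tau' A^-1 tau) = c - b' A^-1 b
    const double tAt = tau1 * (i11 * tau1 + i12 * tau2) +
                       tau2 * (i12 * tau1 + i22 * tau2);
    const double bAb = b1 * (i11 * b1 + i12 * b2) + b2 * (i12 * b1 + i22 * b2);
    const double denom = 1.0 - tAt, num = c - bAb;
    if (denom > 1e-14 && num >= 0.0) {
      const double s = std::sqrt(num / denom);
      const double r1 = b1 - s * tau1, r2 = b2 - s * tau2;
      const double l1 = i11 * r1 + i12 * r2;
      const double l2 = i12 * r1 + i22 * r2;
      if (l1 >= 0.0 && l2 >= 0.0 && l1 + l2 <= 1.0) {
        double z[3] = {w[0] - l1 * P1[0] - l2 * P2[0],
                       w[1] - l1 * P1[1] - l2 * P2[1],
                       w[2] - l1 * P1[2] - l2 * P2[2]};
        best = t3 + l1 * tau1 + l2 * tau2 + mnorm(M, z);
      }
    }
  }
  best = std::min(best, solve2(x1, t1, x2, t2, xq, M));
  best = std::min(best, solve2(x1, t1, x3, t3, xq, M));
  best = std::min(best, solve2(x2, t2, x3, t3, xq, M));
  return best;
}

// [[Rcpp::export]]
NumericVector eikonal_fim_cpp(NumericMatrix nodes, IntegerMatrix tets,
                              NumericMatrix metric, IntegerVector src,
                              NumericVector src_t, double tol, int max_sweep) {
  const int n = nodes.nrow(), m = tets.nrow();
  if (metric.nrow() != m || metric.ncol() != 6)
    stop("metric must be an n_elem x 6 matrix");
  // node -> incident tets (CSR)
  std::vector<int> cnt(n, 0);
  for (int e = 0; e < m; ++e)
    for (int k = 0; k < 4; ++k) {
      int v = tets(e, k);
      if (v < 0 || v >= n) stop("element references invalid node");
      ++cnt[v];
    }
  std::vector<int> ptr(n + 1, 0);
  for (int i = 0; i < n; ++i) ptr[i + 1] = ptr[i] + cnt[i];
  std::vector<int> adj(ptr[n]);
  std::vector<int> fill(ptr.begin(), ptr.end() - 1);
  for (int e = 0; e < m; ++e)
    for (int k = 0; k < 4; ++k) adj[fill[tets(e, k)]++] = e;

  std::vector<double> X(3 * (std::size_t)n);
  for (int i = 0; i < n; ++i) {
    X[3 * (std::size_t)i] = nodes(i, 0);
    X[3 * (std::size_t)i + 1] = nodes(i, 1);
    X[3 * (std::size_t)i + 2] = nodes(i, 2);
  }
  std::vector<Met> Ms(m);
  for (int e = 0; e < m; ++e) {
    Ms[e].xx = metric(e, 0); Ms[e].yy = metric(e, 1); Ms[e].zz = metric(e, 2);
    Ms[e].xy = metric(e, 3); Ms[e].xz = metric(e, 4); Ms[e].yz = metric(e, 5);
  }

  std::vector<double> T(n, R_PosInf);
  std::vector<char> fixed_src(n, 0);
  for (int k = 0; k < src.size(); ++k) {
    int v = src[k];
    if (v < 0 || v >= n) stop("source node out of range");
    if (src_t[k] < T[v]) T[v] = src_t[k];
    fixed_src[v] = 1;
  }

  // Heap-based label correction: pop the tentatively smallest node and
  // update every other vertex of each incident tet through the face that
  // contains the popped node (closed-form local solver). Re-insert on
  // improvement; stale heap entries are skipped. Equivalent fixed point to
  // Gauss-Seidel iteration; near-Dijkstra cost on causal meshes.
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > heap;
  for (int k = 0; k < src.size(); ++k) heap.push(QE(T[src[k]], src[k]));
  long iter = 0;
  const long iter_cap = (long)max_sweep * (long)n + 1000;
  while (!heap.empty()) {
    if (++iter > iter_cap) break;  // safety; converged meshes never hit this
    const QE top = heap.top();
    heap.pop();
    const int i = top.second;
    if (top.first > T[i] + 1e-12) continue;  // stale
    for (int p = ptr[i]; p < ptr[i + 1]; ++p) {
      const int e = adj[p];
      const Met& M = Ms[e];
      for (int k = 0; k < 4; ++k) {
        const int v = tets(e, k);
        if (v == i || fixed_src[v]) continue;
        int oth[3]; int no = 0;
        for (int q = 0; q < 4; ++q)
          if (tets(e, q) != v) oth[no++] = tets(e, q);
        const double ta = T[oth[0]], tb = T[oth[1]], tc = T[oth[2]];
        if (std::min(ta, std::min(tb, tc)) >= T[v]) continue;
        const double* xq = &X[3 * (std::size_t)v];
        const bool fa = std::isfinite(ta), fb = std::isfinite(tb),
                   fc = std::isfinite(tc);
        double cand = R_PosInf;
        if (fa && fb && fc)
          cand = solve3(&X[3 * (std::size_t)oth[0]], ta,
                        &X[3 * (std::size_t)oth[1]], tb,
                        &X[3 * (std::size_t)oth[2]], tc, xq, M);
        else if (fa && fb)
          cand = solve2(&X[3 * (std::size_t)oth[0]], ta,
                        &X[3 * (std::size_t)oth[1]], tb, xq, M);
        else if (fa && fc)
          cand = solve2(&X[3 * (std::size_t)oth[0]], ta,
                        &X[3 * (std::size_t)oth[2]], tc, xq, M);
        else if (fb && fc)
          cand = solve2(&X[3 * (std::size_t)oth[1]], tb,
                        &X[3 * (std::size_t)oth[2]], tc, xq, M);
        else {
          for (int q = 0; q < 3; ++q) {
            if (!std::isfinite(T[oth[q]])) continue;
            double z[3] = {xq[0] - X[3 * (std::size_t)oth[q]],
                           xq[1] - X[3 * (std::size_t)oth[q] + 1],
                           xq[2] - X[3 * (std::size_t)oth[q] + 2]};
            cand = std::min(cand, T[oth[q]] + mnorm(M, z));
          }
        }
        if (cand < T[v] - tol) {
          T[v] = cand;
          heap.push(QE(cand, v));
        }
      }
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = std::isfinite(T[i]) ? T[i] : NA_REAL;
  return out;
}

// ---------------------------------------------------------------------------
// Source-factored single-source solver: T(x) = t_s + tau(x) * D0(x), with
// D0(x) = ||x - x_s||_M the straight-line metric distance from the source and
// tau solved on the mesh (tau == 1 wherever the metric straight line is a
// true geodesic). Exact on convex homogeneous domains independent of mesh
// resolution; reduces to the regular scheme's accuracy behind obstacles.
// The local face update minimizes
//   g(lambda) = D0(x(lambda)) * tau_hat(lambda) + ||x_v - x(lambda)||_M
// by pattern search in barycentric coordinates.

struct FactCtx {
  const double* X;       // 3n coords
  const Met* Ms;         // per-element metric
  double xs[3];          // source position
  double ts;             // source onset
};

static inline double d0_of(const FactCtx& C, const double* x, const Met& M) {
  double z[3] = {x[0] - C.xs[0], x[1] - C.xs[1], x[2] - C.xs[2]};
  return mnorm(M, z);
}

// Objective for target xq over face (xa,xb,xc): the slowness factor tau is
// taken as the face MAXIMUM, not a linear interpolant. Where tau is locally
// constant (any region the source sees directly, tau == 1) this is exact;
// where tau varies (shadow zones behind the cavities) it is conservative,
// never undershooting the viscosity solution the way linear interpolation
// can across a shadow boundary.
static double fact_obj(const FactCtx& C, const Met& M, const double* xa,
                       const double* xb, const double* xc, double fmax,
                       const double* xq, double u, double v) {
  const double w = 1.0 - u - v;
  double xp[3] = {u * xa[0] + v * xb[0] + w * xc[0],
                  u * xa[1] + v * xb[1] + w * xc[1],
                  u * xa[2] + v * xb[2] + w * xc[2]};
  double z[3] = {xq[0] - xp[0], xq[1] - xp[1], xq[2] - xp[2]};
  return d0_of(C, xp, M) * fmax + mnorm(M, z);
}

// pattern-search minimization over the barycentric simplex (objective is a
// sum of two convex norms, hence convex)
static double fact_face_min(const FactCtx& C, const Met& M, const double* xa,
                            const double* xb, const double* xc, double fa,
                            double fb, double fc, const double* xq) {
  const double fmax = std::max(fa, std::max(fb, fc));
  static const double U0[7] = {1, 0, 0, 0.5, 0.5, 0, 1.0 / 3.0};
  static const double V0[7] = {0, 1, 0, 0.5, 0, 0.5, 1.0 / 3.0};
  double bu = 0, bv = 0, bf = R_PosInf;
  for (int k = 0; k < 7; ++k) {
    const double f = fact_obj(C, M, xa, xb, xc, fmax, xq, U0[k], V0[k]);
    if (f < bf) { bf = f; bu = U0[k]; bv = V0[k]; }
  }
  double step = 0.25;
  for (int it = 0; it < 30; ++it) {
    bool moved = false;
    static const double DU[4] = {1, -1, 0, 0};
    static const double DV[4] = {0, 0, 1, -1};
    for (int d = 0; d < 4; ++d) {
      double u = bu + step * DU[d], v = bv + step * DV[d];
      if (u < 0 || v < 0 || u + v > 1) continue;
      const double f = fact_obj(C, M, xa, xb, xc, fmax, xq, u, v);
      if (f < bf - 1e-14) { bf = f; bu = u; bv = v; moved = true; }
    }
    if (!moved) {
      step *= 0.5;
      if (step < 1e-3) break;
    }
  }
  return bf;
}

// [[Rcpp::export]]
NumericVector eikonal_factored_cpp(NumericMatrix nodes, IntegerMatrix tets,
                                   NumericMatrix metric, int src_node,
                                   double src_t, double tol, int max_sweep) {
  const int n = nodes.nrow(), m = tets.nrow();
  if (metric.nrow() != m || metric.ncol() != 6)
    stop("metric must be an n_elem x 6 matrix");
  if (src_node < 0 || src_node >= n) stop("source node out of range");
  std::vector<int> TT(4 * (std::size_t)m);
  for (int e = 0; e < m; ++e)
    for (int k = 0; k < 4; ++k) {
      int v = tets(e, k);
      if (v < 0 || v >= n) stop("element references invalid node");
      TT[4 * (std::size_t)e + k] = v;
    }
  std::vector<int> cnt(n, 0);
  for (std::size_t q = 0; q < TT.size(); ++q) ++cnt[TT[q]];
  std::vector<int> ptr(n + 1, 0);
  for (int i = 0; i < n; ++i) ptr[i + 1] = ptr[i] + cnt[i];
  std::vector<int> adj(ptr[n]);
  {
    std::vector<int> fill(ptr.begin(), ptr.end() - 1);
    for (int e = 0; e < m; ++e)
      for (int k = 0; k < 4; ++k) adj[fill[TT[4 * (std::size_t)e + k]]++] = e;
  }
  std::vector<double> X(3 * (std::size_t)n);
  for (int i = 0; i < n; ++i) {
    X[3 * (std::size_t)i] = nodes(i, 0);
    X[3 * (std::size_t)i + 1] = nodes(i, 1);
    X[3 * (std::size_t)i + 2] = nodes(i, 2);
  }
  std::vector<Met> Ms(m);
  for (int e = 0; e < m; ++e) {
    Ms[e].xx = metric(e, 0); Ms[e].yy = metric(e, 1); Ms[e].zz = metric(e, 2);
    Ms[e].xy = metric(e, 3); Ms[e].xz = metric(e, 4); Ms[e].yz = metric(e, 5);
  }
  FactCtx C;
  C.X = X.data(); C.Ms = Ms.data(); C.ts = src_t;
  C.xs[0] = nodes(src_node, 0); C.xs[1] = nodes(src_node, 1);
  C.xs[2] = nodes(src_node, 2);

  std::vector<double> T(n, R_PosInf), F(n, R_PosInf);
  T[src_node] = src_t;
  F[src_node] = 1.0;
  auto set_T = [&](int v, double t) {
    T[v] = t;
    const Met& M = Ms[adj[ptr[v]]];  // metric of first incident element
    const double d0 = d0_of(C, &X[3 * (std::size_t)v], M);
    F[v] = d0 > 1e-12 ? (t - C.ts) / d0 : 1.0;
  };

  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > heap;
  heap.push(QE(src_t, src_node));
  long iter = 0;
  const long iter_cap = (long)max_sweep * (long)n + 1000;
  while (!heap.empty()) {
    if (++iter > iter_cap) break;
    const QE top = heap.top();
    heap.pop();
    const int i = top.second;
    if (top.first > T[i] + 1e-12) continue;  // stale
    // update every other vertex of every incident tet through the face
    // containing i (the face opposite the updated vertex)
    for (int p = ptr[i]; p < ptr[i + 1]; ++p) {
      const int e = adj[p];
      const int* vv = &TT[4 * (std::size_t)e];
      for (int k = 0; k < 4; ++k) {
        const int v = vv[k];
        if (v == i) continue;
        int oth[3]; int no = 0;
        for (int q2 = 0; q2 < 4; ++q2)
          if (vv[q2] != v) oth[no++] = vv[q2];
        const double ta = T[oth[0]], tb = T[oth[1]], tc = T[oth[2]];
        // causality filter: a face whose earliest time is not below the
        // node's current value cannot improve it
        if (std::min(ta, std::min(tb, tc)) >= T[v]) continue;
        const Met& M = Ms[e];
        const double* xq = &X[3 * (std::size_t)v];
        double cand = R_PosInf;
        if (std::isfinite(ta) && std::isfinite(tb) && std::isfinite(tc)) {
          cand = C.ts + fact_face_min(C, M, &X[3 * (std::size_t)oth[0]],
                                      &X[3 * (std::size_t)oth[1]],
                                      &X[3 * (std::size_t)oth[2]], F[oth[0]],
                                      F[oth[1]], F[oth[2]], xq);
        } else {
          for (int q2 = 0; q2 < 3; ++q2) {
            if (!std::isfinite(T[oth[q2]])) continue;
            double z[3] = {xq[0] - X[3 * (std::size_t)oth[q2]],
                           xq[1] - X[3 * (std::size_t)oth[q2] + 1],
                           xq[2] - X[3 * (std::size_t)oth[q2] + 2]};
            const double via = T[oth[q2]] + mnorm(M, z);
            if (via < cand) cand = via;
          }
        }
        if (cand < T[v] - tol) {
          set_T(v, cand);
          heap.push(QE(cand, v));
        }
      }
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = std::isfinite(T[i]) ? T[i] : NA_REAL;
  return out;
}
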