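// Vertex-model force evaluation and overdamped integration hot loop.
// Topology (T1/T2, division) is handled in R; this engine advances vertex
// positions between topology events and reports back when an interior edge
// drops below the T1 threshold.
#include <Rcpp.h>
using namespace Rcpp;

static void compute_forces(const std::vector<double>& x,
                           const std::vector<double>& y,
                           const IntegerVector& sv, const IntegerVector& svn,
                           const IntegerVector& svp, const IntegerVector& sc,
                           int ncell,
                           const std::vector<double>& A0,
                           const std::vector<double>& C0,
                           const NumericVector& gam,
                           double lambda, double beta,
                           std::vector<double>& A, std::vector<double>& C,
                           std::vector<double>& fx, std::vector<double>& fy) {
  const int ns = sv.size();
  std::fill(A.begin(), A.end(), 0.0);
  std::fill(C.begin(), C.end(), 0.0);
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);

  for (int s = 0; s < ns; ++s) {
    const int v = sv[s], n = svn[s], c = sc[s];
    const double ex = x[n] - x[v], ey = y[n] - y[v];
    A[c] += 0.5 * (x[v] * y[n] - x[n] * y[v]);
    C[c] += std::sqrt(ex * ex + ey * ey);
  }
  std::vector<double> cA(ncell), cC(ncell);
  for (int c = 0; c < ncell; ++c) {
    cA[c] = 2.0 * lambda * (A[c] - A0[c]);
    cC[c] = 2.0 * beta * (C[c] - C0[c]);
  }
  for (int s = 0; s < ns; ++s) {
    const int v = sv[s], n = svn[s], p = svp[s], c = sc[s];
    // area term
    fx[v] -= cA[c] * 0.5 * (y[n] - y[p]);
    fy[v] -= cA[c] * 0.5 * (x[p] - x[n]);
    // perimeter term
    double lnx = x[v] - x[n], lny = y[v] - y[n];
    double lpx = x[v] - x[p], lpy = y[v] - y[p];
    double ln = std::sqrt(lnx * lnx + lny * lny);
    double lp = std::sqrt(lpx * lpx + lpy * lpy);
    if (ln < 1e-14) ln = 1e-14;
    if (lp < 1e-14) lp = 1e-14;
    fx[v] -= cC[c] * (lnx / ln + lpx / lp);
    fy[v] -= cC[c] * (lny / ln + lpy / lp);
    // line tension on edge v->n (acts on both endpoints)
    fx[v] -= gam[s] * lnx / ln;
    fy[v] -= gam[s] * lny / ln;
    fx[n] += gam[s] * lnx / ln;
    fy[n] += gam[s] * lny / ln;
  }
}

// [[Rcpp::export]]
NumericMatrix vm_forces_cpp(NumericMatrix V, IntegerVector sv,
                            IntegerVector svn, IntegerVector svp,
                            IntegerVector sc, int ncell,
                            NumericVector A0, NumericVector C0,
                            NumericVector gam, double lambda, double beta) {
  const int nv = V.nrow();
  std::vector<double> x(nv), y(nv);
  for (int i = 0; i < nv; ++i) { x[i] = V(i, 0); y[i] = V(i, 1); }
  std::vector<double> A(ncell), C(ncell), fx(nv), fy(nv);
  std::vector<double> A0v(A0.begin(), A0.end()), C0v(C0.begin(), C0.end());
  compute_forces(x, y, sv, svn, svp, sc, ncell, A0v, C0v, gam, lambda, beta,
                 A, C, fx, fy);
  NumericMatrix out(nv, 2);
  for (int i = 0; i < nv; ++i) { out(i, 0) = fx[i]; out(i, 1) = fy[i]; }
  return out;
}

// Advance overdamped dynamics for up to t_chunk time units.
// Returns early (status 1) when an interior edge drops below t1_threshold
// (only if watch_edges is TRUE). Target areas grow linearly in time at
// per-cell rate dA0dt; C0 = c0 * sqrt(A0).
// status: 0 = chunk completed, 1 = short edge, 2 = step budget exhausted.
// [[Rcpp::export]]
List vm_relax_cpp(NumericMatrix V, IntegerVector sv, IntegerVector svn,
                  IntegerVector svp, IntegerVector sc, int ncell,
                  NumericVector A0_start, NumericVector dA0dt, double c0,
                  NumericVector gam, NumericMatrix fext,
                  double lambda, double beta, double drag,
                  double dt_max, double disp_max, double t_chunk,
                  IntegerVector watch_a, IntegerVector watch_b,
                  double t1_threshold, bool watch_edges, int max_steps) {
  const int nv = V.nrow();
  const int ns = sv.size();
  std::vector<double> x(nv), y(nv);
  for (int i = 0; i < nv; ++i) { x[i] = V(i, 0); y[i] = V(i, 1); }
  std::vector<double> A(ncell), C(ncell), fx(nv), fy(nv);
  std::vector<double> A0(ncell), C0(ncell);
  const int nw = watch_a.size();

  double t = 0.0;
  int status = 2, steps = 0, short_edge = -1;
  while (steps < max_steps) {
    if (t >= t_chunk * (1.0 - 1e-12)) { status = 0; break; }
    for (int c = 0; c < ncell; ++c) {
      A0[c] = A0_start[c] + dA0dt[c] * t;
      C0[c] = c0 * std::sqrt(A0[c]);
    }
    compute_forces(x, y, sv, svn, svp, sc, ncell, A0, C0, gam, lambda, beta,
                   A, C, fx, fy);
    double fmax2 = 0.0;
    for (int i = 0; i < nv; ++i) {
      fx[i] += fext(i, 0);
      fy[i] += fext(i, 1);
      const double f2 = fx[i] * fx[i] + fy[i] * fy[i];
      if (f2 > fmax2) fmax2 = f2;
    }
    const double fmax = std::sqrt(fmax2);
    if (!std::isfinite(fmax)) {
      status = 3;
      break;
    }
    double dt = dt_max;
    if (fmax > 0 && dt * fmax / drag > disp_max) dt = disp_max * drag / fmax;
    if (t + dt > t_chunk) dt = t_chunk - t;
    const double sc_dt = dt / drag;
    for (int i = 0; i < nv; ++i) { x[i] += sc_dt * fx[i]; y[i] += sc_dt * fy[i]; }
    t += dt;
    ++steps;
    if (watch_edges && nw > 0) {
      const double thr2 = t1_threshold * t1_threshold;
      for (int e = 0; e < nw; ++e) {
        const double dx = x[watch_a[e]] - x[watch_b[e]];
        const double dy = y[watch_a[e]] - y[watch_b[e]];
        if (dx * dx + dy * dy < thr2) { short_edge = e; break; }
      }
      if (short_edge >= 0) { status = 1; break; }
    }
  }
  NumericMatrix Vout(nv, 2);
  for (int i = 0; i < nv; ++i) { Vout(i, 0) = x[i]; Vout(i, 1) = y[i]; }
  return List::create(_["V"] = Vout, _["t"] = t, _["status"] = status,
                      _["short_edge"] = short_edge + 1, _["steps"] = steps);
}
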