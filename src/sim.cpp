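#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Response function f(x): weight of a positive behaviour shift.
// mode 0 = ramp_plus_noise (mean of the middle branch is the linear ramp
// joining the saturated branches), mode 1 = pure_noise (x-independent
// middle branch, the literal piecewise form).
static inline double response(double x, double r, double xi, int mode) {
  if (x <= -r) return 0.0;
  if (x >= r) return 1.0;
  double f = (mode == 0) ? (r + x + xi) / (2.0 * r) : (r + xi) / (2.0 * r);
  if (f < 0.0) f = 0.0;
  if (f > 1.0) f = 1.0;
  return f;
}

// Advance a realization by n_events single-site persuasion events.
//
// The adjacency is in CSR form: adj_ptr is 0-based, length n+1; the
// neighbours of node i (0-based) sit at adj_nbr[adj_ptr[i] .. adj_ptr[i+1]-1]
// with edge weights aligned in adj_w.
//
// RNG contract (shared with the R reference stepper, which must stay
// bit-identical): every event consumes exactly three uniforms from R's
// global stream, in this order:
//   u1 -> i = floor(u1 * n)           (agent to be updated)
//   u2 -> j = neighbour floor(u2 * deg_i) of i
//   u3 -> xi = (2 u3 - 1) * r         (interaction noise)
// Draws are consumed even when the event is a no-op (pinned or isolated i).
//
// behaviours is modified in place and returned; pinned agents are selected
// like any other but their update is discarded.
// [[Rcpp::export(name = ".run_events_cpp")]]
List run_events_cpp(NumericVector behaviours, IntegerVector adj_ptr,
                    IntegerVector adj_nbr, NumericVector adj_w,
                    LogicalVector pinned, double self_weight, double phi,
                    double r, int mode, int n_events) {
  NumericVector b = clone(behaviours);  // preserve R copy-on-modify semantics
  const int n = b.size();
  int skipped = 0;
  for (int ev = 0; ev < n_events; ++ev) {
    double u1 = unif_rand();
    double u2 = unif_rand();
    double u3 = unif_rand();
    int i = (int)(u1 * n);
    if (i >= n) i = n - 1;
    int deg = adj_ptr[i + 1] - adj_ptr[i];
    if (deg == 0) { ++skipped; continue; }
    int pos = adj_ptr[i] + (int)(u2 * deg);
    if (pos >= adj_ptr[i + 1]) pos = adj_ptr[i + 1] - 1;
    if (pinned[i]) continue;
    double bi = b[i];
    double bj = b[adj_nbr[pos]];
    double x = self_weight * bi + adj_w[pos] * bj + phi;
    double xi = (2.0 * u3 - 1.0) * r;
    double f = response(x, r, xi, mode);
    double bn = bi + std::fabs(bi - bj) * (2.0 * f - bi - 1.0);
    if (bn > 1.0) bn = 1.0;
    if (bn < -1.0) bn = -1.0;
    b[i] = bn;
  }
  return List::create(_["behaviours"] = b, _["skipped"] = skipped);
}
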