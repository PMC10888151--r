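#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gillespie direct method over term-wise unit-step channels.
//
// Channel k has linear term t_k = coef(k, .) . S, propensity |t_k|, and a
// +/-1 step on component target[k] with the sign of t_k. Terms are
// recomputed from the state at every event (the state is integer-valued and
// the coefficient rows are short, so this is cheap and avoids drift from
// incremental float updates).
//
// Two recording modes:
//   record_every == 0: zero-order hold on the uniform time grid `grid`
//     (grid times strictly before the next event time take the current
//     state); the run stops once t reaches t_end.
//   record_every == N > 0: the state and its event time are stored after
//     every Nth event until length(grid) records are taken (grid is only
//     used for its length); the run stops when the record buffer is full
//     or t exceeds t_end (pass a generous t_end in this mode).
//
// RNG: R's generator via unif_rand(), seeded from R by set.seed(), which
// pins the stream to a named, versioned algorithm on every platform.

// [[Rcpp::export]]
List ssa_core(NumericVector init, NumericMatrix coef, IntegerVector target,
              NumericVector grid, double t_end, double max_events,
              int record_every) {
  const int K = coef.nrow();
  const int d = coef.ncol();
  const int G = grid.size();

  std::vector<double> S(init.begin(), init.end());
  NumericMatrix out(G, d);
  NumericVector tout(G);
  std::vector<double> a(K), sgn(K);

  // sparse view of coef rows (most rows have 1-2 nonzeros)
  std::vector<std::vector<std::pair<int, double> > > rows(K);
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < d; ++j)
      if (coef(k, j) != 0.0) rows[k].push_back(std::make_pair(j, coef(k, j)));

  RNGScope scope;
  double t = 0.0, n_events = 0.0;
  int gi = 0, since_record = 0;
  bool absorbed = false, capped = false;

  while (t < t_end && (record_every == 0 || gi < G)) {
    double total = 0.0;
    for (int k = 0; k < K; ++k) {
      double term = 0.0;
      const std::vector<std::pair<int, double> >& r = rows[k];
      for (size_t u = 0; u < r.size(); ++u) term += r[u].second * S[r[u].first];
      a[k] = std::fabs(term);
      sgn[k] = (term > 0.0) ? 1.0 : ((term < 0.0) ? -1.0 : 0.0);
      total += a[k];
    }
    if (total <= 0.0) { absorbed = true; break; }

    double r1 = unif_rand();
    while (r1 <= 0.0) r1 = unif_rand();   // guard: r1 in (0, 1]
    double tau = -std::log(r1) / total;
    double t_next = t + tau;

    if (record_every == 0) {
      while (gi < G && grid[gi] < t_next) {  // zero-order hold
        for (int j = 0; j < d; ++j) out(gi, j) = S[j];
        tout[gi] = grid[gi];
        ++gi;
      }
      if (t_next >= t_end) { t = t_end; break; }
    }

    double thr = unif_rand() * total;      // r2 in [0, 1)
    double cum = 0.0;
    int pick = K - 1;
    for (int k = 0; k < K; ++k) {
      cum += a[k];
      if (thr < cum) { pick = k; break; }
    }
    S[target[pick]] += sgn[pick];
    t = t_next;
    n_events += 1.0;

    if (record_every > 0 && ++since_record >= record_every) {
      for (int j = 0; j < d; ++j) out(gi, j) = S[j];
      tout[gi] = t;
      ++gi;
      since_record = 0;
    }
    if (n_events >= max_events) { capped = true; break; }
  }

  if (record_every == 0) {                 // frozen tail (absorbed/cap/end)
    for (; gi < G; ++gi) {
      for (int j = 0; j < d; ++j) out(gi, j) = S[j];
      tout[gi] = grid[gi];
    }
  }

  return List::create(_["states"] = out, _["times"] = tout,
                      _["n_recorded"] = gi, _["n_events"] = n_events,
                      _["t_final"] = t, _["absorbed"] = absorbed,
                      _["capped"] = capped);
}
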