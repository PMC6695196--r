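#include <Rcpp.h>
using namespace Rcpp;

// Model codes (kept in sync with .model_code() on the R side):
// 0 simple_bd, 1 strongA_birth, 2 strongA_death, 3 strongA_both,
// 4 extA_birth, 5 extA_death, 6 extA_both

// Total birth/death event rates (per hour) at integer count n.
// The Allee reduction acts on the total rate; negative raw rates are
// clamped at 0 and n = 0 is absorbing.
static inline void total_rates(int code, double b, double d, double A,
                               double tau, double n, double *br, double *dr) {
  if (n <= 0.0) { *br = 0.0; *dr = 0.0; return; }
  double g = b - d;
  double term = 0.0;       // total-rate Allee term
  if (code >= 1 && code <= 3) {
    term = g * A;
  } else if (code >= 4) {
    term = g * n * (A + tau) / (n + tau);
  }
  double birth = b * n, death = d * n;
  switch (code) {
  case 1: birth -= term; break;
  case 2: death += term; break;
  case 3: birth -= 0.5 * term; death += 0.5 * term; break;
  case 4: birth -= term; break;
  case 5: death += term; break;
  case 6: birth -= 0.5 * term; death += 0.5 * term; break;
  default: break;
  }
  *br = birth > 0.0 ? birth : 0.0;
  *dr = death > 0.0 ? death : 0.0;
}

// [[Rcpp::export]]
NumericVector propensities_cpp(int code, double b, double d, double A,
                               double tau, NumericVector n) {
  int m = n.size();
  NumericVector out(2 * m);
  for (int i = 0; i < m; ++i) {
    double br, dr;
    total_rates(code, b, d, A, tau, n[i], &br, &dr);
    out[i] = br;
    out[m + i] = dr;
  }
  out.attr("dim") = Dimension(m, 2);
  return out;
}

// Moment-closure right-hand side: y = (mean, variance).
// Mean (shared within a family): dM/dt = g M (1 - phi),
//   phi = 0 (exponential), A/M (strong), (A+tau)/(M+tau) (extended).
// Variance:
//   exponential/strong: dS/dt = 2 g S + (b+d) M + s g A
//   extended:           dS/dt = 2 g S (1-phi) + (b+d) M + s g M phi
// with s = -1 (_birth), +1 (_death), 0 (_both / simple). The strong rows
// are exact (linear propensities); the extended rows close the factor
// 1/(n+tau) at the mean, consistently in the first- and second-moment
// equations.
// [[Rcpp::export]]
NumericVector moment_rhs_cpp(int code, double b, double d, double A,
                             double tau, NumericVector y) {
  double M = y[0], S = y[1], g = b - d;
  NumericVector dy(2);
  if (code >= 1 && code <= 3) {
    double phi = A / M;
    double s = (code == 1) ? -1.0 : (code == 2 ? 1.0 : 0.0);
    dy[0] = g * M * (1.0 - phi);
    dy[1] = 2.0 * g * S + (b + d) * M + s * g * A;
  } else if (code >= 4) {
    double phi = (A + tau) / (M + tau);
    double s = (code == 4) ? -1.0 : (code == 5 ? 1.0 : 0.0);
    dy[0] = g * M * (1.0 - phi);
    dy[1] = 2.0 * g * S * (1.0 - phi) + (b + d) * M + s * g * M * phi;
  } else {
    dy[0] = g * M;
    dy[1] = 2.0 * g * S + (b + d) * M;
  }
  return dy;
}

// One exact SSA sample path reported on a fixed observation grid
// (last-value carry-forward between events). Draws from R's RNG.
// [[Rcpp::export]]
IntegerVector ssa_grid_cpp(int code, double b, double d, double A, double tau,
                           int n0, NumericVector grid) {
  int m = grid.size();
  IntegerVector out(m);
  RNGScope scope;
  double t = 0.0;
  int n = n0, k = 0;
  double horizon = grid[m - 1];
  while (k < m) {
    double br, dr;
    total_rates(code, b, d, A, tau, (double)n, &br, &dr);
    double tot = br + dr;
    double tnext;
    if (tot <= 0.0) {
      tnext = horizon + 1.0;  // frozen (absorbed or no events possible)
    } else {
      tnext = t + R::exp_rand() / tot;
    }
    while (k < m && grid[k] < tnext) {
      out[k++] = n;
    }
    if (tnext > horizon) break;
    t = tnext;
    if (tot * unif_rand() < br) n += 1; else n -= 1;
  }
  while (k < m) out[k++] = n;
  return out;
}

// Full event path (event times and counts after each event), for
// trajectory-level inspection; capped at max_events.
// [[Rcpp::export]]
List ssa_path_cpp(int code, double b, double d, double A, double tau,
                  int n0, double horizon, int max_events) {
  std::vector<double> times;
  std::vector<int> counts;
  times.reserve(256); counts.reserve(256);
  times.push_back(0.0); counts.push_back(n0);
  RNGScope scope;
  double t = 0.0;
  int n = n0;
  while ((int)times.size() - 1 < max_events) {
    double br, dr;
    total_rates(code, b, d, A, tau, (double)n, &br, &dr);
    double tot = br + dr;
    if (tot <= 0.0) break;
    t += R::exp_rand() / tot;
    if (t > horizon) break;
    if (tot * unif_rand() < br) n += 1; else n -= 1;
    times.push_back(t);
    counts.push_back(n);
  }
  return List::create(_["event_times"] = wrap(times),
                      _["counts"] = wrap(counts));
}
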