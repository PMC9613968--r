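#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-match pair counts for sample entropy (Richman & Moorman
// convention: N - m templates at both lengths m and m + 1, self-matches
// excluded, Chebyshev distance <= r). Returns c(A, B) where B counts
// length-m matches and A counts length-(m+1) matches.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // usable templates
  double A = 0.0, B = 0.0;
  if (nt < 2) return NumericVector::create(NA_REAL, NA_REAL);
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (match) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}

// Kennel false-nearest-neighbour fraction for one candidate dimension.
// x: scalar series; ref: 0-based indices of reference delay vectors, all
// valid for dimension dim + 1. For each reference the nearest neighbour in
// the dim-dimensional embedding (Euclidean) is found among all valid
// vectors, then the two Kennel tests are applied: the extra-coordinate
// distance relative to the neighbour distance (rtol) and relative to the
// attractor size (atol).
// [[Rcpp::export]]
List fnn_fraction_cpp(NumericVector x, int delay, int dim,
                      double rtol, double atol, double attractor_size,
                      IntegerVector ref, int theiler) {
  const int n = x.size();
  const int span = dim * delay;            // extra coordinate index offset
  const int m_valid = n - span;            // vectors valid at dim + 1
  int n_false = 0, n_used = 0;
  for (int a = 0; a < ref.size(); ++a) {
    const int i = ref[a];
    double best = R_PosInf;
    int jbest = -1;
    for (int j = 0; j < m_valid; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double d2 = 0.0;
      for (int k = 0; k < dim; ++k) {
        const double dk = x[i + k * delay] - x[j + k * delay];
        d2 += dk * dk;
        if (d2 >= best) break;
      }
      if (d2 < best) { best = d2; jbest = j; }
    }
    if (jbest < 0) continue;
    const double rd = std::sqrt(best);
    const double extra = std::fabs(x[i + span] - x[jbest + span]);
    const double eps = 1e-10 * attractor_size;  // numerical-noise floor
    bool is_false;
    if (rd <= eps && extra <= eps) {
      is_false = false;  // pair identical to machine precision
    } else if (rd > 0.0) {
      is_false = (extra / rd > rtol) ||
                 (std::sqrt(rd * rd + extra * extra) / attractor_size > atol);
    } else {
      is_false = extra > 0.0;
    }
    if (is_false) ++n_false;
    ++n_used;
  }
  return List::create(_["n_false"] = n_false, _["n_used"] = n_used);
}

// Rosenstein mean log-divergence curve. traj: M x d trajectory matrix.
// For each point i (restricted so the pair can be followed for max_steps)
// the nearest neighbour outside the Theiler window is found; the pairwise
// Euclidean distance is then tracked forward and ln d accumulated per step.
// Returns sum of ln d and pair counts per step (0..max_steps).
// [[Rcpp::export]]
List rosenstein_divergence_cpp(NumericMatrix traj, int theiler, int max_steps) {
  const int M = traj.nrow();
  const int d = traj.ncol();
  const int last = M - max_steps;          // pairs must be trackable
  if (last < 2) stop("trajectory too short for the requested number of steps");
  NumericVector log_sum(max_steps + 1);
  IntegerVector count(max_steps + 1);
  for (int i = 0; i < last; ++i) {
    double best = R_PosInf;
    int jbest = -1;
    for (int j = 0; j < last; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double d2 = 0.0;
      for (int k = 0; k < d; ++k) {
        const double dk = traj(i, k) - traj(j, k);
        d2 += dk * dk;
        if (d2 >= best) break;
      }
      if (d2 < best) { best = d2; jbest = j; }
    }
    if (jbest < 0) continue;
    for (int s = 0; s <= max_steps; ++s) {
      double d2 = 0.0;
      for (int k = 0; k < d; ++k) {
        const double dk = traj(i + s, k) - traj(jbest + s, k);
        d2 += dk * dk;
      }
      if (d2 > 0.0) {
        log_sum[s] += 0.5 * std::log(d2);
        count[s] += 1;
      }
    }
  }
  return List::create(_["log_sum"] = log_sum, _["count"] = count);
}
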