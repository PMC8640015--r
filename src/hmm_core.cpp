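#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Viterbi over one observation sequence, all matrices in log space.
// obs is 0-based; returns 0-based hidden path. Ties resolve to the lowest
// state index, both per step and at the final state.
static bool viterbi_one(const int* obs, const int T, const int N,
                        const double* logT,   // N x N, column-major
                        const double* logO,   // N x M, column-major
                        const double* logS,   // length N
                        std::vector<double>& delta,
                        std::vector<double>& delta_new,
                        std::vector<int>& psi, // T x N backpointers
                        int* path,
                        int& blocked_t) {
  for (int s = 0; s < N; ++s)
    delta[s] = logS[s] + logO[s + N * obs[0]];
  bool any0 = false;
  for (int s = 0; s < N; ++s) if (delta[s] > R_NegInf) { any0 = true; break; }
  if (!any0) { blocked_t = 0; return false; }

  for (int t = 1; t < T; ++t) {
    const double* oc = logO + N * obs[t];
    bool any = false;
    for (int j = 0; j < N; ++j) {
      double best = R_NegInf;
      int arg = 0;
      const double* tc = logT + N * j; // column j: transitions i -> j
      for (int i = 0; i < N; ++i) {
        double v = delta[i] + tc[i];
        if (v > best) { best = v; arg = i; }
      }
      double v = best + oc[j];
      delta_new[j] = v;
      psi[t * N + j] = arg;
      if (v > R_NegInf) any = true;
    }
    if (!any) { blocked_t = t; return false; }
    std::swap(delta, delta_new);
  }

  double best = R_NegInf; int arg = 0;
  for (int s = 0; s < N; ++s)
    if (delta[s] > best) { best = delta[s]; arg = s; }
  path[T - 1] = arg;
  for (int t = T - 1; t > 0; --t)
    path[t - 1] = psi[t * N + path[t]];
  return true;
}

//' @noRd
// [[Rcpp::export(name = ".viterbi_path_cpp")]]
IntegerVector viterbi_path_cpp(IntegerVector obs, NumericMatrix log_trans,
                               NumericMatrix log_emis, NumericVector log_start) {
  const int T = obs.size();
  const int N = log_trans.nrow();
  std::vector<double> delta(N), delta_new(N);
  std::vector<int> psi(static_cast<size_t>(T) * N, 0);
  IntegerVector path(T);
  int blocked = -1;
  bool ok = viterbi_one(INTEGER(obs), T, N, REAL(log_trans), REAL(log_emis),
                        REAL(log_start), delta, delta_new, psi,
                        INTEGER(path), blocked);
  if (!ok)
    stop("no feasible path: every candidate path has zero probability at time step %d",
         blocked);
  return path;
}

// Refine a T x S matrix of observable indices: one Viterbi decode per column,
// with the constant-observation shortcut when enabled. shortcut_class maps
// each observable to the hidden class that emits it with highest probability
// (-1 marks an all-zero emission column, which forces full decoding).
//' @noRd
// [[Rcpp::export(name = ".refine_obs_matrix_cpp")]]
List refine_obs_matrix_cpp(IntegerMatrix obs, NumericMatrix log_trans,
                           NumericMatrix log_emis, NumericVector log_start,
                           bool use_shortcut, IntegerVector shortcut_class) {
  const int T = obs.nrow();
  const R_xlen_t S = obs.ncol();
  const int N = log_trans.nrow();
  IntegerMatrix out(T, S);
  std::vector<double> delta(N), delta_new(N);
  std::vector<int> psi(static_cast<size_t>(T) * N, 0);
  const int* po = INTEGER(obs);
  int* pr = INTEGER(out);
  R_xlen_t n_shortcut = 0;

  for (R_xlen_t s = 0; s < S; ++s) {
    const int* col = po + static_cast<R_xlen_t>(T) * s;
    int* res = pr + static_cast<R_xlen_t>(T) * s;
    bool constant = true;
    for (int t = 1; t < T; ++t)
      if (col[t] != col[0]) { constant = false; break; }
    if (use_shortcut && constant && shortcut_class[col[0]] >= 0) {
      const int cls = shortcut_class[col[0]];
      for (int t = 0; t < T; ++t) res[t] = cls;
      ++n_shortcut;
      continue;
    }
    int blocked = -1;
    bool ok = viterbi_one(col, T, N, REAL(log_trans), REAL(log_emis),
                          REAL(log_start), delta, delta_new, psi, res, blocked);
    if (!ok)
      stop("no feasible path for site %ld: every candidate path has zero probability at time step %d",
           static_cast<long>(s + 1), blocked);
  }
  return List::create(_["refined"] = out,
                      _["n_shortcut"] = static_cast<double>(n_shortcut));
}

// Running median along time (rows) for each column, odd window, nearest-edge
// padding. Values are small non-negative integer labels.
//' @noRd
// [[Rcpp::export(name = ".median_time_cpp")]]
IntegerMatrix median_time_cpp(IntegerMatrix labels, int window) {
  const int T = labels.nrow();
  const R_xlen_t S = labels.ncol();
  const int half = window / 2;
  IntegerMatrix out(T, S);
  std::vector<int> buf(window);
  const int* pl = INTEGER(labels);
  int* po = INTEGER(out);
  for (R_xlen_t s = 0; s < S; ++s) {
    const int* col = pl + static_cast<R_xlen_t>(T) * s;
    int* res = po + static_cast<R_xlen_t>(T) * s;
    for (int t = 0; t < T; ++t) {
      for (int k = -half; k <= half; ++k) {
        int tt = t + k;
        if (tt < 0) tt = 0;
        if (tt >= T) tt = T - 1;
        buf[k + half] = col[tt];
      }
      std::nth_element(buf.begin(), buf.begin() + half, buf.end());
      res[t] = buf[half];
    }
  }
  return out;
}

// Count label changes between consecutive time steps, per column, optionally
// restricted to a site mask.
//' @noRd
// [[Rcpp::export(name = ".temporal_flips_cpp")]]
double temporal_flips_cpp(IntegerMatrix labels, LogicalVector site_mask) {
  const int T = labels.nrow();
  const R_xlen_t S = labels.ncol();
  const bool use_mask = site_mask.size() > 0;
  const int* pl = INTEGER(labels);
  double flips = 0;
  for (R_xlen_t s = 0; s < S; ++s) {
    if (use_mask && !site_mask[s]) continue;
    const int* col = pl + static_cast<R_xlen_t>(T) * s;
    for (int t = 1; t < T; ++t)
      if (col[t] != col[t - 1]) ++flips;
  }
  return flips;
}
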