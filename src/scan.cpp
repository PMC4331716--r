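#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Level-wise discriminating-error scan for one gene.
//
// `v` and `stage` are in canonical (stage-major) sample order, so `stage`
// is non-decreasing with values in 1..N.  At level k a candidate line is
// drawn at each lower-group sample (stage <= k, masked or not); its error
// counts unmasked lower-group samples strictly on the high side and
// unmasked upper-group samples strictly on the low side (inequalities
// reversed for descending).  Ties at the minimum go to the highest stage,
// then the lowest canonical sample number.  Samples on the wrong side of a
// selected line are masked for all later levels, so each sample is charged
// at most once across the N-1 levels.
static void scan_core(const double *v, const int *stage, const int S,
                      const int N, const bool asc, int *level_err,
                      int *line_idx, std::vector<bool> &mask) {
  mask.assign(S, false);
  for (int k = 1; k <= N - 1; ++k) {
    int best_err = -1, best_stage = -1, best_idx = -1;
    for (int c = 0; c < S && stage[c] <= k; ++c) {
      const double vc = v[c];
      int err = 0;
      for (int s = 0; s < S; ++s) {
        if (mask[s]) continue;
        const bool lower = stage[s] <= k;
        const bool wrong = asc ? (lower ? v[s] > vc : v[s] < vc)
                               : (lower ? v[s] < vc : v[s] > vc);
        if (wrong) ++err;
      }
      if (best_idx < 0 || err < best_err ||
          (err == best_err && stage[c] > best_stage)) {
        best_err = err;
        best_stage = stage[c];
        best_idx = c;
      }
    }
    const double vl = v[best_idx];
    for (int s = 0; s < S; ++s) {
      if (mask[s]) continue;
      const bool lower = stage[s] <= k;
      const bool wrong = asc ? (lower ? v[s] > vl : v[s] < vl)
                             : (lower ? v[s] < vl : v[s] > vl);
      if (wrong) mask[s] = true;
    }
    level_err[k - 1] = best_err;
    line_idx[k - 1] = best_idx + 1;  // 1-based canonical sample number
  }
}

// [[Rcpp::export(name = ".scan_gene_cpp")]]
List scan_gene_cpp(NumericVector values, IntegerVector stage, int nstages,
                   bool ascending) {
  const int S = values.size();
  IntegerVector level_err(nstages - 1), line_idx(nstages - 1);
  std::vector<bool> mask;
  scan_core(REAL(values), INTEGER(stage), S, nstages, ascending,
            INTEGER(level_err), INTEGER(line_idx), mask);
  LogicalVector masked(S);
  for (int s = 0; s < S; ++s) masked[s] = mask[s];
  int de_total = 0;
  for (int k = 0; k < nstages - 1; ++k) de_total += level_err[k];
  return List::create(_["level_errors"] = level_err,
                      _["line_numbers"] = line_idx,
                      _["de_total"] = de_total,
                      _["masked"] = masked);
}

// Batch scan over a genes x samples matrix (columns in canonical order).
// Returns only DE_total per gene; used for permutation nulls and SVDE
// replicates where the per-level details are not needed.
// [[Rcpp::export(name = ".scan_de_cpp")]]
IntegerVector scan_de_cpp(NumericMatrix x, IntegerVector stage, int nstages,
                          bool ascending) {
  const int G = x.nrow(), S = x.ncol();
  IntegerVector de(G);
  std::vector<double> v(S);
  std::vector<int> lev(nstages - 1), lin(nstages - 1);
  std::vector<bool> mask;
  for (int g = 0; g < G; ++g) {
    for (int s = 0; s < S; ++s) v[s] = x(g, s);
    scan_core(v.data(), INTEGER(stage), S, nstages, ascending, lev.data(),
              lin.data(), mask);
    int tot = 0;
    for (int k = 0; k < nstages - 1; ++k) tot += lev[k];
    de[g] = tot;
  }
  return de;
}

// Batch scan keeping per-level errors and line numbers.
// [[Rcpp::export(name = ".scan_matrix_cpp")]]
List scan_matrix_cpp(NumericMatrix x, IntegerVector stage, int nstages,
                     bool ascending) {
  const int G = x.nrow(), S = x.ncol(), L = nstages - 1;
  IntegerMatrix level_err(G, L), line_idx(G, L);
  IntegerVector de(G);
  std::vector<double> v(S);
  std::vector<int> lev(L), lin(L);
  std::vector<bool> mask;
  for (int g = 0; g < G; ++g) {
    for (int s = 0; s < S; ++s) v[s] = x(g, s);
    scan_core(v.data(), INTEGER(stage), S, nstages, ascending, lev.data(),
              lin.data(), mask);
    int tot = 0;
    for (int k = 0; k < L; ++k) {
      level_err(g, k) = lev[k];
      line_idx(g, k) = lin[k];
      tot += lev[k];
    }
    de[g] = tot;
  }
  return List::create(_["de_total"] = de, _["level_errors"] = level_err,
                      _["line_numbers"] = line_idx);
}
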