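#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Iterative half-loop elimination on a binary case array D versus a fixed
// control array X. Per iteration the differential-sharing score
//   Q[j,k] = fracDD[j,k] - fracDX[j,k]
// is computed over the retained submatrix (fraction of other retained cases
// sharing the cell's value, minus the fraction of controls sharing it),
// then the gamma-fraction of rows and columns with lowest row-/column-scores
// is removed (at least one of each; ties broken by ascending original
// index). Controls are never removed. Optional nonnegative weight matrices
// (cases x cases with zero diagonal, and cases x controls) replace the
// uniform sharing fractions with kernel-weighted fractions; weights are
// renormalised over the retained, observed entries via the running
// denominators, so they need not be pre-normalised.
//
// Missing cells (NA) are excluded from all denominators and contribute 0.
//
// [[Rcpp::export]]
List halfloop_core(IntegerMatrix D, IntegerMatrix X, double gamma,
                   Nullable<NumericMatrix> WDD_ = R_NilValue,
                   Nullable<NumericMatrix> WDX_ = R_NilValue) {
  const int M = D.nrow(), N = D.ncol(), MX = X.nrow();
  if (N != X.ncol()) stop("D and X must share columns");
  if (!(gamma > 0.0 && gamma <= 0.5)) stop("gamma must lie in (0, 0.5]");

  const bool weighted = WDD_.isNotNull();
  NumericMatrix WDD, WDX;
  if (weighted) {
    WDD = NumericMatrix(WDD_);
    if (WDX_.isNull()) stop("weighted runs need both WDD and WDX");
    WDX = NumericMatrix(WDX_);
    if (WDD.nrow() != M || WDD.ncol() != M) stop("WDD must be cases x cases");
    if (WDX.nrow() != M || WDX.ncol() != MX) stop("WDX must be cases x controls");
  }

  std::vector<char> row_active(M, 1), col_active(N, 1);
  std::vector<int> row_elim(M, NA_INTEGER), col_elim(N, NA_INTEGER);

  // uniform-path running counts over active case rows
  std::vector<double> s1(N, 0.0), m(N, 0.0);
  // control counts (columns only ever masked, never changed)
  std::vector<double> x1(N, 0.0), xo(N, 0.0);
  for (int k = 0; k < N; ++k) {
    double a = 0, b = 0;
    for (int j = 0; j < M; ++j) {
      int v = D(j, k);
      if (v != NA_INTEGER) { b += 1; a += v; }
    }
    s1[k] = a; m[k] = b;
    double c = 0, d = 0;
    for (int j = 0; j < MX; ++j) {
      int v = X(j, k);
      if (v != NA_INTEGER) { d += 1; c += v; }
    }
    x1[k] = c; xo[k] = d;
  }

  // weighted-path running numerators/denominators
  std::vector<double> P1, PO, PX1, PXO;
  if (weighted) {
    P1.assign((size_t)M * N, 0.0);
    PO.assign((size_t)M * N, 0.0);
    PX1.assign((size_t)M * N, 0.0);
    PXO.assign((size_t)M * N, 0.0);
    for (int k = 0; k < N; ++k) {
      for (int jp = 0; jp < M; ++jp) {
        int v = D(jp, k);
        if (v == NA_INTEGER) continue;
        for (int j = 0; j < M; ++j) {
          double w = WDD(j, jp);
          if (w == 0.0) continue;
          P1[(size_t)k * M + j] += w * v;
          PO[(size_t)k * M + j] += w;
        }
      }
      for (int jx = 0; jx < MX; ++jx) {
        int v = X(jx, k);
        if (v == NA_INTEGER) continue;
        for (int j = 0; j < M; ++j) {
          double w = WDX(j, jx);
          if (w == 0.0) continue;
          PX1[(size_t)k * M + j] += w * v;
          PXO[(size_t)k * M + j] += w;
        }
      }
    }
  }

  // per-row lists of one-cells and missing cells: with the one-hot encoding
  // only a third of entries are 1, so row scores can be accumulated over the
  // ones lists instead of the full row
  std::vector<std::vector<int> > row_ones(M), row_nas(M);
  if (!weighted) {
    for (int j = 0; j < M; ++j) {
      for (int k = 0; k < N; ++k) {
        int v = D(j, k);
        if (v == NA_INTEGER) row_nas[j].push_back(k);
        else if (v == 1) row_ones[j].push_back(k);
      }
    }
  }

  std::vector<int> it_idx, it_M, it_N;
  std::vector<double> it_trace, it_trace_col;

  std::vector<int> act_rows, act_cols;
  act_rows.reserve(M); act_cols.reserve(N);
  std::vector<double> rscore(M), cscore(N);
  const double eps = 1e-12;

  int Mact = M, Nact = N, iter = 0;
  while (Mact > 0 && Nact > 0) {
    ++iter;
    act_rows.clear(); act_cols.clear();
    for (int j = 0; j < M; ++j) if (row_active[j]) act_rows.push_back(j);
    for (int k = 0; k < N; ++k) if (col_active[k]) act_cols.push_back(k);

    double trace_row = 0.0, trace_col = 0.0;
    for (int j : act_rows) rscore[j] = 0.0;
    for (int k : act_cols) cscore[k] = 0.0;

    if (!weighted) {
      std::vector<double> a_adj(N, 0.0), b_adj(N, 0.0);
      double sum_b = 0.0;
      for (int k : act_cols) {
        const double mk = m[k], s1k = s1[k], xok = xo[k], x1k = x1[k];
        if (mk >= 2.0 && xok > 0.0) {
          double alpha = (s1k - 1.0) / (mk - 1.0) - x1k / xok;
          double beta = (mk - s1k - 1.0) / (mk - 1.0) - (xok - x1k) / xok;
          a_adj[k] = alpha;
          b_adj[k] = beta;
          sum_b += beta;
          // column score from counts: 1-cells contribute alpha, 0-cells beta
          cscore[k] = s1k * alpha + (mk - s1k) * beta;
          trace_col += cscore[k];
        }
      }
      for (int j : act_rows) {
        double r = sum_b;
        for (int k : row_ones[j]) {
          if (col_active[k]) r += a_adj[k] - b_adj[k];
        }
        for (int k : row_nas[j]) {
          if (col_active[k]) r -= b_adj[k];
        }
        rscore[j] = r;
        trace_row += r;
      }
    } else {
      for (int k : act_cols) {
        const size_t off = (size_t)k * M;
        double cs = 0.0;
        for (int j : act_rows) {
          int v = D(j, k);
          if (v == NA_INTEGER) continue;
          double po = PO[off + j], pxo = PXO[off + j];
          if (po <= eps || pxo <= eps) continue;
          double p1 = P1[off + j], px1 = PX1[off + j];
          double fdd = v ? (p1 / po) : (1.0 - p1 / po);
          double fdx = v ? (px1 / pxo) : (1.0 - px1 / pxo);
          double q = fdd - fdx;
          rscore[j] += q;
          cs += q;
        }
        cscore[k] = cs;
        trace_col += cs;
      }
      for (int j : act_rows) trace_row += rscore[j];
    }

    it_idx.push_back(iter);
    it_M.push_back(Mact);
    it_N.push_back(Nact);
    it_trace.push_back(trace_row);
    it_trace_col.push_back(trace_col);

    // ---- removal ----
    int n_rm_rows = std::max(1, (int)std::lround(gamma * Mact));
    int n_rm_cols = std::max(1, (int)std::lround(gamma * Nact));
    n_rm_rows = std::min(n_rm_rows, Mact);
    n_rm_cols = std::min(n_rm_cols, Nact);

    std::vector<int> rows_sorted = act_rows, cols_sorted = act_cols;
    std::stable_sort(rows_sorted.begin(), rows_sorted.end(),
                     [&](int a, int b) {
                       if (rscore[a] != rscore[b]) return rscore[a] < rscore[b];
                       return a < b;
                     });
    std::stable_sort(cols_sorted.begin(), cols_sorted.end(),
                     [&](int a, int b) {
                       if (cscore[a] != cscore[b]) return cscore[a] < cscore[b];
                       return a < b;
                     });

    for (int r = 0; r < n_rm_rows; ++r) {
      int j = rows_sorted[r];
      row_active[j] = 0;
      row_elim[j] = iter;
      // downdate column counts / weighted denominators
      if (!weighted) {
        for (int k : act_cols) {
          int v = D(j, k);
          if (v == NA_INTEGER) continue;
          m[k] -= 1.0;
          s1[k] -= v;
        }
      } else {
        for (int k : act_cols) {
          int v = D(j, k);
          if (v == NA_INTEGER) continue;
          const size_t off = (size_t)k * M;
          for (int j2 : act_rows) {
            double w = WDD(j2, j);
            if (w == 0.0) continue;
            P1[off + j2] -= w * v;
            PO[off + j2] -= w;
          }
        }
      }
    }
    Mact -= n_rm_rows;
    for (int r = 0; r < n_rm_cols; ++r) {
      int k = cols_sorted[r];
      col_active[k] = 0;
      col_elim[k] = iter;
    }
    Nact -= n_rm_cols;
    if (iter % 64 == 0) Rcpp::checkUserInterrupt();
  }

  // terminal record: the exhausted state
  it_idx.push_back(iter + 1);
  it_M.push_back(Mact);
  it_N.push_back(Nact);
  it_trace.push_back(0.0);
  it_trace_col.push_back(0.0);

  return List::create(
    _["iteration"] = wrap(it_idx),
    _["M"] = wrap(it_M),
    _["N"] = wrap(it_N),
    _["trace"] = wrap(it_trace),
    _["trace_col"] = wrap(it_trace_col),
    _["row_elim"] = wrap(row_elim),
    _["col_elim"] = wrap(col_elim)
  );
}
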