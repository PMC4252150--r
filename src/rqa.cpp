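#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Embedded vectors are handed around as an n x m matrix (row = state
// vector). For the pairwise passes we copy into a row-major buffer so each
// state vector is contiguous in memory.
static std::vector<double> row_major(const NumericMatrix &E) {
  const int n = E.nrow(), m = E.ncol();
  std::vector<double> buf(static_cast<size_t>(n) * m);
  for (int k = 0; k < m; ++k)
    for (int i = 0; i < n; ++i)
      buf[static_cast<size_t>(i) * m + k] = E(i, k);
  return buf;
}

static inline double dist_rm(const double *a, const double *b, const int m,
                             const bool euclidean) {
  double acc = 0.0;
  if (euclidean) {
    for (int k = 0; k < m; ++k) {
      const double d = a[k] - b[k];
      acc += d * d;
    }
    return std::sqrt(acc);
  }
  for (int k = 0; k < m; ++k) {
    const double d = std::fabs(a[k] - b[k]);
    if (d > acc) acc = d;
  }
  return acc;
}

// Recurrence decision with early exit once the squared Euclidean partial
// sum (or the running maximum) exceeds the threshold.
static inline bool is_recurrent(const double *a, const double *b, const int m,
                                const bool euclidean, const double eps,
                                const double eps2) {
  if (euclidean) {
    double acc = 0.0;
    for (int k = 0; k < m; ++k) {
      const double d = a[k] - b[k];
      acc += d * d;
      if (acc > eps2) return false;
    }
    return true;
  }
  for (int k = 0; k < m; ++k) {
    if (std::fabs(a[k] - b[k]) > eps) return false;
  }
  return true;
}

// Reference phase-space scale for the relative-radius mode: the mean
// pairwise distance over at most `max_points` evenly spaced vectors
// (deterministic; exact when n <= max_points).
// [[Rcpp::export(name = ".cpp_mean_pairwise_distance")]]
double cpp_mean_pairwise_distance(NumericMatrix emb, bool euclidean,
                                  int max_points = 1024) {
  const int n = emb.nrow(), m = emb.ncol();
  if (n < 2) return NA_REAL;
  std::vector<double> buf = row_major(emb);
  std::vector<int> idx;
  if (n <= max_points) {
    idx.resize(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
  } else {
    idx.resize(max_points);
    for (int i = 0; i < max_points; ++i)
      idx[i] = static_cast<int>(
          (static_cast<double>(i) * (n - 1)) / (max_points - 1));
  }
  const int s = static_cast<int>(idx.size());
  double acc = 0.0;
  long long cnt = 0;
  for (int i = 0; i < s - 1; ++i) {
    const double *a = &buf[static_cast<size_t>(idx[i]) * m];
    for (int j = i + 1; j < s; ++j) {
      acc += dist_rm(a, &buf[static_cast<size_t>(idx[j]) * m], m, euclidean);
      ++cnt;
    }
  }
  return acc / static_cast<double>(cnt);
}

// Binary recurrence matrix: R[i,j] = 1 iff dist(v_i, v_j) <= radius
// (boundary counts as recurrent). theiler = 0 keeps the identity line;
// theiler > 0 zeroes the whole band |i - j| <= theiler.
// [[Rcpp::export(name = ".cpp_recurrence_matrix")]]
IntegerMatrix cpp_recurrence_matrix(NumericMatrix emb, double radius,
                                    bool euclidean, int theiler) {
  const int n = emb.nrow(), m = emb.ncol();
  const double eps2 = radius * radius;
  std::vector<double> buf = row_major(emb);
  IntegerMatrix R(n, n);
  for (int i = 0; i < n; ++i) {
    R(i, i) = (theiler == 0) ? 1 : 0;
    const double *a = &buf[static_cast<size_t>(i) * m];
    for (int j = i + 1; j < n; ++j) {
      int rec = 0;
      if (j - i > theiler)
        rec = is_recurrent(a, &buf[static_cast<size_t>(j) * m], m, euclidean,
                           radius, eps2)
                  ? 1
                  : 0;
      R(i, j) = rec;
      R(j, i) = rec;
    }
  }
  return R;
}

// Fused single-pass engine behind rqa(): thresholds all pairs once into a
// byte matrix, then extracts every quantity the scalar measures need.
// Returns total recurrent points (full matrix convention), diagonal and
// vertical maximal line lengths, and per-diagonal recurrence densities.
// [[Rcpp::export(name = ".cpp_rqa_engine")]]
List cpp_rqa_engine(NumericMatrix emb, double radius, bool euclidean,
                    int theiler) {
  const int n = emb.nrow(), m = emb.ncol();
  const double eps2 = radius * radius;
  std::vector<double> buf = row_major(emb);
  std::vector<uint8_t> R(static_cast<size_t>(n) * n, 0);
  long long total = 0;
  for (int i = 0; i < n; ++i) {
    if (theiler == 0) {
      R[static_cast<size_t>(i) * n + i] = 1;
      ++total;
    }
    const double *a = &buf[static_cast<size_t>(i) * m];
    for (int j = i + 1 + theiler; j < n; ++j) {
      if (is_recurrent(a, &buf[static_cast<size_t>(j) * m], m, euclidean,
                       radius, eps2)) {
        R[static_cast<size_t>(i) * n + j] = 1;
        R[static_cast<size_t>(j) * n + i] = 1;
        total += 2;
      }
    }
  }
  // diagonal lines (upper triangle, offsets > theiler band) and densities
  std::vector<int> dlen;
  NumericVector dens(n - 1);
  const int kmin = (theiler > 0 ? theiler : 0) + 1;
  for (int k = 1; k < n; ++k) {
    long long s = 0;
    if (k >= kmin) {
      int run = 0;
      for (int i = 0; i + k < n; ++i) {
        if (R[static_cast<size_t>(i) * n + i + k]) {
          ++run;
          ++s;
        } else if (run) {
          dlen.push_back(run);
          run = 0;
        }
      }
      if (run) dlen.push_back(run);
    }
    dens[k - 1] = static_cast<double>(s) / static_cast<double>(n - k);
  }
  // vertical lines over the matrix as stored; R is symmetric, so column j
  // can be scanned as row j (contiguous memory)
  std::vector<int> vlen;
  for (int j = 0; j < n; ++j) {
    int run = 0;
    for (int i = 0; i < n; ++i) {
      if (R[static_cast<size_t>(j) * n + i]) {
        ++run;
      } else if (run) {
        vlen.push_back(run);
        run = 0;
      }
    }
    if (run) vlen.push_back(run);
  }
  return List::create(_["total"] = static_cast<double>(total),
                      _["n"] = n,
                      _["diagonal"] = wrap(dlen),
                      _["vertical"] = wrap(vlen),
                      _["density"] = dens);
}

// Lengths of maximal runs of 1s along the upper-triangle diagonals,
// offsets k = max(theiler, 0) + 1 ... n-1. The identity line is never
// scanned; by symmetry each unordered line is counted once.
// [[Rcpp::export(name = ".cpp_diagonal_line_lengths")]]
IntegerVector cpp_diagonal_line_lengths(IntegerMatrix R, int theiler) {
  const int n = R.nrow();
  std::vector<int> out;
  const int kmin = (theiler > 0 ? theiler : 0) + 1;
  for (int k = kmin; k < n; ++k) {
    int run = 0;
    for (int i = 0; i + k < n; ++i) {
      if (R(i, i + k)) {
        ++run;
      } else if (run) {
        out.push_back(run);
        run = 0;
      }
    }
    if (run) out.push_back(run);
  }
  return wrap(out);
}

// Lengths of maximal vertical runs of 1s, column by column, over the full
// matrix as stored (identity line participates when theiler = 0; an
// excluded Theiler band is already zero).
// [[Rcpp::export(name = ".cpp_vertical_line_lengths")]]
IntegerVector cpp_vertical_line_lengths(IntegerMatrix R) {
  const int n = R.nrow();
  std::vector<int> out;
  for (int j = 0; j < n; ++j) {
    int run = 0;
    for (int i = 0; i < n; ++i) {
      if (R(i, j)) {
        ++run;
      } else if (run) {
        out.push_back(run);
        run = 0;
      }
    }
    if (run) out.push_back(run);
  }
  return wrap(out);
}

// Recurrence density of each upper-triangle diagonal (offset k = 1..n-1).
// [[Rcpp::export(name = ".cpp_diagonal_density")]]
NumericVector cpp_diagonal_density(IntegerMatrix R) {
  const int n = R.nrow();
  NumericVector dens(n - 1);
  for (int k = 1; k < n; ++k) {
    long long s = 0;
    for (int i = 0; i + k < n; ++i) s += R(i, i + k);
    dens[k - 1] = static_cast<double>(s) / static_cast<double>(n - k);
  }
  return dens;
}
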