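#include <Rcpp.h>
using namespace Rcpp;

// Dependent multivariate DTW: one warping path shared across channels,
// local cost = squared Euclidean distance across channels, classic
// O(n*m) dynamic program, no warping-window constraint.
//
// Series are stored column-major as length x channels buffers. The DP is
// rolled over two rows with the boundary cases hoisted out of the inner
// loop; the common 3-channel case has a specialized local-cost path.

static inline double local_cost(const double* a, int i, int lda,
                                const double* b, int j, int ldb, int nch) {
  if (nch == 3) {
    double d0 = a[i] - b[j];
    double d1 = a[i + lda] - b[j + ldb];
    double d2 = a[i + 2 * lda] - b[j + 2 * ldb];
    return d0 * d0 + d1 * d1 + d2 * d2;
  }
  double cost = 0.0;
  for (int c = 0; c < nch; ++c) {
    double d = a[i + lda * c] - b[j + ldb * c];
    cost += d * d;
  }
  return cost;
}

static double dtw_pair(const double* a, int na, const double* b, int nb,
                       int nch, int lda, int ldb, std::vector<double>& row) {
  row.resize(nb);
  // first row: cumulative along j
  double acc = 0.0;
  for (int j = 0; j < nb; ++j) {
    acc += local_cost(a, 0, lda, b, j, ldb, nch);
    row[j] = acc;
  }
  for (int i = 1; i < na; ++i) {
    double diag = row[0];                       // D(i-1, 0)
    row[0] = diag + local_cost(a, i, lda, b, 0, ldb, nch);
    double left = row[0];
    for (int j = 1; j < nb; ++j) {
      double up = row[j];                       // D(i-1, j)
      double best = diag < up ? diag : up;
      if (left < best) best = left;
      left = local_cost(a, i, lda, b, j, ldb, nch) + best;
      row[j] = left;
      diag = up;
    }
  }
  return row[nb - 1];
}

// [[Rcpp::export]]
double dtw_distance_cpp(NumericMatrix a, NumericMatrix b) {
  if (a.nrow() == 0 || b.nrow() == 0)
    stop("DTW is undefined for empty series");
  if (a.ncol() != b.ncol())
    stop("series must have the same number of channels");
  std::vector<double> row;
  return dtw_pair(REAL(a), a.nrow(), REAL(b), b.nrow(), a.ncol(),
                  a.nrow(), b.nrow(), row);
}

// Pairwise distances between two stacks of equal-length windows stored as
// n x L x C arrays. Returns an nq x nr matrix.
// [[Rcpp::export]]
NumericMatrix dtw_cross_cpp(NumericVector q, NumericVector r) {
  IntegerVector dq = q.attr("dim"), dr = r.attr("dim");
  if (dq.size() != 3 || dr.size() != 3)
    stop("expected 3-dimensional window arrays");
  int nq = dq[0], Lq = dq[1], Cq = dq[2];
  int nr = dr[0], Lr = dr[1], Cr = dr[2];
  if (Cq != Cr) stop("channel counts differ");
  if (Lq == 0 || Lr == 0) stop("DTW is undefined for empty series");
  NumericMatrix out(nq, nr);
  // copy windows once into contiguous L x C buffers
  std::vector<double> bufq((size_t)nq * Lq * Cq), bufr((size_t)nr * Lr * Cr);
  const double* Q = REAL(q);
  const double* R = REAL(r);
  for (int i = 0; i < nq; ++i)
    for (int c = 0; c < Cq; ++c)
      for (int t = 0; t < Lq; ++t)
        bufq[(size_t)i * Lq * Cq + t + Lq * c] = Q[i + (size_t)nq * (t + Lq * c)];
  for (int j = 0; j < nr; ++j)
    for (int c = 0; c < Cr; ++c)
      for (int t = 0; t < Lr; ++t)
        bufr[(size_t)j * Lr * Cr + t + Lr * c] = R[j + (size_t)nr * (t + Lr * c)];
  std::vector<double> row;
  for (int i = 0; i < nq; ++i) {
    const double* wa = &bufq[(size_t)i * Lq * Cq];
    for (int j = 0; j < nr; ++j) {
      const double* wb = &bufr[(size_t)j * Lr * Cr];
      out(i, j) = dtw_pair(wa, Lq, wb, Lr, Cq, Lq, Lr, row);
    }
  }
  return out;
}
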