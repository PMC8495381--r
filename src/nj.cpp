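#include <Rcpp.h>
using namespace Rcpp;

// Canonical neighbor-joining on a symmetric distance matrix.
// Ties in the Q criterion (within 1e-12) are broken by the lexicographically
// smallest (row, col) pair of node ids, leaves first (ids 1..n in input
// order, internal nodes n+1..). Negative branch lengths are clamped to zero
// and counted.
//
// Returns:
//   joins:  (n-3) x 5 matrix, one row per agglomeration:
//           (node_a, node_b, branch_a, branch_b, new_node)
//   final3: 3 x 3 matrix (node, terminal_node, branch) attaching the last
//           three active nodes to the terminal internal node
//   terminal: id of the terminal internal node (= 2n - 2)
//   n_clamped: number of negative branch lengths clamped to zero
// [[Rcpp::export]]
List nj_cpp(NumericMatrix dist) {
  const double eps = 1e-12;
  const int n = dist.nrow();
  if (n < 4) stop("neighbor joining requires >= 4 taxa");
  std::vector<double> d((size_t)n * n);
  std::vector<int> id(n); // slot -> node id (0-based)
  for (int i = 0; i < n; ++i) {
    id[i] = i;
    for (int j = 0; j < n; ++j) d[(size_t)i * n + j] = dist(i, j);
  }
  int m = n;
  int next_id = n;
  int n_clamped = 0;
  NumericMatrix joins(n - 3, 5);
  NumericMatrix final3(3, 3);
  std::vector<double> r(n);

  for (int step = 0; step < n - 3; ++step) {
    for (int i = 0; i < m; ++i) {
      const double* di = &d[(size_t)i * n];
      double s = 0;
      for (int j = 0; j < m; ++j) s += di[j];
      r[i] = s;
    }
    const double m2 = m - 2;
    double best = R_PosInf;
    int bi = -1, bj = -1;       // slots of the chosen pair
    int pa = -1, pb = -1;       // ordered node ids of the chosen pair
    for (int i = 0; i < m; ++i) {
      const double* di = &d[(size_t)i * n];
      const double ri = r[i];
      for (int j = i + 1; j < m; ++j) {
        const double q = m2 * di[j] - ri - r[j];
        if (q > best + eps) continue;  // hot path: not competitive
        const int a = id[i] < id[j] ? id[i] : id[j];
        const int b = id[i] < id[j] ? id[j] : id[i];
        bool take;
        if (q < best - eps) {
          take = true;
        } else {  // within tolerance: smallest (row, col) id pair wins
          take = (pa == -1) || (a < pa) || (a == pa && b < pb);
        }
        if (take) {
          if (q < best) best = q;
          bi = i; bj = j; pa = a; pb = b;
        }
      }
    }
    const double dij = d[(size_t)bi * n + bj];
    double li = 0.5 * dij + (r[bi] - r[bj]) / (2.0 * m2);
    double lj = dij - li;
    if (li < 0) { li = 0; ++n_clamped; }
    if (lj < 0) { lj = 0; ++n_clamped; }
    joins(step, 0) = id[bi] + 1;
    joins(step, 1) = id[bj] + 1;
    joins(step, 2) = li;
    joins(step, 3) = lj;
    joins(step, 4) = next_id + 1;
    // the new node takes slot bi; the last slot moves into bj
    for (int k = 0; k < m; ++k) {
      if (k == bi || k == bj) continue;
      const double dn =
        0.5 * (d[(size_t)bi * n + k] + d[(size_t)bj * n + k] - dij);
      d[(size_t)bi * n + k] = dn;
      d[(size_t)k * n + bi] = dn;
    }
    d[(size_t)bi * n + bi] = 0;
    id[bi] = next_id;
    const int last = m - 1;
    if (bj != last) {
      id[bj] = id[last];
      for (int k = 0; k < m; ++k) {
        d[(size_t)bj * n + k] = d[(size_t)last * n + k];
        d[(size_t)k * n + bj] = d[(size_t)k * n + last];
      }
      d[(size_t)bj * n + bj] = 0;
    }
    --m;
    ++next_id;
  }
  const double d01 = d[1], d02 = d[2], d12 = d[(size_t)n + 2];
  double b0 = 0.5 * (d01 + d02 - d12);
  double b1 = 0.5 * (d01 + d12 - d02);
  double b2 = 0.5 * (d02 + d12 - d01);
  if (b0 < 0) { b0 = 0; ++n_clamped; }
  if (b1 < 0) { b1 = 0; ++n_clamped; }
  if (b2 < 0) { b2 = 0; ++n_clamped; }
  for (int k = 0; k < 3; ++k) final3(k, 1) = next_id + 1;
  final3(0, 0) = id[0] + 1; final3(0, 2) = b0;
  final3(1, 0) = id[1] + 1; final3(1, 2) = b1;
  final3(2, 0) = id[2] + 1; final3(2, 2) = b2;
  return List::create(_["joins"] = joins, _["final3"] = final3,
                      _["terminal"] = next_id + 1,
                      _["n_clamped"] = n_clamped);
}
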