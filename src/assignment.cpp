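#include <Rcpp.h>
#include <limits>
#include <vector>
using namespace Rcpp;

// Minimum-cost rectangular bipartite assignment (rows <= cols) by successive
// shortest augmenting paths with dual potentials (Jonker-Volgenant family).
// Every row ends up assigned to a distinct column and the total cost is the
// global minimum over all one-to-one assignments without replacement.
// Returns the 1-based column assigned to each row.
// [[Rcpp::export]]
IntegerVector lsap_solve(NumericMatrix cost) {
  const int nr = cost.nrow(), nc = cost.ncol();
  if (nr == 0) return IntegerVector(0);
  if (nr > nc) stop("lsap_solve requires nrow <= ncol");
  const double inf = std::numeric_limits<double>::infinity();

  std::vector<double> u(nr, 0.0), v(nc, 0.0);
  std::vector<int> col4row(nr, -1), row4col(nc, -1);

  for (int curRow = 0; curRow < nr; ++curRow) {
    std::vector<double> shortest(nc, inf);
    std::vector<int> path(nc, -1);
    std::vector<char> SR(nr, 0), SC(nc, 0);

    double minVal = 0.0;
    int i = curRow, sink = -1;
    while (sink == -1) {
      SR[i] = 1;
      double lowest = inf;
      int jLow = -1;
      for (int j = 0; j < nc; ++j) {
        if (SC[j]) continue;
        double r = minVal + cost(i, j) - u[i] - v[j];
        if (r < shortest[j]) { shortest[j] = r; path[j] = i; }
        if (shortest[j] < lowest ||
            (shortest[j] == lowest && row4col[j] == -1)) {
          lowest = shortest[j];
          jLow = j;
        }
      }
      minVal = lowest;
      if (!(minVal < inf)) stop("infeasible assignment problem");
      if (row4col[jLow] == -1) sink = jLow; else i = row4col[jLow];
      SC[jLow] = 1;
    }

    u[curRow] += minVal;
    for (int r = 0; r < nr; ++r)
      if (SR[r] && r != curRow) u[r] += minVal - shortest[col4row[r]];
    for (int j = 0; j < nc; ++j)
      if (SC[j]) v[j] -= minVal - shortest[j];

    int j = sink;
    for (;;) {
      int r = path[j];
      row4col[j] = r;
      std::swap(col4row[r], j);
      if (r == curRow) break;
    }
  }

  IntegerVector out(nr);
  for (int r = 0; r < nr; ++r) out[r] = col4row[r] + 1;
  return out;
}
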