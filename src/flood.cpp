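#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <vector>
using namespace Rcpp;

// Marker-controlled flooding ("priority flood"): starting from labelled seed
// pixels, repeatedly extend the lowest-priority front into unlabelled mask
// pixels (8-connected). Ties are broken first-in-first-out via an insertion
// counter, which makes the result fully deterministic. With a constant
// priority image this reduces to multi-source BFS, i.e. nearest-seed
// (geodesic) assignment.
// [[Rcpp::export]]
IntegerMatrix seeded_flood_cpp(NumericMatrix priority, IntegerMatrix seeds,
                               LogicalMatrix mask) {
  int nr = priority.nrow(), nc = priority.ncol();
  IntegerMatrix lab(nr, nc);
  typedef std::tuple<double, long long, int> Node;  // value, order, linear idx
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  long long cnt = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (mask(i, j) && seeds(i, j) > 0) {
        lab(i, j) = seeds(i, j);
        pq.push(Node(priority(i, j), cnt++, i + j * nr));
      }
  const int dr[8] = { -1, 1, 0, 0, -1, -1, 1, 1 };
  const int dc[8] = { 0, 0, -1, 1, -1, 1, -1, 1 };
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    int idx = std::get<2>(nd);
    int i = idx % nr, j = idx / nr;
    int l = lab(i, j);
    for (int k = 0; k < 8; ++k) {
      int ni = i + dr[k], nj = j + dc[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      if (!mask(ni, nj) || lab(ni, nj) != 0) continue;
      lab(ni, nj) = l;
      pq.push(Node(priority(ni, nj), cnt++, ni + nj * nr));
    }
  }
  return lab;
}

// Connected-component labelling with 4- or 8-connectivity. Components are
// numbered 1..N in raster order (column-major, as stored) of their first
// encountered pixel, so labelling is deterministic.
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask, int conn) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = { -1, 1, 0, 0, -1, -1, 1, 1 };
  const int dc8[8] = { 0, 0, -1, 1, -1, 1, -1, 1 };
  int nk = (conn == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int k = 0; k < nk; ++k) {
          int ni = ci + dr8[k], nj = cj + dc8[k];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (!mask(ni, nj) || lab(ni, nj) != 0) continue;
          lab(ni, nj) = next;
          stack.push_back(ni + nj * nr);
        }
      }
    }
  return lab;
}

static inline int nb(const LogicalMatrix& x, int i, int j) {
  if (i < 0 || i >= x.nrow() || j < 0 || j >= x.ncol()) return 0;
  return x(i, j) ? 1 : 0;
}

// Zhang-Suen topological thinning to a 1-pixel-wide, 8-connected skeleton.
// [[Rcpp::export]]
LogicalMatrix skeletonize_cpp(LogicalMatrix x) {
  int nr = x.nrow(), nc = x.ncol();
  LogicalMatrix s = clone(x);
  bool changed = true;
  while (changed) {
    changed = false;
    for (int phase = 0; phase < 2; ++phase) {
      std::vector<int> kill;
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
          if (!s(i, j)) continue;
          // neighbours P2..P9 clockwise from north
          int p2 = nb(s, i - 1, j), p3 = nb(s, i - 1, j + 1);
          int p4 = nb(s, i, j + 1), p5 = nb(s, i + 1, j + 1);
          int p6 = nb(s, i + 1, j), p7 = nb(s, i + 1, j - 1);
          int p8 = nb(s, i, j - 1), p9 = nb(s, i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (phase == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(i + j * nr);
        }
      for (size_t k = 0; k < kill.size(); ++k) {
        s(kill[k] % nr, kill[k] / nr) = false;
        changed = true;
      }
    }
  }
  return s;
}

// Multi-source Dijkstra over the mask: the cost to enter a pixel is the
// step length (1 or sqrt(2)) times the pixel's weight. Returns the label of
// the cheapest seed and the accumulated cost per pixel. Ties resolve
// first-in-first-out, deterministically.
// [[Rcpp::export]]
List geodesic_flood_cpp(NumericMatrix weight, IntegerMatrix seeds,
                        LogicalMatrix mask) {
  int nr = weight.nrow(), nc = weight.ncol();
  IntegerMatrix lab(nr, nc);
  NumericMatrix cost(nr, nc);
  std::fill(cost.begin(), cost.end(), R_PosInf);
  typedef std::tuple<double, long long, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  long long cnt = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (mask(i, j) && seeds(i, j) > 0) {
        lab(i, j) = seeds(i, j);
        cost(i, j) = 0.0;
        pq.push(Node(0.0, cnt++, i + j * nr));
      }
  const int dr[8] = { -1, 1, 0, 0, -1, -1, 1, 1 };
  const int dc[8] = { 0, 0, -1, 1, -1, 1, -1, 1 };
  const double SQ2 = 1.4142135623730951;
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    double c = std::get<0>(nd);
    int idx = std::get<2>(nd);
    int i = idx % nr, j = idx / nr;
    if (c > cost(i, j)) continue;   // stale entry
    int l = lab(i, j);
    for (int k = 0; k < 8; ++k) {
      int ni = i + dr[k], nj = j + dc[k];
      if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
      if (!mask(ni, nj)) continue;
      double step = (k < 4 ? 1.0 : SQ2) * weight(ni, nj);
      double nc2 = c + step;
      if (nc2 < cost(ni, nj)) {
        cost(ni, nj) = nc2;
        lab(ni, nj) = l;
        pq.push(Node(nc2, cnt++, ni + nj * nr));
      }
    }
  }
  return List::create(Rcpp::Named("labels") = lab,
                      Rcpp::Named("cost") = cost);
}
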