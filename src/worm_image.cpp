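#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Assign every pixel within `radius` of the polyline to its nearest vertex.
// Points are 1-based (row, col) image coordinates. Returns nearest-vertex
// index (1-based, 0 = unassigned) and squared distance maps, plus a body mask
// built as the union of discs of per-vertex radius `halfw` (disc model of the
// worm body). Search window per vertex is max(radius, halfw[i]) so the body
// mask is an exact disc union even where halfw exceeds `radius`.
// [[Rcpp::export]]
List cpp_assign_nearest(int nrow, int ncol, NumericVector pr, NumericVector pc,
                        NumericVector halfw, double radius) {
  int n = pr.size();
  IntegerMatrix nearest(nrow, ncol);
  NumericMatrix d2map(nrow, ncol);
  LogicalMatrix body(nrow, ncol);
  std::fill(d2map.begin(), d2map.end(), R_PosInf);
  for (int i = 0; i < n; ++i) {
    double r0 = pr[i] - 1.0, c0 = pc[i] - 1.0;
    double w = halfw.size() == n ? halfw[i] : (halfw.size() == 1 ? halfw[0] : 0.0);
    double rad = std::max(radius, w) + 1.0;
    int rlo = std::max(0, (int)std::floor(r0 - rad));
    int rhi = std::min(nrow - 1, (int)std::ceil(r0 + rad));
    int clo = std::max(0, (int)std::floor(c0 - rad));
    int chi = std::min(ncol - 1, (int)std::ceil(c0 + rad));
    for (int r = rlo; r <= rhi; ++r) {
      double dr = r - r0;
      for (int c = clo; c <= chi; ++c) {
        double dc = c - c0;
        double d2 = dr * dr + dc * dc;
        if (d2 <= w * w) body(r, c) = true;
        if (d2 <= radius * radius && d2 < d2map(r, c)) {
          d2map(r, c) = d2;
          nearest(r, c) = i + 1;
        }
      }
    }
  }
  return List::create(_["nearest"] = nearest, _["dist2"] = d2map,
                      _["body"] = body);
}

static inline int nb(const IntegerMatrix &m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c) != 0;
}

// Zhang-Suen thinning of a binary mask down to a 1-px skeleton.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img = clone(mask);
  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (!img(r, c)) continue;
          int p2 = nb(img, r - 1, c), p3 = nb(img, r - 1, c + 1);
          int p4 = nb(img, r, c + 1), p5 = nb(img, r + 1, c + 1);
          int p6 = nb(img, r + 1, c), p7 = nb(img, r + 1, c - 1);
          int p8 = nb(img, r, c - 1), p9 = nb(img, r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(r, c));
        }
      }
      for (size_t k = 0; k < kill.size(); ++k)
        img(kill[k].first, kill[k].second) = 0;
      if (!kill.empty()) changed = true;
    }
  }
  return img;
}

static IntegerVector bfs_far(const IntegerMatrix &skel,
                             const std::vector<int> &ids, int start,
                             std::vector<int> &dist, std::vector<int> &parent) {
  int nr = skel.nrow(), nc = skel.ncol();
  std::fill(dist.begin(), dist.end(), -1);
  std::fill(parent.begin(), parent.end(), -1);
  std::queue<int> q;
  dist[start] = 0;
  q.push(start);
  int far = start;
  while (!q.empty()) {
    int cur = q.front(); q.pop();
    int r = cur % nr, c = cur / nr;
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        if (!dr && !dc) continue;
        int rr = r + dr, cc = c + dc;
        if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
        if (!skel(rr, cc)) continue;
        int nxt = rr + cc * nr;
        if (dist[nxt] >= 0) continue;
        dist[nxt] = dist[cur] + 1;
        parent[nxt] = cur;
        if (dist[nxt] > dist[far]) far = nxt;
        q.push(nxt);
      }
    }
  }
  return IntegerVector::create(far);
}

// Longest geodesic path through an 8-connected skeleton (double BFS).
// Returns ordered 1-based (row, col) coordinates; side branches are pruned
// implicitly by taking the longest end-to-end route.
// [[Rcpp::export]]
IntegerMatrix cpp_longest_path(IntegerMatrix skel) {
  int nr = skel.nrow(), nc = skel.ncol();
  std::vector<int> ids;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (skel(r, c)) ids.push_back(r + c * nr);
  if (ids.empty()) return IntegerMatrix(0, 2);
  std::vector<int> dist(nr * nc), parent(nr * nc);
  int a = bfs_far(skel, ids, ids[0], dist, parent)[0];
  int b = bfs_far(skel, ids, a, dist, parent)[0];
  std::vector<int> path;
  for (int cur = b; cur != -1; cur = parent[cur]) path.push_back(cur);
  IntegerMatrix out(path.size(), 2);
  for (size_t i = 0; i < path.size(); ++i) {
    out(i, 0) = path[i] % nr + 1;
    out(i, 1) = path[i] / nr + 1;
  }
  return out;
}
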